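make_norm <- function(values) {
  structure(list(values = values,
                 gene_ids = paste0("g", seq_len(nrow(values))),
                 cell_ids = paste0("c", seq_len(ncol(values))),
                 library_target = 1e6),
            class = "normalized_matrix")
}

test_that("select_feature_candidates ranks by variance with stable ties", {
  set.seed(1)
  m <- matrix(rnorm(100 * 8), 100, 8)
  f <- select_feature_candidates(make_norm(m), top_fraction = 0.05)
  expect_length(f$gene_indices, 5L)
  v <- f$variances
  expect_true(min(v[f$gene_indices]) >= max(v[-f$gene_indices]))

  # a constant gene is never preferred over varying genes
  m2 <- rbind(rep(1, 8), matrix(rnorm(40), 5, 8))
  f2 <- select_feature_candidates(make_norm(m2), top_fraction = 0.5)
  expect_false(1L %in% f2$gene_indices)

  # ceiling rule: 3 genes at 0.34 keeps two, the top-variance pair
  m3 <- rbind(c(-2, 2, -2, 2), c(-1, 1, 1, -1) / 2, c(-3, 3, 3, -3))
  f3 <- select_feature_candidates(make_norm(m3), top_fraction = 0.34)
  expect_equal(sort(f3$gene_indices), c(1L, 3L))
})

test_that("sample_feature_subset draws uniform subsets of the right size", {
  f <- structure(list(gene_indices = 1:10, variances = rep(1, 10)),
                 class = "feature_gene_set")
  s <- sample_feature_subset(f, fraction = 0.7, seed = 1)
  expect_length(s, 7L)
  expect_true(all(s %in% 1:10))
  expect_equal(sort(sample_feature_subset(f, fraction = 1, seed = 2)), 1:10)

  # inclusion frequency of simple random sampling is the sampling fraction
  counts <- integer(10)
  set.seed(99)
  for (i in 1:10000) {
    s <- sample_feature_subset(f, fraction = 0.7)
    counts[s] <- counts[s] + 1L
  }
  expect_true(all(abs(counts / 10000 - 0.7) < 0.02))
})

test_that("embed_tsne returns per-cell 2-D coordinates deterministically", {
  tc <- two_clouds(n_per = 30, d = 5, sep = 50, seed = 4)
  y1 <- embed_tsne(tc$x, seed = 11)
  y2 <- embed_tsne(tc$x, seed = 11)
  expect_equal(dim(y1), c(60L, 2L))
  expect_identical(y1, y2)

  # far-separated clouds stay linearly separable: projecting onto the
  # difference of class centroids splits the classes with a clean margin
  mu1 <- colMeans(y1[tc$labels == 1, ])
  mu2 <- colMeans(y1[tc$labels == 2, ])
  proj <- y1 %*% (mu2 - mu1)
  expect_gt(min(proj[tc$labels == 2]), max(proj[tc$labels == 1]))

  expect_error(embed_tsne(matrix(rnorm(6), 3, 2)), "at least 4 cells")
})

test_that("coassociation_from_labels is the shared-label indicator", {
  expect_equal(coassociation_from_labels(c(0, 0, 1)),
               matrix(c(1L, 1L, 0L, 1L, 1L, 0L, 0L, 0L, 1L), 3, 3))
  expect_equal(coassociation_from_labels(rep("a", 4)), matrix(1L, 4, 4))

  # counting identity: total entries = sum of squared cluster sizes;
  # plus symmetry, unit diagonal, and transitivity (equivalence relation)
  set.seed(8)
  for (rep in 1:20) {
    lab <- sample(1:4, 25, replace = TRUE)
    cm <- coassociation_from_labels(lab)
    expect_equal(sum(cm), sum(table(lab)^2))
    expect_identical(cm, t(cm))
    expect_equal(diag(cm), rep(1L, 25))
    expect_identical((cm %*% cm > 0) * 1L, cm)
  }
})

test_that("ensemble similarity satisfies its structural invariants", {
  ds <- small_dataset(seed = 5)
  xn <- normalize_expression(ds$counts)
  L <- 4L
  a <- build_ensemble_similarity(xn, L = L, seed = 21)

  expect_s3_class(a, "ensemble_similarity")
  expect_identical(a$values, t(a$values))
  expect_true(all(a$values == round(a$values)))
  expect_true(all(a$values >= 0 & a$values <= 2 * L))
  expect_equal(diag(a$values), rep(2L * L, ncol(xn$values)))

  # planted structure: same-type cells co-cluster more than different-type
  same <- outer(ds$true_labels, ds$true_labels, "==")
  diag(same) <- NA
  expect_gt(mean(a$values[which(same)]), mean(a$values[which(!same)]))
})

test_that("ensemble similarity is reproducible from the master seed", {
  ds <- small_dataset(seed = 6)
  xn <- normalize_expression(ds$counts)
  a1 <- build_ensemble_similarity(xn, L = 2, seed = 33)
  a2 <- build_ensemble_similarity(xn, L = 2, seed = 33)
  a3 <- build_ensemble_similarity(xn, L = 2, seed = 34)
  expect_identical(a1$values, a2$values)
  expect_false(identical(a1$values, a3$values))
})

test_that("similarity serializes as MTX and edge list", {
  ds <- small_dataset(seed = 7, n_cells = 30, n_genes = 200)
  xn <- normalize_expression(ds$counts)
  a <- build_ensemble_similarity(xn, L = 2, seed = 1)

  dir <- withr::local_tempdir()
  write_similarity(a, file.path(dir, "sim.mtx"), format = "mtx")
  back <- as.matrix(Matrix::readMM(file.path(dir, "sim.mtx")))
  expect_equal(unname(back), unname(a$values))
  expect_equal(readLines(file.path(dir, "cells.tsv")), a$cell_ids)

  write_similarity(a, file.path(dir, "sim.tsv"), format = "edgelist")
  el <- read.delim(file.path(dir, "sim.tsv"))
  expect_named(el, c("cell_i", "cell_j", "weight"))
  # edge list stores the nonzero upper triangle once
  ut <- a$values[upper.tri(a$values, diag = TRUE)]
  expect_equal(sum(el$weight), sum(ut[ut != 0]))
})
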