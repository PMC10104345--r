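#' Select high-variance feature-gene candidates
#'
#' Ranks genes by their expression variance across cells on the normalized
#' (log) scale and keeps the top fraction. High-variance genes are the ones
#' most likely to discriminate cell types (marker-like behaviour), so they
#' form the candidate pool from which each ensemble round samples.
#'
#' @param xn A `normalized_matrix` from [normalize_expression()].
#' @param top_fraction Fraction of genes to keep; the candidate set has
#'   `ceiling(top_fraction * n_genes)` members (ceiling so tiny matrices keep
#'   at least one gene). Default 0.05.
#' @return A list of class `feature_gene_set` with `gene_indices` (row indices
#'   into `xn$values`, variance-descending) and `variances` (all gene
#'   variances, in input gene order).
#' @export
select_feature_candidates <- function(xn, top_fraction = 0.05) {
  stopifnot(inherits(xn, "normalized_matrix"))
  assert_that(top_fraction > 0 && top_fraction <= 1,
              "top_fraction must lie in (0, 1]")
  m <- xn$values
  assert_that(nrow(m) >= 1L && ncol(m) >= 1L, "empty matrix")
  mu <- rowMeans(m)
  # population variance; the ranking is invariant to the denominator choice
  v <- rowMeans(m * m) - mu * mu
  n_keep <- max(1L, as.integer(ceiling(top_fraction * nrow(m))))
  # stable: ties broken by gene index
  ord <- order(-v, seq_along(v))
  structure(list(gene_indices = ord[seq_len(n_keep)], variances = v),
            class = "feature_gene_set")
}

#' Sample a random subset of feature genes
#'
#' Draws a simple random sample (without replacement) from the feature-gene
#' candidate pool; each ensemble round uses a different subset to diversify
#' the similarity measurements.
#'
#' @param f A `feature_gene_set`.
#' @param fraction Fraction of candidates to draw; subset size is
#'   `round(fraction * |F|)`, at least 1. Default 0.7.
#' @param seed Optional integer seed for reproducibility.
#' @return Integer vector of gene row indices.
#' @export
sample_feature_subset <- function(f, fraction = 0.7, seed = NULL) {
  stopifnot(inherits(f, "feature_gene_set"))
  assert_that(fraction > 0 && fraction <= 1, "fraction must lie in (0, 1]")
  n <- length(f$gene_indices)
  size <- max(1L, as.integer(round(fraction * n)))
  with_seed(seed, sort(sample(f$gene_indices, size = size, replace = FALSE)))
}

#' Embed cells in two dimensions with t-SNE
#'
#' Runs Barnes-Hut t-SNE on cells (points) described by the supplied feature
#' columns, producing one 2-D coordinate pair per cell. The perplexity is
#' lowered automatically when there are too few cells for the requested value
#' (t-SNE requires `3 * perplexity < N - 1`).
#'
#' @param x Numeric matrix, cells in rows, features in columns.
#' @param perplexity Target perplexity (default 30, auto-reduced).
#' @param seed Optional integer seed; fixed seeds give identical embeddings.
#' @param max_iter t-SNE gradient-descent iterations (default 500).
#' @return An N x 2 coordinate matrix.
#' @export
embed_tsne <- function(x, perplexity = 30, seed = NULL, max_iter = 500) {
  x <- as.matrix(x)
  n <- nrow(x)
  assert_that(n >= 4L, "t-SNE needs at least 4 cells")
  perp <- min(perplexity, floor((n - 1) / 3))
  if (perp < 1) {
    stop_validation("too few cells (", n, ") for any usable perplexity; ",
                    "lower the perplexity or supply more cells")
  }
  out <- with_seed(seed, Rtsne::Rtsne(
    x, dims = 2L, perplexity = perp, max_iter = max_iter,
    check_duplicates = FALSE, pca = FALSE, verbose = FALSE
  ))
  out$Y
}

#' Co-association matrix of a clustering
#'
#' Converts a label vector into the binary cell x cell indicator of shared
#' cluster membership: entry (i, j) is 1 exactly when cells i and j carry the
#' same label. The result is a symmetric equivalence-relation indicator with
#' unit diagonal.
#'
#' @param labels Vector of cluster labels, one per cell.
#' @return N x N binary integer matrix.
#' @export
coassociation_from_labels <- function(labels) {
  assert_that(length(labels) >= 1L && !anyNA(labels),
              "labels must be non-empty and free of NA")
  g <- as.integer(factor(labels))
  ind <- outer(g, g, "==")
  storage.mode(ind) <- "integer"
  ind
}

#' Build the ensemble cell-to-cell similarity matrix
#'
#' The core similarity-learning loop: for each of `L` rounds, a random 70%
#' subset of the high-variance feature-gene candidates is drawn, cells are
#' embedded in 2-D with t-SNE on that subset, and both k-means and Ward
#' hierarchical clustering partition the embedding into `k_sub` groups. Each
#' partition contributes a binary co-association matrix; their sum over all
#' rounds is the ensemble similarity `A`, an integer matrix in `[0, 2L]`
#' whose entries count how often two cells were grouped together. `A` doubles
#' as the weighted adjacency matrix of the cell-similarity graph consumed by
#' the graph autoencoder.
#'
#' @param xn A `normalized_matrix`.
#' @param L Number of ensemble rounds (default 20).
#' @param k_sub Number of clusters per similarity measurement (default 30;
#'   deliberately larger than the expected number of cell types so each group
#'   is highly homogeneous). Clamped to `max(2, N - 1)` when N is small.
#' @param top_fraction Feature-candidate fraction passed to
#'   [select_feature_candidates()].
#' @param subset_fraction Per-round sampling fraction passed to
#'   [sample_feature_subset()].
#' @param perplexity t-SNE perplexity (auto-reduced for small N).
#' @param tsne_iter t-SNE iterations per round.
#' @param seed Master seed; per-round substreams are derived from it so the
#'   whole ensemble is reproducible.
#' @return A list of class `ensemble_similarity` with `values` (N x N integer
#'   matrix), `L`, and `cell_ids`.
#' @export
build_ensemble_similarity <- function(xn, L = 20, k_sub = 30,
                                      top_fraction = 0.05,
                                      subset_fraction = 0.7,
                                      perplexity = 30,
                                      tsne_iter = 500,
                                      seed = NULL) {
  stopifnot(inherits(xn, "normalized_matrix"))
  assert_that(L >= 1, "L must be at least 1")
  assert_that(k_sub >= 2, "k_sub must be at least 2")
  n <- ncol(xn$values)
  assert_that(n >= 4L, "need at least 4 cells")
  k_eff <- min(k_sub, max(2L, n - 1L))

  f <- select_feature_candidates(xn, top_fraction = top_fraction)
  acc <- matrix(0L, n, n)
  for (l in seq_len(L)) {
    sub <- sample_feature_subset(f, fraction = subset_fraction,
                                 seed = derive_seed(seed, "subset", l))
    emb <- embed_tsne(t(xn$values[sub, , drop = FALSE]),
                      perplexity = perplexity,
                      seed = derive_seed(seed, "tsne", l),
                      max_iter = tsne_iter)
    km <- with_seed(derive_seed(seed, "kmeans", l),
                    stats::kmeans(emb, centers = k_eff, nstart = 10L,
                                  iter.max = 50L))
    hc <- stats::hclust(stats::dist(emb), method = "ward.D2")
    hl <- stats::cutree(hc, k = k_eff)
    acc <- acc + coassociation_from_labels(km$cluster) +
      coassociation_from_labels(hl)
  }
  structure(list(values = acc, L = as.integer(L), cell_ids = xn$cell_ids),
            class = "ensemble_similarity")
}

#' @export
print.ensemble_similarity <- function(x, ...) {
  cat(sprintf("ensemble_similarity: %d cells, L = %d (entries in [0, %d])\n",
              nrow(x$values), x$L, 2L * x$L))
  invisible(x)
}

#' Write an ensemble similarity matrix to disk
#'
#' Serializes the similarity either as a sparse symmetric MatrixMarket file
#' with a cell-id sidecar (`cells.tsv`), or as a three-column edge list
#' (`cell_i`, `cell_j`, `weight`) over nonzero upper-triangle entries.
#'
#' @param a An `ensemble_similarity`.
#' @param path Output path (`.mtx` or `.tsv`).
#' @param format `"mtx"` or `"edgelist"`.
#' @return `path`, invisibly.
#' @export
write_similarity <- function(a, path, format = c("mtx", "edgelist")) {
  stopifnot(inherits(a, "ensemble_similarity"))
  format <- match.arg(format)
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(a$values, sparse = TRUE), path)
    utils::write.table(data.frame(cell = a$cell_ids),
                       file.path(dirname(path), "cells.tsv"),
                       sep = "\t", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  } else {
    idx <- which(upper.tri(a$values, diag = TRUE) & a$values != 0,
                 arr.ind = TRUE)
    el <- data.frame(cell_i = a$cell_ids[idx[, 1L]],
                     cell_j = a$cell_ids[idx[, 2L]],
                     weight = a$values[idx])
    utils::write.table(el, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
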