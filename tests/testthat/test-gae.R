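test_that("normalize_adjacency matches hand computations and round-trips", {
  a_id <- structure(list(values = diag(3), L = 1L, cell_ids = letters[1:3]),
                    class = "ensemble_similarity")
  expect_equal(normalize_adjacency(a_id)$values, diag(3))

  expect_equal(normalize_adjacency(matrix(2, 2, 2))$values,
               matrix(0.5, 2, 2))

  # D^(1/2) A_tilde D^(1/2) recovers A
  tb <- two_block_similarity(n = 40, L = 5, seed = 2)
  adj <- normalize_adjacency(tb$a)
  d_half <- sqrt(adj$degree)
  rec <- adj$values * tcrossprod(d_half)
  expect_equal(rec, tb$a$values, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(adj$values, t(adj$values), tolerance = 1e-12)

  expect_error(normalize_adjacency(matrix(c(1, 0, 0, 0), 2, 2)),
               "zero-degree")
})

test_that("compute_node_features returns ordered principal components", {
  ds <- small_dataset(seed = 9, n_cells = 60, n_genes = 150)
  xn <- normalize_expression(ds$counts)
  pcs <- compute_node_features(xn, n_components = 10)
  expect_equal(dim(pcs), c(60L, 10L))
  vars <- apply(pcs, 2, var)
  expect_true(all(diff(vars) <= 1e-10))

  # data confined to a 3-D subspace: components beyond 3 carry no variance
  set.seed(10)
  basis <- matrix(rnorm(50 * 3), 50, 3)
  coords <- matrix(rnorm(3 * 30), 3, 30)
  xn_low <- structure(list(values = basis %*% coords + 5,
                           gene_ids = paste0("g", 1:50),
                           cell_ids = paste0("c", 1:30),
                           library_target = 1e6),
                      class = "normalized_matrix")
  pcs_low <- compute_node_features(xn_low, n_components = 10)
  v <- apply(pcs_low, 2, var)
  expect_lt(sum(v[4:10]), 1e-8 * sum(v))

  # PC1 variance equals the top covariance eigenvalue
  ev <- eigen(cov(t(xn$values)), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(var(pcs[, 1]), ev[1], tolerance = 1e-6)

  expect_error(compute_node_features(xn, n_components = 60), "more cells")
})

test_that("gcn_encode computes the two-layer propagation exactly", {
  tb <- two_block_similarity(n = 5, L = 3, seed = 3)
  adj <- normalize_adjacency(tb$a)
  set.seed(11)
  x <- matrix(rnorm(5 * 10), 5, 10)
  w0 <- matrix(rnorm(10 * 32, sd = 0.3), 10, 32)
  w1 <- matrix(rnorm(32 * 16, sd = 0.3), 32, 16)

  z <- gcn_encode(x, adj, w0, w1)
  expect_equal(z, oracle_gcn_forward(x, adj$values, w0, w1),
               tolerance = 1e-10, ignore_attr = TRUE)

  expect_equal(gcn_encode(x, adj, matrix(0, 10, 32), w1),
               matrix(0, 5, 16), ignore_attr = TRUE)
  expect_error(gcn_encode(x, adj, matrix(0, 9, 32), w1), "dimension")
})

test_that("decode_adjacency is a symmetric sigmoid inner product", {
  expect_equal(decode_adjacency(matrix(0, 4, 3)), matrix(0.5, 4, 4))
  set.seed(12)
  z <- matrix(rnorm(12), 4, 3)
  p <- decode_adjacency(z)
  expect_equal(p, t(p))
  expect_true(all(p > 0 & p < 1))
  expect_equal(p[1, 2], 1 / (1 + exp(-sum(z[1, ] * z[2, ]))))
  # scaling pushes positive-inner-product pairs toward 1
  p_big <- decode_adjacency(100 * z)
  expect_true(all(p_big[p > 0.5 & row(p) != col(p)] > 0.999))
})

test_that("train_gae reduces the loss and is seed-reproducible", {
  tb <- two_block_similarity(n = 60, L = 10, seed = 5)
  set.seed(13)
  feats <- cbind(tb$truth + rnorm(60, sd = 0.3),
                 matrix(rnorm(60 * 9, sd = 0.5), 60, 9))

  z1 <- train_gae(tb$a, feats, epochs = 50, seed = 17)
  expect_length(z1$loss_history, 50L)
  expect_lt(z1$loss_history[50], z1$loss_history[1])
  expect_equal(dim(z1$values), c(60L, 16L))
  expect_true(all(is.finite(z1$values)))

  z2 <- train_gae(tb$a, feats, epochs = 50, seed = 17)
  expect_identical(z1$loss_history, z2$loss_history)
  expect_identical(z1$values, z2$values)
})

test_that("encoder is equivariant to a permutation of the cells", {
  tb <- two_block_similarity(n = 30, L = 5, seed = 6)
  adj <- normalize_adjacency(tb$a)
  set.seed(14)
  x <- matrix(rnorm(30 * 10), 30, 10)
  w0 <- matrix(rnorm(10 * 32, sd = 0.3), 10, 32)
  w1 <- matrix(rnorm(32 * 16, sd = 0.3), 32, 16)
  z <- gcn_encode(x, adj, w0, w1)

  p <- sample(30)
  adj_p <- structure(list(values = adj$values[p, p], degree = adj$degree[p]),
                     class = "normalized_adjacency")
  z_p <- gcn_encode(x[p, ], adj_p, w0, w1)
  expect_equal(z_p, z[p, ], tolerance = 1e-12)
})

test_that("embedding separates a planted two-block partition", {
  tb <- two_block_similarity(n = 80, L = 10, seed = 7)
  set.seed(15)
  feats <- matrix(rnorm(80 * 10), 80, 10)
  z <- train_gae(tb$a, feats, epochs = 100, seed = 23)
  ip <- tcrossprod(z$values)
  same <- outer(tb$truth, tb$truth, "==")
  diag(same) <- NA
  expect_gt(mean(ip[which(same)]), mean(ip[which(!same)]))
})
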