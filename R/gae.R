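#' Symmetric adjacency normalization
#'
#' Computes the symmetrically normalized adjacency
#' `A_tilde = D^(-1/2) A D^(-1/2)` with `D = diag(rowSums(A))`, the
#' propagation operator of a graph convolutional layer. The ensemble
#' similarity matrix already carries a positive diagonal (every cell always
#' co-clusters with itself), so no extra self-loops are added.
#'
#' @param a An `ensemble_similarity` or a symmetric non-negative matrix with
#'   positive row sums.
#' @return A list of class `normalized_adjacency` with `values` (the
#'   normalized matrix) and `degree` (the row-sum vector of `A`).
#' @export
normalize_adjacency <- function(a) {
  m <- if (inherits(a, "ensemble_similarity")) a$values else as.matrix(a)
  deg <- rowSums(m)
  if (any(deg <= 0)) {
    stop_validation("adjacency has zero-degree node(s): ",
                    paste(which(deg <= 0), collapse = ", "))
  }
  dinv <- 1 / sqrt(deg)
  at <- m * tcrossprod(dinv)   # D^{-1/2} A D^{-1/2}, elementwise outer form
  structure(list(values = at, degree = deg), class = "normalized_adjacency")
}

#' Node features: leading principal components of cells
#'
#' Projects cells onto the first `n_components` principal components of the
#' normalized expression matrix (cells as observations, genes as variables,
#' mean-centered, unscaled). These scores are the feature input of the GCN
#' encoder. Component signs are fixed so the largest-magnitude loading of
#' each component is positive, making the output deterministic.
#'
#' @param xn A `normalized_matrix`.
#' @param n_components Number of components (default 10).
#' @return N x `n_components` score matrix with cells in rows.
#' @export
compute_node_features <- function(xn, n_components = 10) {
  stopifnot(inherits(xn, "normalized_matrix"))
  n <- ncol(xn$values)
  assert_that(n > n_components,
              "need more cells (", n, ") than components (", n_components, ")")
  pc <- stats::prcomp(t(xn$values), center = TRUE, scale. = FALSE,
                      rank. = n_components)
  flip <- apply(pc$rotation, 2L, function(w) sign(w[which.max(abs(w))]))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x[, seq_len(n_components), drop = FALSE], 2L, flip, "*")
  rownames(scores) <- xn$cell_ids
  scores
}

relu <- function(x) (x > 0) * x

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Two-layer GCN encoder forward pass
#'
#' Computes the node embedding
#' `Z = A_tilde %*% ReLU(A_tilde %*% X %*% W0) %*% W1`
#' exactly as written: two graph-convolution layers, ReLU after the first,
#' linear second layer, no bias terms.
#'
#' @param features N x d0 node-feature matrix.
#' @param adj A `normalized_adjacency`.
#' @param w0 d0 x d1 first-layer weights.
#' @param w1 d1 x d2 second-layer weights.
#' @return N x d2 embedding matrix.
#' @export
gcn_encode <- function(features, adj, w0, w1) {
  stopifnot(inherits(adj, "normalized_adjacency"))
  at <- adj$values
  assert_that(ncol(features) == nrow(w0) && ncol(w0) == nrow(w1),
              "dimension mismatch in GCN weight chain")
  assert_that(nrow(features) == nrow(at),
              "feature rows must match adjacency size")
  at %*% relu(at %*% features %*% w0) %*% w1
}

#' Inner-product decoder
#'
#' Reconstructs edge probabilities from an embedding via
#' `A_hat[i, j] = sigmoid(<z_i, z_j>)`; symmetric with entries in (0, 1).
#'
#' @param z N x d embedding matrix.
#' @return N x N reconstructed adjacency.
#' @export
decode_adjacency <- function(z) {
  sigmoid(tcrossprod(as.matrix(z)))
}

# Glorot/Xavier uniform initialization: U(+-sqrt(6 / (fan_in + fan_out))).
glorot_init <- function(fan_in, fan_out) {
  r <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -r, r), fan_in, fan_out)
}

#' Train the graph autoencoder
#'
#' Learns the cell embedding by full-batch gradient optimization of a
#' reconstruction loss between the decoded adjacency `sigmoid(Z Z^T)` and the
#' ensemble similarity graph. The integer similarity `A` is rescaled to soft
#' targets `A / (2L)` in `[0, 1]` (preserving the ensemble's confidence
#' information) and compared element-wise by binary cross-entropy with the
#' positive class reweighted by `(N^2 - sum(targets)) / sum(targets)`, the
#' usual correction for edge sparsity; the whole matrix is used (no edge
#' masking or train/validation split). Optimization is Adam with the given
#' learning rate; weights start from variance-scaled (Glorot) uniform
#' initialization.
#'
#' @param a An `ensemble_similarity`.
#' @param features N x d0 node-feature matrix from [compute_node_features()].
#' @param epochs Number of full-batch epochs (default 200).
#' @param learning_rate Adam step size (default 0.01).
#' @param hidden_dims Integer vector of the two layer widths (default
#'   `c(32, 16)`; the second is the embedding dimension).
#' @param binarize_threshold Optional threshold in (0, 1]; when set, targets
#'   become the strict binary `A >= threshold * 2L` instead of soft values.
#' @param seed Seed for weight initialization.
#' @return A list of class `cell_embedding` with `values` (N x d embedding),
#'   `loss_history` (one value per epoch), `w0`, `w1`, and `config`.
#' @export
train_gae <- function(a, features, epochs = 200, learning_rate = 0.01,
                      hidden_dims = c(32, 16), binarize_threshold = NULL,
                      seed = NULL) {
  stopifnot(inherits(a, "ensemble_similarity"))
  assert_that(epochs >= 1, "epochs must be at least 1")
  assert_that(length(hidden_dims) == 2L, "hidden_dims must give two widths")
  x <- as.matrix(features)
  n <- nrow(x)
  assert_that(n == nrow(a$values), "features and similarity disagree on N")

  adj <- normalize_adjacency(a)
  at <- adj$values
  targets <- a$values / (2 * a$L)
  if (!is.null(binarize_threshold)) {
    targets <- (a$values >= binarize_threshold * 2 * a$L) * 1
  }
  pos_sum <- sum(targets)
  pos_weight <- (n * n - pos_sum) / pos_sum

  d0 <- ncol(x)
  w0 <- with_seed(seed, glorot_init(d0, hidden_dims[1L]))
  w1 <- with_seed(if (is.null(seed)) NULL else derive_seed(seed, "w1"),
                  glorot_init(hidden_dims[1L], hidden_dims[2L]))

  # Adam state
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  m0 <- v0 <- matrix(0, nrow(w0), ncol(w0))
  m1 <- v1 <- matrix(0, nrow(w1), ncol(w1))

  ax <- at %*% x
  loss_history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    u <- ax %*% w0        # pre-activation, layer 1
    h <- relu(u)
    ah <- at %*% h
    z <- ah %*% w1
    s <- tcrossprod(z)
    p <- sigmoid(s)

    # cross-entropy with logits: pw*t*softplus(-s) + (1-t)*softplus(s)
    sp_pos <- pmax(s, 0) + log1p(exp(-abs(s)))   # softplus(s)
    loss <- mean(pos_weight * targets * (sp_pos - s) +
                   (1 - targets) * sp_pos)
    if (!is.finite(loss)) {
      stop("non-finite reconstruction loss at epoch ", ep)
    }
    loss_history[ep] <- loss

    # gradient wrt logits s, then backprop through decoder and both layers
    g <- (pos_weight * targets * (p - 1) + (1 - targets) * p) / (n * n)
    dz <- (g + t(g)) %*% z
    d_ah <- dz %*% t(w1)
    g_w1 <- crossprod(ah, dz)
    du <- (at %*% d_ah) * (u > 0)
    g_w0 <- crossprod(ax, du)

    # Adam update
    m0 <- b1 * m0 + (1 - b1) * g_w0; v0 <- b2 * v0 + (1 - b2) * g_w0^2
    m1 <- b1 * m1 + (1 - b1) * g_w1; v1 <- b2 * v1 + (1 - b2) * g_w1^2
    c1 <- 1 - b1^ep; c2 <- 1 - b2^ep
    w0 <- w0 - learning_rate * (m0 / c1) / (sqrt(v0 / c2) + eps)
    w1 <- w1 - learning_rate * (m1 / c1) / (sqrt(v1 / c2) + eps)
  }

  z <- gcn_encode(x, adj, w0, w1)
  rownames(z) <- a$cell_ids
  structure(list(values = z, loss_history = loss_history, w0 = w0, w1 = w1,
                 config = list(epochs = epochs, learning_rate = learning_rate,
                               hidden_dims = hidden_dims,
                               binarize_threshold = binarize_threshold,
                               seed = seed)),
            class = "cell_embedding")
}

#' @export
print.cell_embedding <- function(x, ...) {
  cat(sprintf("cell_embedding: %d cells x %d dimensions (final loss %.4g)\n",
              nrow(x$values), ncol(x$values),
              x$loss_history[length(x$loss_history)]))
  invisible(x)
}

#' Write an embedding to TSV
#'
#' @param z A `cell_embedding`.
#' @param path Output TSV path (cell_id column plus one column per dimension).
#' @return `path`, invisibly.
#' @export
write_embedding <- function(z, path) {
  stopifnot(inherits(z, "cell_embedding"))
  df <- data.frame(cell_id = rownames(z$values), z$values,
                   check.names = FALSE)
  colnames(df) <- c("cell_id", paste0("dim", seq_len(ncol(z$values))))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
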