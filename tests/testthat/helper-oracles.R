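## Independent brute-force oracles used to validate the package's metric and
## encoder implementations. These deliberately share no code with R/.

# Rand-family statistics by explicit enumeration of all unordered pairs.
oracle_pair_counts <- function(truth, predicted) {
  n <- length(truth)
  tp <- fp <- fn <- tn <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same_t <- truth[i] == truth[j]
      same_p <- predicted[i] == predicted[j]
      if (same_t && same_p) tp <- tp + 1
      else if (!same_t && same_p) fp <- fp + 1
      else if (same_t && !same_p) fn <- fn + 1
      else tn <- tn + 1
    }
  }
  list(TP = tp, FP = fp, FN = fn, TN = tn)
}

oracle_ari <- function(truth, predicted) {
  pc <- oracle_pair_counts(truth, predicted)
  n_pairs <- with(pc, TP + FP + FN + TN)
  # expected-index-corrected Rand from the pair counts
  sum_a <- pc$TP + pc$FN
  sum_b <- pc$TP + pc$FP
  expected <- sum_a * sum_b / n_pairs
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (pc$TP - expected) / (max_idx - expected)
}

oracle_jaccard <- function(truth, predicted) {
  pc <- oracle_pair_counts(truth, predicted)
  denom <- pc$TP + pc$FP + pc$FN
  if (denom == 0) return(1)
  pc$TP / denom
}

oracle_nmi <- function(truth, predicted) {
  n <- length(truth)
  tl <- unique(truth); pl <- unique(predicted)
  joint <- outer(tl, pl, Vectorize(function(a, b) {
    sum(truth == a & predicted == b)
  })) / n
  pt <- rowSums(joint); pp <- colSums(joint)
  ent <- function(p) -sum(ifelse(p > 0, p * log(p), 0))
  mi <- 0
  for (i in seq_along(tl)) {
    for (j in seq_along(pl)) {
      if (joint[i, j] > 0) {
        mi <- mi + joint[i, j] * log(joint[i, j] / (pt[i] * pp[j]))
      }
    }
  }
  if (ent(pt) + ent(pp) == 0) return(1)
  2 * mi / (ent(pt) + ent(pp))
}

oracle_purity <- function(truth, predicted) {
  total <- 0
  for (cl in unique(predicted)) {
    members <- truth[predicted == cl]
    total <- total + max(table(members))
  }
  total / length(truth)
}

# Step-by-step GCN forward pass with explicit loops over entries.
oracle_gcn_forward <- function(x, a_tilde, w0, w1) {
  mm <- function(p, q) {
    out <- matrix(0, nrow(p), ncol(q))
    for (i in seq_len(nrow(p))) {
      for (j in seq_len(ncol(q))) {
        out[i, j] <- sum(p[i, ] * q[, j])
      }
    }
    out
  }
  h <- mm(a_tilde, mm(x, w0))
  h[h < 0] <- 0
  mm(a_tilde, mm(h, w1))
}

# Two far-separated isotropic Gaussian point clouds.
two_clouds <- function(n_per = 30, d = 5, sep = 50, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * d), n_per, d),
             matrix(rnorm(n_per * d) + sep, n_per, d))
  list(x = x, labels = rep(1:2, each = n_per))
}

# Small synthetic expression fixture for fast stage-level tests.
small_dataset <- function(seed = 1L, n_cells = 120, n_genes = 400,
                          n_types = 3) {
  generate_synthetic(synthetic_spec(
    n_cells = n_cells, n_genes = n_genes, n_types = n_types,
    type_proportions = rep(1 / n_types, n_types), seed = seed))
}

# A planted two-block ensemble similarity: L noisy repetitions of the true
# two-block partition, accumulated exactly like the ensemble stage does.
two_block_similarity <- function(n = 100, L = 20, flip_rate = 0.1, seed = 1) {
  set.seed(seed)
  truth <- rep(1:2, times = c(ceiling(n / 2), floor(n / 2)))
  acc <- matrix(0L, n, n)
  for (l in seq_len(2 * L)) {
    lab <- truth
    flip <- runif(n) < flip_rate
    lab[flip] <- 3 - lab[flip]
    acc <- acc + coassociation_from_labels(lab)
  }
  list(a = structure(list(values = acc, L = as.integer(L),
                          cell_ids = paste0("cell", seq_len(n))),
                     class = "ensemble_similarity"),
       truth = truth)
}
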