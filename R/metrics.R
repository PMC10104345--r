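## External clustering validation: partition-agreement metrics computed from
## the truth x prediction contingency table or from unordered cell pairs.

label_pair_table <- function(truth, predicted) {
  assert_that(length(truth) == length(predicted),
              "label vectors must have equal length")
  assert_that(length(truth) >= 2L, "need at least two cells")
  assert_that(!anyNA(truth) && !anyNA(predicted), "labels must not contain NA")
  table(factor(truth), factor(predicted))
}

choose2 <- function(n) n * (n - 1) / 2

# TP/FP/FN/TN over unordered cell pairs, from the contingency table:
# TP pairs co-clustered in both partitions, FP co-clustered only in the
# prediction, FN only in the truth.
pair_counts <- function(truth, predicted) {
  ct <- label_pair_table(truth, predicted)
  n <- sum(ct)
  tp <- sum(choose2(ct))
  fp <- sum(choose2(colSums(ct))) - tp
  fn <- sum(choose2(rowSums(ct))) - tp
  tn <- choose2(n) - tp - fp - fn
  list(TP = tp, FP = fp, FN = fn, TN = tn)
}

#' Adjusted Rand index
#'
#' Pair-counting agreement between two partitions, corrected for the
#' agreement expected under random labelings with the same cluster sizes:
#' `(sum_ij C(n_ij,2) - E) / (max - E)` with
#' `E = sum_i C(a_i,2) * sum_j C(b_j,2) / C(n,2)` and
#' `max = (sum_i C(a_i,2) + sum_j C(b_j,2)) / 2`,
#' where `n_ij` is the contingency table and `a_i`, `b_j` its margins.
#' Returns 1 for identical partitions (up to renaming), about 0 for
#' independent ones, and can be negative.
#'
#' @param truth,predicted Equal-length label vectors.
#' @return A number in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(truth, predicted) {
  ct <- label_pair_table(truth, predicted)
  n <- sum(ct)
  sum_ij <- sum(choose2(ct))
  sum_a <- sum(choose2(rowSums(ct)))
  sum_b <- sum(choose2(colSums(ct)))
  expected <- sum_a * sum_b / choose2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_idx - expected)
}

#' Normalized mutual information
#'
#' `2 I(Y; C) / (H(Y) + H(C))` with entropies and mutual information taken
#' from the empirical joint distribution of the two labelings (natural log;
#' the normalization makes the base irrelevant). Equals 1 for identical
#' partitions. When both partitions are single-cluster (both entropies zero)
#' the 0/0 case is defined as 1, since the partitions agree exactly.
#'
#' @param truth,predicted Equal-length label vectors.
#' @return A number in `[0, 1]`.
#' @export
normalized_mutual_information <- function(truth, predicted) {
  ct <- label_pair_table(truth, predicted)
  n <- sum(ct)
  p_joint <- ct / n
  p_t <- rowSums(p_joint)
  p_p <- colSums(p_joint)
  h_t <- -sum(p_t[p_t > 0] * log(p_t[p_t > 0]))
  h_p <- -sum(p_p[p_p > 0] * log(p_p[p_p > 0]))
  if (h_t + h_p == 0) return(1)
  expected <- outer(p_t, p_p)
  nz <- p_joint > 0
  mi <- sum(p_joint[nz] * log(p_joint[nz] / expected[nz]))
  2 * mi / (h_t + h_p)
}

#' Pairwise Jaccard index of two partitions
#'
#' `TP / (TP + FP + FN)` over unordered cell pairs, where TP pairs share a
#' cluster in both partitions, FP only in the prediction, and FN only in the
#' truth. When all three counts are zero (both partitions all singletons) the
#' index is defined as 1.
#'
#' @param truth,predicted Equal-length label vectors.
#' @return A number in `[0, 1]`.
#' @export
jaccard_index <- function(truth, predicted) {
  pc <- pair_counts(truth, predicted)
  denom <- pc$TP + pc$FP + pc$FN
  if (denom == 0) return(1)
  pc$TP / denom
}

#' Purity of a predicted partition
#'
#' For each predicted cluster, counts the cells belonging to its
#' best-matching true class, sums over clusters, and divides by N. High
#' purity means clusters are internally homogeneous; note the size bias —
#' an all-singleton prediction trivially scores 1.
#'
#' @param truth,predicted Equal-length label vectors.
#' @return A number in `(0, 1]`.
#' @export
purity <- function(truth, predicted) {
  ct <- label_pair_table(truth, predicted)
  sum(apply(ct, 2L, max)) / sum(ct)
}

#' Average cluster-number estimation error
#'
#' Summarizes how far estimated cluster counts fall from the truth over
#' several datasets and repeated trials. Two variants are reported: the
#' per-dataset sum of absolute errors averaged over datasets,
#' `1/N * sum_n sum_i |K_n - x_{n,i}|`, and the fully averaged per-trial
#' error `1/(N L) * sum_n sum_i |K_n - x_{n,i}|`.
#'
#' @param true_k Integer vector, the true cluster count per dataset.
#' @param estimated_k List (one element per dataset) of integer vectors of
#'   per-trial estimates, or a single vector when there is one dataset.
#' @return A list with `total_per_dataset` (the 1/N variant) and `per_trial`
#'   (the 1/(N L) variant).
#' @export
avg_cluster_number_error <- function(true_k, estimated_k) {
  if (!is.list(estimated_k)) estimated_k <- list(estimated_k)
  assert_that(length(true_k) == length(estimated_k),
              "one vector of estimates per dataset is required")
  assert_that(length(true_k) >= 1L, "empty input")
  n_trials <- lengths(estimated_k)
  assert_that(all(n_trials >= 1L), "every dataset needs at least one trial")
  abs_err <- mapply(function(k, est) sum(abs(k - est)), true_k, estimated_k)
  list(total_per_dataset = sum(abs_err) / length(true_k),
       per_trial = sum(abs_err) / sum(n_trials))
}

#' All four external validation metrics at once
#'
#' @param truth,predicted Equal-length label vectors.
#' @return Named list with `ari`, `nmi`, `jcci`, `purity`.
#' @export
evaluate_clustering <- function(truth, predicted) {
  list(ari = adjusted_rand_index(truth, predicted),
       nmi = normalized_mutual_information(truth, predicted),
       jcci = jaccard_index(truth, predicted),
       purity = purity(truth, predicted))
}
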