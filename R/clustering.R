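#' Estimate the number of clusters with the elbow method
#'
#' Runs k-means for every k in `[k_min, k_max]` on the embedding, records the
#' within-cluster sum of squares (inertia), and returns the elbow of the
#' curve: both axes are rescaled to `[0, 1]` and the k maximizing the second
#' forward difference of the rescaled curve (the point of sharpest bend) is
#' chosen. A distance-to-chord variant (the largest vertical gap between the
#' rescaled curve and the straight line joining its endpoints) is available
#' via `method = "chord"`.
#'
#' @param z A `cell_embedding` or a numeric matrix (cells in rows).
#' @param k_min,k_max Search range (defaults 2 and 30); `k_max` must be
#'   below the number of cells (the pipeline caps its configured range at
#'   N - 1 before calling).
#' @param method Elbow rule: `"second_diff"` (default) or `"chord"`.
#' @param nstart k-means restarts per k (default 10).
#' @param seed Seed shared across the k sweep.
#' @return A list with `k` (the estimate) and `inertia_curve` (data frame of
#'   k and within-cluster sum of squares).
#' @export
estimate_num_clusters <- function(z, k_min = 2, k_max = 30,
                                  method = c("second_diff", "chord"),
                                  nstart = 10, seed = NULL) {
  method <- match.arg(method)
  m <- if (inherits(z, "cell_embedding")) z$values else as.matrix(z)
  n <- nrow(m)
  assert_that(k_min >= 2, "k_min must be at least 2")
  assert_that(k_max < n, "k_max (", k_max, ") must be below the number of cells")
  assert_that(k_max >= k_min, "k_max must be >= k_min")
  ks <- seq.int(k_min, k_max)
  wss <- vapply(seq_along(ks), function(i) {
    km <- with_seed(if (is.null(seed)) NULL else derive_seed(seed, "elbow", i),
                    stats::kmeans(m, centers = ks[i], nstart = nstart,
                                  iter.max = 50L))
    km$tot.withinss
  }, numeric(1))
  # enforce monotonicity against restart noise: the k-means objective is
  # non-increasing in k for the best partition, so take the running minimum
  wss_mono <- cummin(wss)
  curve <- data.frame(k = ks, wss = wss)

  if (length(ks) == 1L) {
    return(list(k = ks, inertia_curve = curve))
  }
  xs <- (ks - ks[1L]) / (ks[length(ks)] - ks[1L])
  rng <- max(wss_mono) - min(wss_mono)
  ys <- if (rng > 0) (wss_mono - min(wss_mono)) / rng else rep(0, length(ks))
  k_hat <- if (method == "second_diff") {
    if (length(ks) < 3L) {
      ks[1L]
    } else {
      d2 <- ys[1:(length(ys) - 2L)] - 2 * ys[2:(length(ys) - 1L)] +
        ys[3:length(ys)]
      ks[which.max(d2) + 1L]
    }
  } else {
    chord <- ys[1L] + (ys[length(ys)] - ys[1L]) * xs
    ks[which.max(chord - ys)]
  }
  list(k = k_hat, inertia_curve = curve)
}

#' Final cluster labels by k-means on the embedding
#'
#' Partitions cells into `k` clusters with k-means (10 restarts, best
#' objective kept). Labels are renumbered 1..k in order of first appearance
#' along the cell ordering so identical partitions always print identically.
#'
#' @param z A `cell_embedding` or numeric matrix (cells in rows).
#' @param k Number of clusters, `2 <= k < N`.
#' @param nstart k-means restarts (default 10).
#' @param seed Seed for the k-means initializations.
#' @return A list of class `clustering_result` with `labels` (integer vector,
#'   values 1..k), `k_used`, `k_estimated` (NA here; filled by the pipeline),
#'   `inertia` (best within-cluster sum of squares), `cell_ids`, and `seed`.
#' @export
final_labels <- function(z, k, nstart = 10, seed = NULL) {
  m <- if (inherits(z, "cell_embedding")) z$values else as.matrix(z)
  n <- nrow(m)
  assert_that(k >= 2 && k < n, "k must satisfy 2 <= k < N")
  km <- with_seed(seed, stats::kmeans(m, centers = k, nstart = nstart,
                                      iter.max = 50L))
  raw <- km$cluster
  # stable relabeling: cluster names ordered by first appearance
  lab <- match(raw, unique(raw))
  structure(list(labels = as.integer(lab),
                 k_used = as.integer(k),
                 k_estimated = NA_integer_,
                 inertia = km$tot.withinss,
                 cell_ids = rownames(m),
                 seed = seed),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("clustering_result: %d cells in %d clusters (k estimated: %s)\n",
              length(x$labels), x$k_used,
              ifelse(is.na(x$k_estimated), "-", x$k_estimated)))
  invisible(x)
}

#' Write cluster labels to TSV
#'
#' @param cl A `clustering_result`.
#' @param path Output path for a two-column (cell_id, cluster) TSV.
#' @return `path`, invisibly.
#' @export
write_labels <- function(cl, path) {
  stopifnot(inherits(cl, "clustering_result"))
  ids <- cl$cell_ids
  if (is.null(ids)) ids <- paste0("cell", seq_along(cl$labels))
  utils::write.table(data.frame(cell_id = ids, cluster = cl$labels),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
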