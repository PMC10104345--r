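#' Synthetic single-cell dataset specification
#'
#' Parameters of the negative-binomial count simulator with planted cell
#' types. Defaults emulate a mid-sized droplet experiment: a few thousand
#' genes, hundreds of cells, a handful of cell types of unequal sizes,
#' marker-gene structure, overdispersed counts, and excess zeros.
#'
#' @param n_cells Number of cells (default 500).
#' @param n_genes Number of genes (default 2000).
#' @param n_types Number of planted cell types (default 4).
#' @param type_proportions Simplex vector of type frequencies (default
#'   `c(0.4, 0.3, 0.2, 0.1)`, echoing the unequal populations of real
#'   tissues).
#' @param marker_frac Fraction of genes elevated as markers per type
#'   (default 0.05; distinct cell types differ in hundreds of genes).
#' @param marker_fold Multiplicative mean shift for a type's marker genes
#'   (default 8; 1 means no type signal at all).
#' @param dispersion Negative-binomial size parameter; smaller is more
#'   overdispersed (default 2, typical of UMI count data).
#' @param dropout_rate Extra probability of forcing an observed count to
#'   zero (default 0.1), weighted toward low-mean genes when
#'   `dropout_shape > 0`.
#' @param dropout_shape Exponential decay rate of dropout with log-mean
#'   expression; 0 gives uniform dropout (default 1).
#' @param mean_log_mu,sd_log_mu Log-normal baseline for gene mean expression
#'   (defaults -1 and 1.5, a heavy-tailed mean distribution).
#' @param seed Integer seed making the draw fully reproducible.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_cells = 500, n_genes = 2000, n_types = 4,
                           type_proportions = c(0.4, 0.3, 0.2, 0.1),
                           marker_frac = 0.05, marker_fold = 8,
                           dispersion = 2, dropout_rate = 0.1,
                           dropout_shape = 1,
                           mean_log_mu = -1, sd_log_mu = 1.5,
                           seed = 1L) {
  assert_that(n_cells >= n_types, "need at least one cell per type")
  assert_that(abs(sum(type_proportions) - 1) < 1e-8,
              "type_proportions must sum to 1")
  assert_that(length(type_proportions) == n_types,
              "type_proportions length must equal n_types")
  assert_that(marker_frac * n_genes >= 1,
              "marker_frac * n_genes must be at least 1")
  assert_that(dropout_rate >= 0 && dropout_rate < 1,
              "dropout_rate must lie in [0, 1)")
  assert_that(marker_fold > 0 && dispersion > 0, "parameters must be positive")
  structure(list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                 n_types = as.integer(n_types),
                 type_proportions = type_proportions,
                 marker_frac = marker_frac, marker_fold = marker_fold,
                 dispersion = dispersion, dropout_rate = dropout_rate,
                 dropout_shape = dropout_shape,
                 mean_log_mu = mean_log_mu, sd_log_mu = sd_log_mu,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic single-cell count matrix with planted cell types
#'
#' Draws baseline gene means from a log-normal (heavy-tailed) distribution,
#' elevates each type's disjoint marker-gene block by `marker_fold`, samples
#' counts from a negative binomial with the given dispersion, and injects
#' extra zeros at `dropout_rate` (Bernoulli per entry, weighted toward
#' low-expression genes when `dropout_shape > 0`). Fully reproducible from
#' the spec's seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `synthetic_dataset` with `counts` (an
#'   [expression_matrix()]), `true_labels` (integer vector, one per cell),
#'   and `marker_map` (per-type marker gene index list).
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    m <- spec$n_genes; n <- spec$n_cells; k <- spec$n_types
    labels <- sample(rep(seq_len(k),
                         times = stats::rmultinom(1, n, spec$type_proportions)))
    base_mu <- exp(stats::rnorm(m, spec$mean_log_mu, spec$sd_log_mu))

    n_mark <- max(1L, as.integer(round(spec$marker_frac * m)))
    marker_map <- split(seq_len(n_mark * k),
                        rep(seq_len(k), each = n_mark))
    names(marker_map) <- paste0("type", seq_len(k))

    mu <- matrix(base_mu, m, n)
    for (t in seq_len(k)) {
      cells_t <- labels == t
      mu[marker_map[[t]], cells_t] <- mu[marker_map[[t]], cells_t] *
        spec$marker_fold
    }
    counts <- matrix(stats::rnbinom(m * n, size = spec$dispersion, mu = mu),
                     m, n)
    if (spec$dropout_rate > 0) {
      # dropout probability decays with log mean when dropout_shape > 0
      w <- exp(-spec$dropout_shape * log1p(mu))
      p_drop <- spec$dropout_rate * if (spec$dropout_shape > 0) {
        w / mean(w)
      } else {
        1
      }
      p_drop <- pmin(p_drop, 0.95)
      counts[stats::runif(m * n) < p_drop] <- 0L
    }
    structure(list(
      counts = expression_matrix(counts,
                                 gene_ids = sprintf("gene%04d", seq_len(m)),
                                 cell_ids = sprintf("cell%04d", seq_len(n))),
      true_labels = as.integer(labels),
      marker_map = marker_map,
      spec = spec
    ), class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset: %d genes x %d cells, %d planted types\n",
              nrow(x$counts$values), ncol(x$counts$values), x$spec$n_types))
  invisible(x)
}

#' Write a synthetic dataset as an MTX triplet plus labels
#'
#' Emits `matrix.mtx`, `genes.tsv`, `barcodes.tsv` (the 10x-style triplet
#' consumed by [load_expression()]), a `labels.tsv` with the planted type of
#' every cell, and `spec.json` recording the generator parameters.
#'
#' @param ds A `synthetic_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::Matrix(ds$counts$values, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  utils::write.table(data.frame(g = ds$counts$gene_ids),
                     file.path(dir, "genes.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  utils::write.table(data.frame(b = ds$counts$cell_ids),
                     file.path(dir, "barcodes.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  utils::write.table(data.frame(cell_id = ds$counts$cell_ids,
                                label = ds$true_labels),
                     file.path(dir, "labels.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(unclass(ds$spec), file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
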