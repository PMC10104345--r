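#' Pipeline configuration
#'
#' Collects every tunable of the clustering pipeline with its default:
#' feature-candidate fraction 0.05, per-round subset fraction 0.70, L = 20
#' ensemble rounds at 30 clusters per measurement, 10 principal components as
#' GCN node features, hidden layer widths 32 and 16, 200 training epochs at
#' Adam learning rate 0.01, and a k search range of [2, 30] for the elbow.
#'
#' @param top_fraction Feature-gene candidate fraction.
#' @param subset_fraction Per-round random sampling fraction.
#' @param L Ensemble rounds.
#' @param k_sub Clusters per similarity measurement.
#' @param perplexity t-SNE perplexity (auto-reduced for small N).
#' @param tsne_iter t-SNE iterations per round.
#' @param n_pcs Principal components used as node features.
#' @param hidden_dims GCN layer widths.
#' @param epochs GAE training epochs.
#' @param learning_rate Adam step size.
#' @param k_range Elbow search range `c(k_min, k_max)`.
#' @param binarize_threshold Optional strict binary edge-target threshold.
#' @param seed Master seed; all stage substreams derive from it.
#' @return A list of class `grace_config`.
#' @export
grace_config <- function(top_fraction = 0.05, subset_fraction = 0.7,
                         L = 20, k_sub = 30, perplexity = 30, tsne_iter = 500,
                         n_pcs = 10, hidden_dims = c(32, 16), epochs = 200,
                         learning_rate = 0.01, k_range = c(2, 30),
                         binarize_threshold = NULL, seed = 1L) {
  structure(as.list(environment()), class = "grace_config")
}

config_hash <- function(config) {
  # order-stable digest of the configuration for the run manifest
  s <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE,
                        digits = NA, null = "null")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %%
            4294967291)
}

#' Run the full clustering pipeline
#'
#' Executes all stages in order: normalization (gene filter, CPM, log2),
#' feature-candidate selection, L rounds of feature subsampling + t-SNE +
#' k-means/hierarchical co-association, ensemble similarity accumulation,
#' graph-autoencoder embedding, elbow estimation of the cluster count, and
#' final k-means labels.
#'
#' @param x An [expression_matrix()] of raw counts.
#' @param config A [grace_config()].
#' @param k Optional fixed cluster count; when `NULL` (default) the elbow
#'   estimate is used.
#' @param verbose Print stage progress.
#' @return A list of class `grace_result` with `labels`
#'   (a `clustering_result`), `embedding` (a `cell_embedding`), `similarity`
#'   (an `ensemble_similarity`), `k_estimated`, `inertia_curve`, and
#'   `manifest` (seed, config and its hash, stage timings).
#' @export
run_grace <- function(x, config = grace_config(), k = NULL, verbose = FALSE) {
  stopifnot(inherits(x, "expression_matrix"), inherits(config, "grace_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()

  say("normalizing %d genes x %d cells", nrow(x$values), ncol(x$values))
  xn <- normalize_expression(x)

  say("building ensemble similarity (L = %d)", config$L)
  a <- build_ensemble_similarity(
    xn, L = config$L, k_sub = config$k_sub,
    top_fraction = config$top_fraction,
    subset_fraction = config$subset_fraction,
    perplexity = config$perplexity, tsne_iter = config$tsne_iter,
    seed = derive_seed(config$seed, "ensemble"))

  say("training graph autoencoder (%d epochs)", config$epochs)
  feats <- compute_node_features(xn, n_components = config$n_pcs)
  z <- train_gae(a, feats, epochs = config$epochs,
                 learning_rate = config$learning_rate,
                 hidden_dims = config$hidden_dims,
                 binarize_threshold = config$binarize_threshold,
                 seed = derive_seed(config$seed, "gae"))

  say("estimating number of clusters")
  est <- estimate_num_clusters(z, k_min = config$k_range[1L],
                               k_max = min(config$k_range[2L],
                                           ncol(x$values) - 1L),
                               seed = derive_seed(config$seed, "elbow"))
  k_used <- if (is.null(k)) est$k else as.integer(k)

  say("final k-means with k = %d", k_used)
  cl <- final_labels(z, k = k_used,
                     seed = derive_seed(config$seed, "final_kmeans"))
  cl$k_estimated <- est$k

  manifest <- list(
    seed = config$seed,
    config = unclass(config),
    config_hash = config_hash(unclass(config)),
    n_genes_raw = nrow(x$values), n_genes_used = nrow(xn$values),
    n_cells = ncol(x$values),
    k_estimated = est$k, k_used = k_used,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    package_version = as.character(utils::packageVersion("grace"))
  )
  structure(list(labels = cl, embedding = z, similarity = a,
                 k_estimated = est$k, inertia_curve = est$inertia_curve,
                 manifest = manifest),
            class = "grace_result")
}

#' @export
print.grace_result <- function(x, ...) {
  cat(sprintf("grace_result: %d cells -> %d clusters (k estimated %d)\n",
              length(x$labels$labels), x$labels$k_used, x$k_estimated))
  invisible(x)
}

#' Write all pipeline artifacts to a directory
#'
#' Emits labels TSV, embedding TSV, similarity MTX (+ cell sidecar), loss
#' history CSV, inertia curve CSV, and the run manifest JSON.
#'
#' @param res A `grace_result`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_grace_result <- function(res, dir) {
  stopifnot(inherits(res, "grace_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_labels(res$labels, file.path(dir, "labels.tsv"))
  write_embedding(res$embedding, file.path(dir, "embedding.tsv"))
  write_similarity(res$similarity, file.path(dir, "similarity.mtx"))
  utils::write.csv(data.frame(epoch = seq_along(res$embedding$loss_history),
                              loss = res$embedding$loss_history),
                   file.path(dir, "loss_history.csv"), row.names = FALSE)
  utils::write.csv(res$inertia_curve, file.path(dir, "inertia_curve.csv"),
                   row.names = FALSE)
  jsonlite::write_json(res$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Evaluate predicted labels against true labels from TSV files
#'
#' Reads two label files (two-column TSV with a header: cell_id, label),
#' aligns them on cell id, and reports the four external validation metrics.
#'
#' @param labels_path Path to predicted labels TSV.
#' @param truth_path Path to true labels TSV.
#' @return Named list with `ari`, `nmi`, `jcci`, `purity`, and `n_cells`.
#' @export
run_evaluate <- function(labels_path, truth_path) {
  read_lab <- function(p) {
    if (!file.exists(p)) stop("no such label file: ", p)
    df <- utils::read.table(p, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    assert_that(ncol(df) >= 2L, "label file needs cell_id and label columns: ", p)
    stats::setNames(df[[2L]], df[[1L]])
  }
  pred <- read_lab(labels_path)
  truth <- read_lab(truth_path)
  common <- intersect(names(pred), names(truth))
  if (length(common) == 0L) {
    stop_validation("no shared cell ids between ", labels_path, " and ",
                    truth_path)
  }
  missing <- union(setdiff(names(pred), common), setdiff(names(truth), common))
  if (length(missing) > 0L) {
    stop_validation("cell ids present in only one file: ",
                    paste(utils::head(missing, 10L), collapse = ", "),
                    if (length(missing) > 10L) " ..." else "")
  }
  c(evaluate_clustering(truth[common], pred[common]),
    list(n_cells = length(common)))
}
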