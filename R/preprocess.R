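#' Construct an expression matrix object
#'
#' Bundles a genes x cells matrix of non-negative expression values with
#' unique gene and cell identifiers. This is the raw-count container every
#' downstream stage consumes.
#'
#' @param values Numeric matrix, genes in rows, cells in columns; all entries
#'   must be non-negative and finite.
#' @param gene_ids Character vector of unique gene identifiers (defaults to
#'   rownames of `values`, or `gene1..geneM`).
#' @param cell_ids Character vector of unique cell identifiers (defaults to
#'   colnames of `values`, or `cell1..cellN`).
#' @return An object of class `expression_matrix` with elements `values`,
#'   `gene_ids`, `cell_ids`.
#' @export
expression_matrix <- function(values, gene_ids = NULL, cell_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  assert_that(nrow(values) >= 1L && ncol(values) >= 1L,
              "expression matrix must have at least one gene and one cell")
  assert_that(all(is.finite(values)), "expression values must be finite")
  assert_that(all(values >= 0), "expression values must be non-negative")
  if (is.null(gene_ids)) {
    gene_ids <- rownames(values)
    if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(nrow(values)))
  }
  if (is.null(cell_ids)) {
    cell_ids <- colnames(values)
    if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(ncol(values)))
  }
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  assert_that(length(gene_ids) == nrow(values),
              "gene_ids length must match the number of rows")
  assert_that(length(cell_ids) == ncol(values),
              "cell_ids length must match the number of columns")
  assert_that(!anyDuplicated(gene_ids), "gene_ids must be unique")
  assert_that(!anyDuplicated(cell_ids), "cell_ids must be unique")
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(list(values = values, gene_ids = gene_ids, cell_ids = cell_ids),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d cells\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Load an expression matrix from disk
#'
#' Reads a genes x cells expression matrix from one of three on-disk dialects:
#' a dense delimited file with a header row of cell identifiers and gene
#' identifiers in the first column (`csv`, comma- or tab-separated by file
#' extension or the `sep` argument), a 10x-style MatrixMarket triplet (`mtx`
#' file plus `genes.tsv`/`barcodes.tsv` sidecars), or an HDF5 container with
#' datasets `matrix` (dense, genes x cells), `gene_ids`, and `cell_ids`
#' (requires the rhdf5 package).
#'
#' @param path Path to the matrix file (for `mtx_triplet`, the `.mtx` file;
#'   its sidecars are looked up in the same directory unless given).
#' @param format One of `"csv"`, `"mtx_triplet"`, `"h5"`.
#' @param orientation Orientation of the on-disk matrix: `"genes_x_cells"`
#'   (default, matching the usual convention) or `"cells_x_genes"`, in which
#'   case the matrix is transposed on load.
#' @param sep Field separator for the `csv` format; inferred from the file
#'   extension (`.tsv`/`.txt` gives tab) when `NULL`.
#' @param genes_file,barcodes_file Optional explicit sidecar paths for the
#'   `mtx_triplet` format.
#' @return An [expression_matrix()].
#' @export
load_expression <- function(path,
                            format = c("csv", "mtx_triplet", "h5"),
                            orientation = c("genes_x_cells", "cells_x_genes"),
                            sep = NULL,
                            genes_file = NULL,
                            barcodes_file = NULL) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) {
    stop("cannot read expression data: no such file: ", path)
  }
  res <- switch(
    format,
    csv = {
      if (is.null(sep)) {
        sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
      }
      df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                              check.names = FALSE, comment.char = "")
      m <- as.matrix(df)
      if (!is.numeric(m)) {
        stop("format error in ", path, ": non-numeric entries in matrix body")
      }
      list(values = m, gene_ids = rownames(m), cell_ids = colnames(m))
    },
    mtx_triplet = {
      dir <- dirname(path)
      if (is.null(genes_file)) genes_file <- file.path(dir, "genes.tsv")
      if (is.null(barcodes_file)) barcodes_file <- file.path(dir, "barcodes.tsv")
      for (f in c(genes_file, barcodes_file)) {
        if (!file.exists(f)) stop("missing MTX sidecar file: ", f)
      }
      m <- as.matrix(Matrix::readMM(path))
      genes <- utils::read.table(genes_file, sep = "\t",
                                 stringsAsFactors = FALSE)[[1L]]
      cells <- utils::read.table(barcodes_file, sep = "\t",
                                 stringsAsFactors = FALSE)[[1L]]
      nr <- if (orientation == "genes_x_cells") length(genes) else length(cells)
      nc <- if (orientation == "genes_x_cells") length(cells) else length(genes)
      if (nrow(m) != nr || ncol(m) != nc) {
        stop("format error: MTX dimensions ", nrow(m), "x", ncol(m),
             " do not match sidecar lengths (", length(genes), " genes, ",
             length(cells), " barcodes)")
      }
      list(values = m, gene_ids = genes, cell_ids = cells)
    },
    h5 = {
      if (!requireNamespace("rhdf5", quietly = TRUE)) {
        stop("reading HDF5 requires the rhdf5 package")
      }
      m <- rhdf5::h5read(path, "matrix")
      genes <- as.character(rhdf5::h5read(path, "gene_ids"))
      cells <- as.character(rhdf5::h5read(path, "cell_ids"))
      list(values = m, gene_ids = genes, cell_ids = cells)
    }
  )
  values <- res$values
  gene_ids <- res$gene_ids
  cell_ids <- res$cell_ids
  if (orientation == "cells_x_genes") {
    values <- t(values)
    if (format == "csv") {
      # dense dialect carries ids in its own dimnames, so they swap too
      tmp <- gene_ids; gene_ids <- cell_ids; cell_ids <- tmp
    }
  }
  if (format != "csv") {
    if (nrow(values) != length(gene_ids) || ncol(values) != length(cell_ids)) {
      stop("format error: matrix dimensions do not match identifier lists")
    }
  }
  if (any(values < 0)) {
    stop_validation("negative expression entries found in ", path)
  }
  expression_matrix(values, gene_ids = gene_ids, cell_ids = cell_ids)
}

#' Remove genes never expressed in any cell
#'
#' Drops every gene whose expression is zero across all cells; such genes
#' carry no information but inflate memory and variance-ranking noise.
#' Row order of the remaining genes is preserved.
#'
#' @param x An [expression_matrix()].
#' @return An [expression_matrix()] with only expressed genes.
#' @export
drop_unexpressed_genes <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  keep <- rowSums(x$values != 0) > 0L
  if (!any(keep)) stop_validation("no expressed genes remain after filtering")
  expression_matrix(x$values[keep, , drop = FALSE],
                    gene_ids = x$gene_ids[keep],
                    cell_ids = x$cell_ids)
}

#' Counts-per-million library-size normalization
#'
#' Scales every cell (column) so its total expression equals `library_target`
#' (10^6 by default), removing library-size differences between cells.
#'
#' @param x An [expression_matrix()] or a non-negative numeric matrix
#'   (genes x cells).
#' @param library_target Post-scaling column sum; 1e6 gives counts per million.
#' @return A numeric matrix of the same shape with columns summing to
#'   `library_target`.
#' @export
cpm_normalize <- function(x, library_target = 1e6) {
  m <- if (inherits(x, "expression_matrix")) x$values else as.matrix(x)
  assert_that(all(m >= 0), "expression values must be non-negative")
  libsize <- colSums(m)
  if (any(libsize == 0)) {
    bad <- colnames(m)[libsize == 0]
    if (is.null(bad)) bad <- which(libsize == 0)
    stop_validation("cannot normalize all-zero cell(s): ",
                    paste(bad, collapse = ", "))
  }
  sweep(m, 2L, libsize / library_target, "/")
}

#' log2(1 + x) transformation
#'
#' Compresses the skewed dynamic range of normalized expression values;
#' zero maps to zero.
#'
#' @param x Non-negative numeric matrix.
#' @return Matrix of `log2(1 + x)` values.
#' @export
log_transform <- function(x) {
  m <- as.matrix(x)
  assert_that(all(m >= 0), "log transform requires non-negative values")
  log2(1 + m)
}

#' Full normalization: gene filter, CPM, log2(1 + x)
#'
#' Produces the normalized matrix used throughout the pipeline: unexpressed
#' genes are removed from the raw counts, columns are scaled to counts per
#' million (library sizes computed after the gene filter), and values are
#' log2(1 + x) transformed.
#'
#' @param x An [expression_matrix()].
#' @param filter_genes Drop never-expressed genes first (default TRUE).
#' @param library_target Target library size for CPM (default 1e6).
#' @return An object of class `normalized_matrix` with elements `values`
#'   (genes x cells, log scale), `gene_ids`, `cell_ids`, `library_target`.
#' @export
normalize_expression <- function(x, filter_genes = TRUE, library_target = 1e6) {
  stopifnot(inherits(x, "expression_matrix"))
  if (filter_genes) x <- drop_unexpressed_genes(x)
  v <- log_transform(cpm_normalize(x, library_target = library_target))
  structure(list(values = v,
                 gene_ids = x$gene_ids,
                 cell_ids = x$cell_ids,
                 library_target = library_target),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d genes x %d cells (CPM target %g, log2 scale)\n",
              nrow(x$values), ncol(x$values), x$library_target))
  invisible(x)
}

#' Write a normalized matrix to CSV
#'
#' @param x A `normalized_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_normalized <- function(x, path) {
  stopifnot(inherits(x, "normalized_matrix"))
  utils::write.csv(as.data.frame(x$values), path, row.names = TRUE)
  invisible(path)
}
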