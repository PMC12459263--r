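#' Construct a single-cell dataset
#'
#' The central container of the package: a cells x genes expression matrix
#' together with per-cell batch labels and (optionally) ground-truth cell type
#' labels used only for benchmarking. The `layer_state` field records which
#' preprocessing steps have been applied so that downstream operations can
#' check their preconditions.
#'
#' @param matrix A cells x genes numeric matrix (dense or `Matrix` sparse)
#'   of nonnegative values. Rows are cells.
#' @param batch Per-cell batch labels (character or factor, length = n cells).
#'   Batches are treated as opaque categories ordered by first appearance.
#' @param cell_ids Unique cell identifiers; defaults to matrix rownames or
#'   `cell1..cellN`. Duplicates are made unique deterministically
#'   (first occurrence keeps its name, later ones get a numeric suffix).
#' @param gene_ids Unique gene identifiers; defaults to matrix colnames or
#'   `gene1..geneG`.
#' @param type_label Optional per-cell true type labels (for metrics only).
#' @param layer_state One of `"raw_counts"`, `"normalized"`, `"scaled"`.
#'
#' @return An object of class `bn_dataset`: a list with elements `matrix`,
#'   `cell_ids`, `gene_ids`, `batch` (factor, levels in first-appearance
#'   order), `type_label` (factor or `NULL`) and `layer_state`.
#' @export
bn_dataset <- function(matrix, batch, cell_ids = NULL, gene_ids = NULL,
                       type_label = NULL,
                       layer_state = c("raw_counts", "normalized", "scaled")) {
  layer_state <- match.arg(layer_state)
  if (is.data.frame(matrix)) matrix <- as.matrix(matrix)
  if (!(is.matrix(matrix) || methods::is(matrix, "Matrix")))
    stop("`matrix` must be a matrix of expression values", call. = FALSE)
  if (!is.numeric(matrix[1, 1]))
    stop("expression matrix must be numeric", call. = FALSE)

  n <- nrow(matrix); g <- ncol(matrix)
  if (is.null(cell_ids)) cell_ids <- rownames(matrix)
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(n))
  if (is.null(gene_ids)) gene_ids <- colnames(matrix)
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(g))
  cell_ids <- make.unique(as.character(cell_ids), sep = "-")
  gene_ids <- make.unique(as.character(gene_ids), sep = "-")
  if (length(cell_ids) != n || length(batch) != n)
    stop("cell_ids and batch must match the matrix row count", call. = FALSE)
  if (length(gene_ids) != g)
    stop("gene_ids must match the matrix column count", call. = FALSE)

  batch <- factor(as.character(batch), levels = unique(as.character(batch)))
  if (!is.null(type_label)) {
    if (length(type_label) != n)
      stop("type_label must have one entry per cell", call. = FALSE)
    type_label <- factor(as.character(type_label),
                         levels = unique(as.character(type_label)))
  }
  if (layer_state == "raw_counts" && min_value(matrix) < 0)
    stop("raw counts must be nonnegative", call. = FALSE)
  if (nlevels(batch) == 1L)
    warning("input contains a single batch; only intra-batch MNN pairs ",
            "will be available", call. = FALSE)

  dimnames(matrix) <- list(cell_ids, gene_ids)
  structure(
    list(matrix = matrix, cell_ids = cell_ids, gene_ids = gene_ids,
         batch = batch, type_label = type_label, layer_state = layer_state),
    class = "bn_dataset")
}

min_value <- function(m) {
  if (methods::is(m, "sparseMatrix")) {
    x <- m@x
    if (length(x) == 0) 0 else min(0, min(x))
  } else min(m)
}

#' @export
print.bn_dataset <- function(x, ...) {
  cat(sprintf("<bn_dataset> %d cells x %d genes [%s]\n",
              nrow(x$matrix), ncol(x$matrix), x$layer_state))
  cat(sprintf("  batches: %s\n",
              paste(sprintf("%s (%d)", levels(x$batch), table(x$batch)),
                    collapse = ", ")))
  if (!is.null(x$type_label))
    cat(sprintf("  types:   %s\n", paste(levels(x$type_label), collapse = ", ")))
  invisible(x)
}

#' @export
dim.bn_dataset <- function(x) dim(x$matrix)

#' Number of batches in a dataset
#' @param ds A `bn_dataset`.
#' @return Integer count of distinct batch labels.
#' @export
n_batches <- function(ds) nlevels(ds$batch)

# Row/column subset preserving metadata; used by QC and HVG selection.
subset_dataset <- function(ds, cells = NULL, genes = NULL) {
  if (!is.null(cells)) {
    ds$matrix <- ds$matrix[cells, , drop = FALSE]
    ds$cell_ids <- ds$cell_ids[cells]
    ds$batch <- droplevels(ds$batch[cells])
    if (!is.null(ds$type_label)) ds$type_label <- droplevels(ds$type_label[cells])
  }
  if (!is.null(genes)) {
    ds$matrix <- ds$matrix[, genes, drop = FALSE]
    ds$gene_ids <- ds$gene_ids[genes]
  }
  ds
}

#' Construct an embedding
#'
#' A cells x d coordinate matrix keyed to the cells of a dataset, either the
#' PCA projection (`space = "pca"`) or the network output
#' (`space = "corrected"`).
#'
#' @param coords Numeric cells x d matrix with finite entries.
#' @param cell_ids Cell identifiers aligned with the source dataset order.
#' @param space `"pca"` or `"corrected"`.
#' @return An object of class `bn_embedding`.
#' @export
bn_embedding <- function(coords, cell_ids, space = c("pca", "corrected")) {
  space <- match.arg(space)
  coords <- as.matrix(coords)
  if (!all(is.finite(coords)))
    stop("embedding coordinates must be finite", call. = FALSE)
  if (ncol(coords) < 1) stop("embedding dimension must be >= 1", call. = FALSE)
  if (nrow(coords) != length(cell_ids))
    stop("coords rows must match cell_ids", call. = FALSE)
  rownames(coords) <- cell_ids
  structure(list(coords = coords, cell_ids = as.character(cell_ids),
                 space = space),
            class = "bn_embedding")
}

#' @export
print.bn_embedding <- function(x, ...) {
  cat(sprintf("<bn_embedding> %d cells x %d dims [%s]\n",
              nrow(x$coords), ncol(x$coords), x$space))
  invisible(x)
}

#' @export
dim.bn_embedding <- function(x) dim(x$coords)
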