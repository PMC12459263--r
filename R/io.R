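#' Load a dataset from disk
#'
#' Reads one of three formats into a raw-count [bn_dataset()]:
#'
#' * `"csv"` — one comma-separated table, cells as rows: a `cell_id` column,
#'   the `batch_key` column, optionally a `label_key` column, and one
#'   numeric column per gene (UTF-8, header row).
#' * `"mtx"` — a directory holding `matrix.mtx` (MatrixMarket coordinate,
#'   genes x cells), `genes.tsv` (one gene ID per line) and `barcodes.tsv`
#'   (tab-separated with header: `cell_id`, the `batch_key` column and
#'   optionally `label_key`).
#' * `"h5ad"` — an AnnData container (see [read_h5ad()]).
#'
#' Duplicate cell or gene IDs are deduplicated deterministically: the first
#' occurrence keeps its name, later ones get a `-<k>` suffix.
#'
#' @param path File (csv/h5ad) or directory (mtx) path.
#' @param format One of `"csv"`, `"mtx"`, `"h5ad"`.
#' @param batch_key Name of the column holding per-cell batch labels.
#' @param label_key Optional column holding true type labels.
#' @return A `bn_dataset` with `layer_state = "raw_counts"`.
#' @export
load_dataset <- function(path, format = c("csv", "mtx", "h5ad"),
                         batch_key = "batch", label_key = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(format,
    csv = load_dataset_csv(path, batch_key, label_key),
    mtx = load_dataset_mtx(path, batch_key, label_key),
    h5ad = read_h5ad(path, batch_key, label_key))
}

load_dataset_csv <- function(path, batch_key, label_key) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!batch_key %in% names(df))
    stop("batch_key '", batch_key, "' not found in ", path, call. = FALSE)
  id_col <- if ("cell_id" %in% names(df)) "cell_id" else names(df)[1]
  meta <- c(id_col, batch_key, label_key)
  gene_cols <- setdiff(names(df), meta)
  m <- as.matrix(df[, gene_cols, drop = FALSE])
  if (!is.numeric(m))
    stop("non-numeric expression values in ", path, call. = FALSE)
  bn_dataset(m, batch = df[[batch_key]], cell_ids = df[[id_col]],
             gene_ids = gene_cols,
             type_label = if (!is.null(label_key)) df[[label_key]],
             layer_state = "raw_counts")
}

load_dataset_mtx <- function(dir, batch_key, label_key) {
  mtx <- file.path(dir, "matrix.mtx")
  genes <- file.path(dir, "genes.tsv")
  cells <- file.path(dir, "barcodes.tsv")
  for (f in c(mtx, genes, cells))
    if (!file.exists(f)) stop("missing MTX component: ", f, call. = FALSE)
  m <- Matrix::readMM(mtx)           # genes x cells
  gene_ids <- readLines(genes)
  meta <- utils::read.delim(cells, stringsAsFactors = FALSE)
  if (!batch_key %in% names(meta))
    stop("batch_key '", batch_key, "' not found in barcodes.tsv",
         call. = FALSE)
  bn_dataset(as.matrix(Matrix::t(m)), batch = meta[[batch_key]],
             cell_ids = meta$cell_id, gene_ids = gene_ids,
             type_label = if (!is.null(label_key)) meta[[label_key]],
             layer_state = "raw_counts")
}

#' Write a dataset as an MTX triplet
#'
#' Writes `matrix.mtx` (genes x cells MatrixMarket coordinate format),
#' `genes.tsv` and `barcodes.tsv` (tab-separated metadata with `cell_id`,
#' `batch` and, when present, `cell_type`) into a directory.
#'
#' @param ds A `bn_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_mtx <- function(ds, dir) {
  stopifnot(inherits(ds, "bn_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(Matrix::t(Matrix::Matrix(ds$matrix,
                                                       sparse = TRUE)),
                              "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(ds$gene_ids, file.path(dir, "genes.tsv"))
  meta <- data.frame(cell_id = ds$cell_ids, batch = as.character(ds$batch),
                     stringsAsFactors = FALSE)
  if (!is.null(ds$type_label)) meta$cell_type <- as.character(ds$type_label)
  utils::write.table(meta, file.path(dir, "barcodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Write a dataset as one CSV table
#'
#' Cells as rows; columns are `cell_id`, `batch`, optionally `cell_type`,
#' then one column per gene. Values are printed at full precision (R's
#' default 15 significant digits), so raw integer counts round-trip
#' exactly.
#'
#' @param ds A `bn_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_csv_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "bn_dataset"))
  df <- data.frame(cell_id = ds$cell_ids, batch = as.character(ds$batch),
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(ds$type_label)) df$cell_type <- as.character(ds$type_label)
  df <- cbind(df, as.data.frame(as.matrix(ds$matrix)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Save integration results
#'
#' Writes the corrected embedding and the per-cell global cluster labels as
#' a CSV table (`cell_id`, one column per embedding dimension, `label`),
#' and, when `h5ad` points to an existing AnnData container, also writes
#' them back into it under `obsm/X_corrected` and `obs/global_cluster`.
#'
#' @param embedding A `bn_embedding` (finite coordinates).
#' @param labels Per-cell cluster labels aligned with the embedding.
#' @param path Output CSV path.
#' @param h5ad Optional path to an existing h5ad file to annotate.
#' @return `path`, invisibly.
#' @export
save_result <- function(embedding, labels, path, h5ad = NULL) {
  stopifnot(inherits(embedding, "bn_embedding"))
  if (length(labels) != nrow(embedding$coords))
    stop("labels must align with the embedding", call. = FALSE)
  df <- data.frame(cell_id = embedding$cell_ids,
                   embedding$coords,
                   label = labels, check.names = FALSE)
  ok <- tryCatch({
    utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                     row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("could not write to ", path, call. = FALSE)
  if (!is.null(h5ad)) h5ad_write_result(h5ad, embedding, labels)
  invisible(path)
}

#' Load a saved result CSV
#'
#' Round-trip companion of [save_result()].
#'
#' @param path Path written by [save_result()].
#' @return A list with `embedding` (a corrected-space `bn_embedding`) and
#'   `labels`.
#' @export
load_result <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  coord_cols <- setdiff(names(df), c("cell_id", "label"))
  emb <- bn_embedding(as.matrix(df[, coord_cols, drop = FALSE]),
                      df$cell_id, space = "corrected")
  list(embedding = emb, labels = df$label)
}
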