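# Minimal AnnData (h5ad) container access built on rhdf5. Covers the subset
# of the on-disk layout this package emits and consumes: a dense or
# CSR/CSC-encoded X, dataframe-encoded obs/var with string, categorical or
# numeric columns, and obsm arrays. HDF5 is row-major while R is
# column-major, so 2-D datasets are transposed on the way in and out to keep
# the Python-side shape (n_obs, n_var).

h5_write_string_attr <- function(file, obj, name, value) {
  h5f <- rhdf5::H5Fopen(file)
  on.exit(rhdf5::H5Fclose(h5f), add = TRUE)
  h5o <- rhdf5::H5Oopen(h5f, obj)
  on.exit(rhdf5::H5Oclose(h5o), add = TRUE)
  rhdf5::h5writeAttribute(value, h5o, name, variableLengthString = TRUE,
                          asScalar = length(value) == 1L)
}

# rhdf5's h5writeAttribute rejects zero-length values; create the (empty)
# attribute through the low-level API instead.
h5_write_empty_string_attr <- function(file, obj, name) {
  h5f <- rhdf5::H5Fopen(file)
  on.exit(rhdf5::H5Fclose(h5f), add = TRUE)
  h5o <- rhdf5::H5Oopen(h5f, obj)
  on.exit(rhdf5::H5Oclose(h5o), add = TRUE)
  sid <- rhdf5::H5Screate_simple(0)
  tid <- rhdf5::H5Tcopy("H5T_C_S1")
  rhdf5::H5Tset_size(tid, NULL)
  rhdf5::H5Tset_cset(tid, "UTF-8")
  aid <- rhdf5::H5Acreate(h5o, name, tid, sid)
  rhdf5::H5Aclose(aid)
  rhdf5::H5Sclose(sid)
}

h5_encoding <- function(file, obj, type, version) {
  h5_write_string_attr(file, obj, "encoding-type", type)
  h5_write_string_attr(file, obj, "encoding-version", version)
}

h5_write_string_array <- function(file, name, values) {
  rhdf5::h5write(values, file, name, variableLengthString = TRUE)
  h5_encoding(file, name, "string-array", "0.2.0")
}

h5_write_dataframe <- function(file, name, index_name, index, columns) {
  rhdf5::h5createGroup(file, name)
  h5_encoding(file, name, "dataframe", "0.2.0")
  h5_write_string_attr(file, name, "_index", index_name)
  if (length(columns)) {
    h5_write_string_attr(file, name, "column-order", names(columns))
  } else {
    h5_write_empty_string_attr(file, name, "column-order")
  }
  h5_write_string_array(file, paste0(name, "/", index_name), index)
  for (cn in names(columns)) {
    col <- columns[[cn]]
    path <- paste0(name, "/", cn)
    if (is.numeric(col)) {
      rhdf5::h5write(col, file, path)
      h5_encoding(file, path, "array", "0.2.0")
    } else {
      h5_write_string_array(file, path, as.character(col))
    }
  }
}

#' Write a dataset to an h5ad container
#'
#' Emits a minimal AnnData-layout HDF5 file: dense `X` (cells x genes),
#' `obs` with the batch (and optional type) column, `var` with gene IDs,
#' and optionally `obsm` arrays.
#'
#' @param ds A `bn_dataset`.
#' @param path Output file path (overwritten if present).
#' @param batch_key,label_key Column names used in `obs` (defaults
#'   `"batch"` and `"cell_type"`).
#' @param obsm Optional named list of cells x d matrices stored under
#'   `obsm/<name>`.
#' @return `path`, invisibly.
#' @export
write_h5ad <- function(ds, path, batch_key = "batch",
                       label_key = "cell_type", obsm = NULL) {
  stopifnot(inherits(ds, "bn_dataset"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  h5_encoding(path, "/", "anndata", "0.1.0")
  # transpose: h5py then sees shape (n_obs, n_var)
  rhdf5::h5write(t(as.matrix(ds$matrix)), path, "X")
  h5_encoding(path, "X", "array", "0.2.0")
  cols <- stats::setNames(list(as.character(ds$batch)), batch_key)
  if (!is.null(ds$type_label))
    cols[[label_key]] <- as.character(ds$type_label)
  h5_write_dataframe(path, "obs", "cell_id", ds$cell_ids, cols)
  h5_write_dataframe(path, "var", "gene_id", ds$gene_ids, list())
  rhdf5::h5createGroup(path, "obsm")
  h5_encoding(path, "obsm", "dict", "0.1.0")
  if (!is.null(obsm)) {
    for (nm in names(obsm)) {
      rhdf5::h5write(t(as.matrix(obsm[[nm]])), path, paste0("obsm/", nm))
      h5_encoding(path, paste0("obsm/", nm), "array", "0.2.0")
    }
  }
  rhdf5::h5createGroup(path, "uns")
  h5_encoding(path, "uns", "dict", "0.1.0")
  h5_write_string_array(path, "uns/layer_state", ds$layer_state)
  invisible(path)
}

h5_read_dataframe_column <- function(file, path, contents) {
  base <- basename(path)
  entry <- contents[contents$name == base & contents$group == dirname2(path), ]
  x <- rhdf5::h5read(file, path)
  if (is.list(x) && !is.null(x$categories)) {       # categorical encoding
    as.character(x$categories)[as.integer(x$codes) + 1L]
  } else if (is.array(x) || is.vector(x)) {
    as.vector(x)
  } else x
}

dirname2 <- function(p) {
  d <- dirname(p)
  if (d == ".") "/" else paste0("/", sub("^/", "", d))
}

h5ad_read_x <- function(path) {
  ls <- rhdf5::h5ls(path)
  xrow <- ls[ls$group == "/" & ls$name == "X", ]
  if (nrow(xrow) == 0) stop("no X matrix in h5ad file", call. = FALSE)
  if (xrow$otype == "H5I_GROUP") {
    enc <- tryCatch(
      rhdf5::h5readAttributes(path, "X")[["encoding-type"]],
      error = function(e) "csr_matrix")
    shape <- as.integer(rhdf5::h5readAttributes(path, "X")[["shape"]])
    data <- as.numeric(rhdf5::h5read(path, "X/data"))
    indices <- as.integer(rhdf5::h5read(path, "X/indices"))
    indptr <- as.integer(rhdf5::h5read(path, "X/indptr"))
    if (identical(enc, "csc_matrix")) {
      m <- Matrix::sparseMatrix(i = indices + 1L, p = indptr, x = data,
                                dims = shape)
    } else {  # CSR of (n, g) is CSC of the transpose
      m <- Matrix::t(Matrix::sparseMatrix(i = indices + 1L, p = indptr,
                                          x = data, dims = rev(shape)))
    }
    as.matrix(m)
  } else {
    x <- rhdf5::h5read(path, "X")
    t(as.matrix(x))   # undo the row-major/column-major flip
  }
}

h5ad_read_df <- function(path, group) {
  attrs <- rhdf5::h5readAttributes(path, group)
  index_name <- attrs[["_index"]]
  if (is.null(index_name)) index_name <- "_index"
  ls <- rhdf5::h5ls(path)
  here <- ls[ls$group == paste0("/", group), ]
  idx <- as.character(rhdf5::h5read(path, paste0(group, "/", index_name)))
  cols <- list()
  for (nm in setdiff(here$name, index_name)) {
    x <- rhdf5::h5read(path, paste0(group, "/", nm))
    if (is.list(x) && !is.null(x$categories)) {
      cols[[nm]] <- as.character(x$categories)[as.integer(x$codes) + 1L]
    } else {
      cols[[nm]] <- as.vector(x)
    }
  }
  list(index = idx, columns = cols)
}

#' Read a dataset from an h5ad container
#'
#' Understands dense and CSR/CSC-encoded `X`, and string, categorical or
#' numeric `obs` columns.
#'
#' @param path Path to the h5ad file.
#' @param batch_key Name of the `obs` column holding batch labels.
#' @param label_key Optional name of the `obs` column holding true type
#'   labels.
#' @return A `bn_dataset` in the `raw_counts` state.
#' @export
read_h5ad <- function(path, batch_key = "batch", label_key = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  m <- h5ad_read_x(path)
  obs <- h5ad_read_df(path, "obs")
  var <- h5ad_read_df(path, "var")
  if (!batch_key %in% names(obs$columns))
    stop("batch_key '", batch_key, "' not found in obs", call. = FALSE)
  type_label <- NULL
  if (!is.null(label_key)) {
    if (!label_key %in% names(obs$columns))
      stop("label_key '", label_key, "' not found in obs", call. = FALSE)
    type_label <- obs$columns[[label_key]]
  }
  bn_dataset(m, batch = obs$columns[[batch_key]], cell_ids = obs$index,
             gene_ids = var$index, type_label = type_label,
             layer_state = "raw_counts")
}

#' Write integration results back into an h5ad container
#'
#' Adds the corrected embedding under `obsm/X_corrected` and the global
#' cluster labels as the `obs/global_cluster` column of an existing h5ad
#' file.
#'
#' @param path Path to an existing h5ad file.
#' @param embedding A corrected `bn_embedding`.
#' @param labels Per-cell global cluster labels.
#' @return `path`, invisibly.
#' @export
h5ad_write_result <- function(path, embedding, labels) {
  stopifnot(inherits(embedding, "bn_embedding"))
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls <- rhdf5::h5ls(path)
  if (!any(ls$group == "/" & ls$name == "obsm"))
    rhdf5::h5createGroup(path, "obsm")
  if (any(ls$group == "/obsm" & ls$name == "X_corrected"))
    rhdf5::h5delete(path, "obsm/X_corrected")
  rhdf5::h5write(t(embedding$coords), path, "obsm/X_corrected")
  h5_encoding(path, "obsm/X_corrected", "array", "0.2.0")
  if (any(ls$group == "/obs" & ls$name == "global_cluster"))
    rhdf5::h5delete(path, "obs/global_cluster")
  h5_write_string_array(path, "obs/global_cluster", as.character(labels))
  invisible(path)
}
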