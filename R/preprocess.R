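#' Quality-control filtering
#'
#' Removes low-quality cells expressing fewer than `min_genes` genes (a gene
#' counts as expressed in a cell when its count is > 0), then removes genes
#' expressed in fewer than `min_cells` of the *remaining* cells. Because
#' removing genes can push further cells below the cell threshold, the two
#' passes repeat — cells first, then genes — until nothing changes, so the
#' filter is idempotent.
#'
#' @param ds A `bn_dataset` with `layer_state == "raw_counts"`.
#' @param min_genes Minimum number of expressed genes per cell (default 10).
#' @param min_cells Minimum number of expressing cells per gene (default 3).
#' @return The filtered `bn_dataset`, still in the `raw_counts` state.
#' @export
qc_filter <- function(ds, min_genes = 10L, min_cells = 3L) {
  stopifnot(inherits(ds, "bn_dataset"))
  if (ds$layer_state != "raw_counts")
    stop("qc_filter expects raw counts", call. = FALSE)
  repeat {
    genes_per_cell <- rowSums(ds$matrix > 0)
    keep_cells <- genes_per_cell >= min_genes
    if (!any(keep_cells))
      stop(sprintf(paste0("all cells removed by QC (thresholds: >= %d ",
                          "expressed genes per cell, >= %d expressing cells ",
                          "per gene)"),
                   min_genes, min_cells), call. = FALSE)
    ds <- subset_dataset(ds, cells = which(keep_cells))
    cells_per_gene <- colSums(ds$matrix > 0)
    keep_genes <- cells_per_gene >= min_cells
    ds <- subset_dataset(ds, genes = which(keep_genes))
    if (all(keep_cells) && all(keep_genes)) break
  }
  ds
}

#' Library-size normalisation with log1p transform
#'
#' Divides each cell's counts by the cell total, multiplies by a fixed scale
#' factor (10 000), and applies `log1p`. Zero counts stay zero.
#'
#' @param ds A `bn_dataset` in the `raw_counts` state.
#' @param scale_factor Post-normalisation target total per cell (default 1e4).
#' @return A `bn_dataset` with `layer_state == "normalized"`.
#' @export
normalize_log1p <- function(ds, scale_factor = 1e4) {
  stopifnot(inherits(ds, "bn_dataset"))
  if (ds$layer_state != "raw_counts")
    stop("normalize_log1p expects raw counts", call. = FALSE)
  totals <- rowSums(ds$matrix)
  if (any(totals == 0))
    stop("cells with zero total counts present; run qc_filter first",
         call. = FALSE)
  m <- as.matrix(ds$matrix)
  m <- log1p(m / totals * scale_factor)
  ds$matrix <- m
  ds$layer_state <- "normalized"
  ds
}

# Normalized dispersion of each gene, computed on the log-normalized layer:
# dispersion = variance/mean per gene, z-scored within 20 equal-frequency
# bins of mean expression (the Seurat/scanpy "seurat" flavour). Ties are
# broken by gene ID so the ranking is fully deterministic.
gene_dispersion <- function(m, n_bins = 20L) {
  mu <- colMeans(m)
  v <- colMeans(m^2) - mu^2
  disp <- ifelse(mu > 0, v / mu, 0)
  qs <- unique(stats::quantile(mu, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(mu, breaks = qs, include.lowest = TRUE)
  bmean <- tapply(disp, bin, mean)
  bsd <- tapply(disp, bin, stats::sd)
  bsd[is.na(bsd) | bsd == 0] <- 1
  (disp - bmean[bin]) / bsd[bin]
}

#' Select highly variable genes
#'
#' Ranks genes by binned normalized dispersion on the log-normalized layer
#' (dispersion = variance/mean, z-scored within 20 mean-expression bins) and
#' keeps the top `n_hvg`. The ranking is global across all cells and batches,
#' since the downstream MNN search operates in one shared PCA space.
#'
#' @param ds A `bn_dataset` in the `normalized` state.
#' @param n_hvg Number of genes to keep (default 2000). When `n_hvg` is at
#'   least the number of genes present, the dataset is returned unchanged.
#' @return A `bn_dataset` restricted to the selected genes, in their original
#'   column order.
#' @export
select_hvg <- function(ds, n_hvg = 2000L) {
  stopifnot(inherits(ds, "bn_dataset"))
  if (ds$layer_state != "normalized")
    stop("select_hvg expects the normalized layer", call. = FALSE)
  if (n_hvg <= 0) stop("n_hvg must be positive", call. = FALSE)
  if (n_hvg >= ncol(ds$matrix)) return(ds)
  score <- gene_dispersion(as.matrix(ds$matrix))
  ord <- order(-score, ds$gene_ids)
  keep <- sort(ord[seq_len(n_hvg)])
  subset_dataset(ds, genes = keep)
}

#' Z-score scaling of genes
#'
#' Centers each gene and divides by its population (1/N) standard deviation
#' so every nondegenerate gene has mean 0 and variance 1 across cells.
#' Zero-variance genes become all-zero columns.
#'
#' @param ds A `bn_dataset` in the `normalized` state (typically HVG-subset).
#' @return A `bn_dataset` with `layer_state == "scaled"`.
#' @export
zscore_scale <- function(ds) {
  stopifnot(inherits(ds, "bn_dataset"))
  if (ds$layer_state != "normalized")
    stop("zscore_scale expects the normalized layer", call. = FALSE)
  m <- as.matrix(ds$matrix)
  mu <- colMeans(m)
  sd_pop <- sqrt(colMeans(m^2) - mu^2)
  m <- sweep(m, 2, mu)
  nz <- sd_pop > 0
  m[, nz] <- sweep(m[, nz, drop = FALSE], 2, sd_pop[nz], "/")
  m[, !nz] <- 0
  ds$matrix <- m
  ds$layer_state <- "scaled"
  ds
}

#' Principal component embedding
#'
#' Exact PCA of the scaled matrix (centered; already unit-variance columns),
#' retaining the top `n_pcs` components ordered by decreasing explained
#' variance. A deterministic sign convention is applied: within each
#' component, the loading of largest magnitude is made positive.
#'
#' @param ds A `bn_dataset` in the `scaled` state.
#' @param n_pcs Number of components to retain (default 100); capped at the
#'   matrix rank.
#' @return A `bn_embedding` in the `"pca"` space, with attribute
#'   `"explained_variance"` holding the per-component variances.
#' @export
pca_embed <- function(ds, n_pcs = 100L) {
  stopifnot(inherits(ds, "bn_dataset"))
  if (ds$layer_state != "scaled")
    stop("pca_embed expects the scaled layer", call. = FALSE)
  if (n_pcs < 1) stop("n_pcs must be >= 1", call. = FALSE)
  m <- as.matrix(ds$matrix)
  m <- sweep(m, 2, colMeans(m))   # guard: exact centering
  sv <- svd(m, nu = min(n_pcs, dim(m)), nv = 0)
  tol <- max(dim(m)) * .Machine$double.eps * sv$d[1]
  rank <- sum(sv$d > tol)
  d <- min(n_pcs, rank)
  scores <- sv$u[, seq_len(d), drop = FALSE] %*% diag(sv$d[seq_len(d)], d)
  # sign convention: largest-magnitude score coordinate positive per component
  for (j in seq_len(d)) {
    i_max <- which.max(abs(scores[, j]))
    if (scores[i_max, j] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("PC", seq_len(d))
  emb <- bn_embedding(scores, ds$cell_ids, space = "pca")
  attr(emb, "explained_variance") <- sv$d[seq_len(d)]^2 / nrow(m)
  emb
}

#' Run the full preprocessing workflow
#'
#' Convenience wrapper chaining [qc_filter()], [normalize_log1p()],
#' [select_hvg()], [zscore_scale()] and [pca_embed()].
#'
#' @param ds A raw-count `bn_dataset`.
#' @param cfg A [bn_config()]; `n_hvg` and `n_pcs_global` are used.
#' @return A list with the preprocessed `dataset` (scaled HVG matrix) and the
#'   PCA `embedding`.
#' @export
preprocess <- function(ds, cfg = bn_config()) {
  ds <- qc_filter(ds)
  ds <- normalize_log1p(ds)
  ds <- select_hvg(ds, n_hvg = cfg$n_hvg)
  ds <- zscore_scale(ds)
  emb <- pca_embed(ds, n_pcs = cfg$n_pcs_global)
  list(dataset = ds, embedding = emb)
}
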