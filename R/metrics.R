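#' Adjusted Rand index
#'
#' Chance-adjusted agreement between a predicted clustering and reference
#' labels, computed from the contingency table by the Hubert-Arabie
#' pair-counting formula. 1 means a perfect match; values near 0 are
#' expected for random clusterings; negative values are possible.
#'
#' @param pred,truth Equal-length label vectors (>= 2 cells).
#' @return The ARI value.
#' @export
metric_ari <- function(pred, truth) {
  check_labels(pred, truth)
  tab <- table(pred, truth)
  n <- sum(tab)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  expected <- sum_a * sum_b / choose2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)   # both partitions trivial
  (sum_ij - expected) / (max_idx - expected)
}

#' Normalized mutual information
#'
#' Mutual information between two labelings normalized by the arithmetic
#' mean of their entropies (natural logarithms; the ratio is base
#' invariant): `2 I(pred; truth) / (H(pred) + H(truth))`. Ranges from 0 (no
#' mutual information) to 1 (perfect agreement). When both labelings are
#' single-class, both entropies vanish and the value is 1 by convention.
#'
#' @param pred,truth Equal-length label vectors (>= 2 cells).
#' @return The NMI value.
#' @export
metric_nmi <- function(pred, truth) {
  check_labels(pred, truth)
  tab <- table(pred, truth)
  n <- sum(tab)
  pij <- tab / n
  pi_ <- rowSums(pij); pj_ <- colSums(pij)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  h1 <- ent(pi_); h2 <- ent(pj_)
  if (h1 + h2 == 0) return(1)
  outer_p <- outer(pi_, pj_)
  pos <- pij > 0
  mi <- sum(pij[pos] * log(pij[pos] / outer_p[pos]))
  2 * mi / (h1 + h2)
}

check_labels <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("label vectors must have equal length", call. = FALSE)
  if (length(pred) < 2) stop("need at least 2 cells", call. = FALSE)
}

#' Cell-type average silhouette width, rescaled to the unit interval
#'
#' Per-cell silhouette `s_i = (b_i - a_i) / max(a_i, b_i)` under Euclidean
#' distance in the embedding, where `a_i` is the mean distance to the other
#' cells of cell i's type and `b_i` the minimum over other types of the mean
#' distance to that type. Cells in singleton types get `s_i = 0`. The mean
#' silhouette is mapped to `[0, 1]` as `(mean + 1) / 2`, so 1 indicates
#' well-separated types and 0.5 corresponds to no separation.
#'
#' @param emb A `bn_embedding`.
#' @param types Per-cell type labels (>= 2 distinct types).
#' @return ASW_celltype in `[0, 1]`.
#' @export
metric_asw_celltype <- function(emb, types) {
  x <- if (inherits(emb, "bn_embedding")) emb$coords else as.matrix(emb)
  types <- as.character(types)
  if (length(unique(types)) < 2)
    stop("silhouette needs at least two types", call. = FALSE)
  # stats::dist computes coordinate differences directly, which is more
  # accurate than the a^2 + b^2 - 2ab expansion used for neighbour search
  d <- as.matrix(stats::dist(x))
  n <- nrow(x)
  lv <- unique(types)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- types == types[i]
    n_own <- sum(own) - 1L
    if (n_own == 0L) { s[i] <- 0; next }
    a_i <- sum(d[i, own]) / n_own         # d[i,i] = 0 drops out
    b_i <- min(vapply(lv[lv != types[i]],
                      function(l) mean(d[i, types == l]), 1.0))
    s[i] <- (b_i - a_i) / max(a_i, b_i)
  }
  (mean(s) + 1) / 2
}

# k nearest neighbours of every cell (Euclidean, self excluded).
knn_indices <- function(x, k) {
  d <- euclidean_dist(x)
  knn_from_dist(d, k, exclude_self = TRUE)
}

#' Batch-mixing deviation score (iLISI variant)
#'
#' For each cell, the inverse Simpson index of batch proportions among its
#' `k_lisi` nearest neighbours (self excluded) measures how many batches mix
#' locally. An ideally integrated cell of type p should score close to
#' `N_i`, the number of batches in which type p occurs. The reported score
#' averages the relative deviation `|iLISI(i) - N_i| / N_i` within each
#' batch, then across batches, so *lower is better* and 0 is ideal mixing.
#'
#' @param emb A `bn_embedding`.
#' @param batch Per-cell batch labels.
#' @param types Per-cell type labels (required: the ideal neighbourhood
#'   diversity depends on where each type occurs).
#' @param k_lisi Neighbourhood size (default 90, capped at n-1).
#' @return The mean deviation score (>= 0).
#' @export
metric_ilisi <- function(emb, batch, types, k_lisi = 90L) {
  x <- if (inherits(emb, "bn_embedding")) emb$coords else as.matrix(emb)
  if (is.null(types)) stop("type labels are required for this score",
                           call. = FALSE)
  batch <- as.character(batch); types <- as.character(types)
  n <- nrow(x)
  k <- min(k_lisi, n - 1L)
  nn <- knn_indices(x, k)
  # N_i: number of batches in which cell i's type occurs
  type_batches <- tapply(batch, types, function(b) length(unique(b)))
  N <- as.numeric(type_batches[types])
  ilisi_cell <- vapply(seq_len(n), function(i) {
    p <- table(batch[nn[i, ]]) / k
    1 / sum(p^2)
  }, 1.0)
  dev <- abs(ilisi_cell - N) / N
  mean(vapply(unique(batch), function(b) mean(dev[batch == b]), 1.0))
}

#' Kullback-Leibler divergence of local batch mixing
#'
#' Compares the batch composition of each cell's neighbourhood (`p`,
#' estimated from the `k_kl` nearest neighbours, self excluded) with the
#' global batch proportions (`q`) via `KL(p || q) = sum_b p_b log(p_b/q_b)`
#' (terms with `p_b = 0` are omitted). Per-cell divergences are averaged
#' over a seeded subsample of `min(1000, n)` cells; the subsample is drawn
#' in sorted cell-ID order so the value does not depend on cell order.
#' Lower values indicate better mixing; 0 means local composition equals the
#' global one everywhere.
#'
#' @param emb A `bn_embedding`.
#' @param batch Per-cell batch labels. A single batch returns 0 with a
#'   warning.
#' @param seed Seed of the evaluation-cell subsample.
#' @param k_kl Neighbourhood size (default 100, capped at n-1).
#' @param n_eval Number of evaluation cells (default 1000).
#' @return The mean local KL divergence (>= 0).
#' @export
metric_batch_kl <- function(emb, batch, seed = 0L, k_kl = 100L,
                            n_eval = 1000L) {
  x <- if (inherits(emb, "bn_embedding")) emb$coords else as.matrix(emb)
  ids <- if (inherits(emb, "bn_embedding")) emb$cell_ids
         else as.character(seq_len(nrow(x)))
  batch <- as.character(batch)
  lv <- sort(unique(batch))
  if (length(lv) < 2) {
    warning("only one batch present; BatchKL is 0 by convention",
            call. = FALSE)
    return(0)
  }
  n <- nrow(x)
  k <- min(k_kl, n - 1L)
  q <- as.vector(table(factor(batch, levels = lv))) / n
  ord <- order(ids)                      # order-invariant subsample
  n_sub <- min(n_eval, n)
  pick <- withr::with_seed(seed, sort(sample(ord, n_sub)))
  nn <- knn_indices(x, k)
  kl <- vapply(pick, function(i) {
    p <- as.vector(table(factor(batch[nn[i, ]], levels = lv))) / k
    pos <- p > 0
    sum(p[pos] * log(p[pos] / q[pos]))
  }, 1.0)
  mean(kl)
}

#' Composite biological-conservation score
#'
#' Arithmetic mean of ARI, NMI and ASW_celltype.
#'
#' @param ari,nmi,asw The three base scores.
#' @return `(ari + nmi + asw) / 3`.
#' @export
biological_conservation <- function(ari, nmi, asw) (ari + nmi + asw) / 3

#' Composite batch-mixing score
#'
#' Combines BatchKL and the iLISI deviation score as
#' `((3 - BatchKL)/3 + iLISI/3) / 2`, with BatchKL clipped to `[0, 3]`
#' before use.
#'
#' @param batch_kl The BatchKL value.
#' @param ilisi The iLISI deviation value.
#' @return The composite score.
#' @export
batch_mixing <- function(batch_kl, ilisi) {
  bk <- min(max(batch_kl, 0), 3)
  ((3 - bk) / 3 + ilisi / 3) / 2
}

#' Full integration metric report
#'
#' Computes the five base metrics and the two composites for one embedding.
#'
#' @param emb A `bn_embedding` (typically the corrected space).
#' @param batch Per-cell batch labels.
#' @param types Per-cell true type labels.
#' @param pred Predicted per-cell cluster labels compared against `types`
#'   for ARI/NMI.
#' @param seed Seed of the BatchKL subsample.
#' @param k_lisi,k_kl Neighbourhood sizes of the two mixing metrics.
#' @return A list of class `bn_metric_report` with fields `ari`, `nmi`,
#'   `asw_celltype`, `ilisi`, `batch_kl`, `biological_conservation`,
#'   `batch_mixing`, and the neighbourhood parameters used.
#' @export
evaluate_integration <- function(emb, batch, types, pred, seed = 0L,
                                 k_lisi = 90L, k_kl = 100L) {
  ari <- metric_ari(pred, types)
  nmi <- metric_nmi(pred, types)
  asw <- metric_asw_celltype(emb, types)
  il <- metric_ilisi(emb, batch, types, k_lisi = k_lisi)
  bk <- metric_batch_kl(emb, batch, seed = seed, k_kl = k_kl)
  structure(list(ari = ari, nmi = nmi, asw_celltype = asw, ilisi = il,
                 batch_kl = bk,
                 biological_conservation = biological_conservation(ari, nmi, asw),
                 batch_mixing = batch_mixing(bk, il),
                 k_lisi = k_lisi, k_kl = k_kl),
            class = "bn_metric_report")
}

#' @export
print.bn_metric_report <- function(x, ...) {
  cat("<bn_metric_report>\n")
  for (nm in c("ari", "nmi", "asw_celltype", "ilisi", "batch_kl",
               "biological_conservation", "batch_mixing"))
    cat(sprintf("  %-24s %.4f\n", nm, x[[nm]]))
  invisible(x)
}
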