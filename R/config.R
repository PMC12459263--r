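#' Pipeline configuration
#'
#' Collects every tunable parameter of the integration pipeline with its
#' default. Defaults follow the method's reference settings: Leiden
#' resolution 3.0, 100 global PCs, MNN search on the first 10 PCs with
#' k = 10 mutual neighbours, and T = 10 random-walk expansion steps.
#'
#' @param leiden_resolution Resolution of the per-batch Leiden clustering
#'   (> 0). Higher values give finer initial clusters; default 3.0.
#' @param n_pcs_global Number of principal components retained after
#'   preprocessing (default 100). This space feeds the Leiden clustering and
#'   the correction network.
#' @param n_pcs_mnn Number of leading PCs used for the cosine-distance MNN
#'   search (default 10); must not exceed `n_pcs_global`.
#' @param knn_k Neighbourhood size k of the mutual nearest-neighbour search
#'   (default 10).
#' @param walk_steps Number of expansion steps T of the nearest-neighbour
#'   walk over MNN pairs (default 10).
#' @param snn_k Neighbourhood size of the shared-nearest-neighbour graph
#'   underlying Leiden (default 15).
#' @param n_spectral_groups Number of spectral groups, or `"auto"` to choose
#'   it by the largest eigengap among the first `min(20, n_nodes)` Laplacian
#'   eigenvalues.
#' @param cluster_size_norm `"product"` divides MNN counts by the product of
#'   the two cluster sizes (pair capacity); `"sqrt"` divides by its square
#'   root.
#' @param n_hvg Number of highly variable genes kept (default 2000).
#' @param embed_dim Output dimension of the correction network (default 32).
#' @param k_tuple Tuple size of the tuplet margin loss: one anchor-positive
#'   pair contrasted against `k_tuple - 1` negatives (default 4).
#' @param epochs,batch_size,learning_rate,momentum Mini-batch SGD settings
#'   (defaults 50 epochs, 256 tuplets per step, lr 0.01, momentum 0.9).
#' @param k_lisi Neighbourhood size of the per-cell inverse Simpson index
#'   (default 90).
#' @param k_kl Neighbourhood size of the local batch proportions in BatchKL
#'   (default 100).
#' @param rng_seed Global seed; per-stage seeds are derived from it (see
#'   [derive_seed()]).
#'
#' @return A list of class `bn_config`.
#' @export
bn_config <- function(leiden_resolution = 3.0,
                      n_pcs_global = 100L,
                      n_pcs_mnn = 10L,
                      knn_k = 10L,
                      walk_steps = 10L,
                      snn_k = 15L,
                      n_spectral_groups = "auto",
                      cluster_size_norm = c("product", "sqrt"),
                      n_hvg = 2000L,
                      embed_dim = 32L,
                      k_tuple = 4L,
                      epochs = 50L,
                      batch_size = 256L,
                      learning_rate = 0.01,
                      momentum = 0.9,
                      k_lisi = 90L,
                      k_kl = 100L,
                      rng_seed = 0L) {
  cluster_size_norm <- match.arg(cluster_size_norm)
  cfg <- list(leiden_resolution = leiden_resolution,
              n_pcs_global = as.integer(n_pcs_global),
              n_pcs_mnn = as.integer(n_pcs_mnn),
              knn_k = as.integer(knn_k),
              walk_steps = as.integer(walk_steps),
              snn_k = as.integer(snn_k),
              n_spectral_groups = n_spectral_groups,
              cluster_size_norm = cluster_size_norm,
              n_hvg = as.integer(n_hvg),
              embed_dim = as.integer(embed_dim),
              k_tuple = as.integer(k_tuple),
              epochs = as.integer(epochs),
              batch_size = as.integer(batch_size),
              learning_rate = learning_rate,
              momentum = momentum,
              k_lisi = as.integer(k_lisi),
              k_kl = as.integer(k_kl),
              rng_seed = as.integer(rng_seed))
  counts <- c("n_pcs_global", "n_pcs_mnn", "knn_k", "snn_k", "n_hvg",
              "embed_dim", "k_tuple", "batch_size", "k_lisi", "k_kl")
  for (nm in counts)
    if (cfg[[nm]] < 1L) stop(nm, " must be a positive integer", call. = FALSE)
  if (cfg$walk_steps < 0L) stop("walk_steps must be >= 0", call. = FALSE)
  if (cfg$epochs < 0L) stop("epochs must be >= 0", call. = FALSE)
  if (cfg$leiden_resolution <= 0) stop("leiden_resolution must be > 0", call. = FALSE)
  if (cfg$n_pcs_mnn > cfg$n_pcs_global)
    stop("n_pcs_mnn cannot exceed n_pcs_global", call. = FALSE)
  if (cfg$k_tuple < 2L) stop("k_tuple must be >= 2 (needs >= 1 negative)", call. = FALSE)
  if (!identical(n_spectral_groups, "auto") &&
      (!is.numeric(n_spectral_groups) || n_spectral_groups < 1))
    stop("n_spectral_groups must be a positive integer or \"auto\"", call. = FALSE)
  structure(cfg, class = "bn_config")
}

# Fixed per-stage offsets; each stage draws from an independent, documented
# stream so stages can be re-run in isolation with identical results.
.stage_offsets <- c(simulate = 11L, leiden = 23L, spectral = 37L,
                    tuplets = 53L, network = 71L, metrics = 89L)

#' Derive a per-stage seed from the global seed
#'
#' Deterministic fan-out of one global seed into independent per-stage seeds,
#' so that individual stages (Leiden, tuplet sampling, network initialisation,
#' metric subsampling) are reproducible in isolation. The derivation is
#' `(seed * 10007 + offset * 7919) mod (2^31 - 1)` with a fixed documented
#' offset per stage name.
#'
#' @param seed Integer global seed.
#' @param stage One of `"simulate"`, `"leiden"`, `"spectral"`, `"tuplets"`,
#'   `"network"`, `"metrics"`.
#' @return A nonnegative integer seed below 2^31.
#' @export
derive_seed <- function(seed, stage) {
  if (!stage %in% names(.stage_offsets))
    stop("unknown stage: ", stage, call. = FALSE)
  off <- .stage_offsets[[stage]]
  m <- 2147483647
  as.integer((as.numeric(seed) %% m * 10007 + as.numeric(off) * 7919) %% m)
}
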