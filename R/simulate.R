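#' Simulation parameters
#'
#' Parameter block of the Splatter-style multi-batch, multi-type
#' negative-binomial count generator. The generative recipe
#' (see [simulate_counts()]) is: gamma-distributed base gene means,
#' per-type multiplicative differential-expression factors on a random gene
#' subset, per-batch multiplicative factors on all genes, log-normal
#' library sizes, and negative-binomial sampling.
#'
#' @param n_cells Total number of cells; split across batches by
#'   `batch_proportions`.
#' @param n_genes Number of genes.
#' @param n_types Number of cell types (>= 2).
#' @param n_batches Number of batches (>= 1).
#' @param type_proportions Either one probability vector of length
#'   `n_types`, or a `n_batches x n_types` matrix with one composition per
#'   batch (rows sum to 1) to emulate unbalanced compositions.
#' @param batch_proportions Fraction of cells in each batch (sums to 1).
#' @param de_prob Probability that a gene is differentially expressed in a
#'   given type (default 0.1).
#' @param de_facLoc,de_facScale Location and scale of the log-normal DE
#'   factors (defaults 1.0 and 0.4); each DE factor is inverted with
#'   probability 1/2 so expression moves in both directions.
#' @param batch_facLoc,batch_facScale Location and scale of the log-normal
#'   batch factors applied to all genes (defaults 0.15, 0.15).
#' @param lib_loc,lib_scale Meanlog and sdlog of the log-normal library
#'   sizes (defaults log(10000) ~ 9.21, 0.25).
#' @param mean_shape,mean_rate Shape and rate of the gamma base gene means
#'   (defaults 0.6, 0.3).
#' @param nb_size Negative-binomial size (inverse dispersion, default 10).
#' @param seed Integer seed.
#' @return A validated list of class `bn_sim_params`.
#' @export
sim_params <- function(n_cells = 2000L, n_genes = 2000L, n_types = 4L,
                       n_batches = 3L,
                       type_proportions = NULL,
                       batch_proportions = NULL,
                       de_prob = 0.1, de_facLoc = 1.0, de_facScale = 0.4,
                       batch_facLoc = 0.15, batch_facScale = 0.15,
                       lib_loc = log(1e4), lib_scale = 0.25,
                       mean_shape = 0.6, mean_rate = 0.3,
                       nb_size = 10, seed = 0L) {
  if (n_types < 2) stop("n_types must be >= 2", call. = FALSE)
  if (n_batches < 1) stop("n_batches must be >= 1", call. = FALSE)
  if (is.null(type_proportions))
    type_proportions <- rep(1 / n_types, n_types)
  if (is.null(dim(type_proportions)))
    type_proportions <- matrix(type_proportions, n_batches, n_types,
                               byrow = TRUE)
  if (!all(abs(rowSums(type_proportions) - 1) < 1e-8))
    stop("type proportions must sum to 1 per batch", call. = FALSE)
  if (is.null(batch_proportions))
    batch_proportions <- rep(1 / n_batches, n_batches)
  if (abs(sum(batch_proportions) - 1) > 1e-8)
    stop("batch proportions must sum to 1", call. = FALSE)
  for (nm in c("de_facScale", "batch_facScale", "lib_scale", "mean_shape",
               "mean_rate", "nb_size"))
    if (get(nm) <= 0) stop(nm, " must be positive", call. = FALSE)
  structure(list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                 n_types = as.integer(n_types),
                 n_batches = as.integer(n_batches),
                 type_proportions = type_proportions,
                 batch_proportions = batch_proportions,
                 de_prob = de_prob, de_facLoc = de_facLoc,
                 de_facScale = de_facScale, batch_facLoc = batch_facLoc,
                 batch_facScale = batch_facScale, lib_loc = lib_loc,
                 lib_scale = lib_scale, mean_shape = mean_shape,
                 mean_rate = mean_rate, nb_size = nb_size,
                 seed = as.integer(seed)),
            class = "bn_sim_params")
}

#' Simulate multi-batch, multi-type single-cell counts
#'
#' Splatter-style generative model. Step by step:
#' 1. Base gene means `mu_g ~ Gamma(mean_shape, rate = mean_rate)`.
#' 2. For each type t, genes are flagged DE with probability `de_prob`;
#'    flagged genes get factor `f = exp(N(de_facLoc, de_facScale))`,
#'    inverted (`1/f`) with probability 1/2. Type means are
#'    `mu_gt = mu_g * f_gt`.
#' 3. For each batch m, every gene gets factor
#'    `g = exp(N(batch_facLoc, batch_facScale))`, inverted with probability
#'    1/2, giving `mu_gtm = mu_gt * g_gm`.
#' 4. Cell counts per (batch, type) follow `batch_proportions` and the
#'    per-batch `type_proportions` rows exactly (largest-remainder
#'    rounding).
#' 5. Library sizes `L_c ~ LogNormal(lib_loc, lib_scale)`; the expected
#'    count of gene g in cell c is `L_c * mu_gtm / sum_g mu_gtm`.
#' 6. Observed counts are negative binomial with that mean and size
#'    `nb_size`.
#'
#' @param p A [sim_params()] object.
#' @return A raw-count `bn_dataset` with `batch` and `type_label` set, and
#'   attributes `"de_genes"` (type x gene DE flags) and `"sim_params"`.
#' @export
simulate_counts <- function(p) {
  stopifnot(inherits(p, "bn_sim_params"))
  withr::with_seed(p$seed, {
    G <- p$n_genes
    mu <- stats::rgamma(G, shape = p$mean_shape, rate = p$mean_rate)
    de_flag <- matrix(FALSE, p$n_types, G)
    de_fac <- matrix(1, p$n_types, G)
    for (t in seq_len(p$n_types)) {
      de_flag[t, ] <- stats::runif(G) < p$de_prob
      f <- exp(stats::rnorm(G, p$de_facLoc, p$de_facScale))
      inv <- stats::runif(G) < 0.5
      f[inv] <- 1 / f[inv]
      de_fac[t, de_flag[t, ]] <- f[de_flag[t, ]]
    }
    batch_fac <- matrix(1, p$n_batches, G)
    for (m in seq_len(p$n_batches)) {
      g <- exp(stats::rnorm(G, p$batch_facLoc, p$batch_facScale))
      inv <- stats::runif(G) < 0.5
      batch_fac[m, inv] <- 1 / g[inv]
      batch_fac[m, !inv] <- g[!inv]
    }
    n_per_batch <- largest_remainder(p$batch_proportions * p$n_cells)
    batch <- character(0); type <- character(0)
    for (m in seq_len(p$n_batches)) {
      n_per_type <- largest_remainder(p$type_proportions[m, ] * n_per_batch[m])
      batch <- c(batch, rep(paste0("batch", m), n_per_batch[m]))
      type <- c(type, rep(paste0("type", seq_len(p$n_types)), n_per_type))
    }
    n <- length(batch)
    lib <- stats::rlnorm(n, p$lib_loc, p$lib_scale)
    counts <- matrix(0L, n, G)
    t_idx <- as.integer(sub("type", "", type))
    m_idx <- as.integer(sub("batch", "", batch))
    for (i in seq_len(n)) {
      mu_cell <- mu * de_fac[t_idx[i], ] * batch_fac[m_idx[i], ]
      lambda <- lib[i] * mu_cell / sum(mu_cell)
      counts[i, ] <- stats::rnbinom(G, size = p$nb_size, mu = lambda)
    }
    ds <- bn_dataset(counts,
                     batch = batch,
                     cell_ids = sprintf("cell%04d", seq_len(n)),
                     gene_ids = sprintf("gene%04d", seq_len(G)),
                     type_label = type,
                     layer_state = "raw_counts")
    attr(ds, "de_genes") <- de_flag
    attr(ds, "sim_params") <- p
    ds
  })
}

largest_remainder <- function(x) {
  fl <- floor(x)
  rem <- round(sum(x)) - sum(fl)
  out <- fl
  if (rem > 0) {
    ord <- order(-(x - fl), seq_along(x))
    out[ord[seq_len(rem)]] <- out[ord[seq_len(rem)]] + 1
  }
  as.integer(out)
}

#' The frozen four-type, three-batch benchmark simulation
#'
#' Reference fixture used throughout the test and acceptance suites: four
#' cell types across three batches (~2000 cells, 2000 genes) with strong
#' type separation (DE prob 0.1, factor location 1.0) and moderate batch
#' effects (factor location 0.15 on all genes) so that raw PCA shows
#' batch-driven separation while types remain separable. Per-batch type
#' compositions are mildly unbalanced (30/30/20/20, balanced, 20/20/30/30).
#' All generator parameters are frozen here; only the seed varies.
#'
#' @param seed Integer seed.
#' @return A raw-count `bn_dataset` with 3 batch labels and 4 type labels.
#' @export
make_dataset1_analog <- function(seed = 0L) {
  props <- rbind(c(0.30, 0.30, 0.20, 0.20),
                 c(0.25, 0.25, 0.25, 0.25),
                 c(0.20, 0.20, 0.30, 0.30))
  simulate_counts(sim_params(
    n_cells = 2000L, n_genes = 2000L, n_types = 4L, n_batches = 3L,
    type_proportions = props,
    batch_proportions = c(0.35, 0.325, 0.325),
    de_prob = 0.1, de_facLoc = 1.0, de_facScale = 0.4,
    batch_facLoc = 0.15, batch_facScale = 0.15,
    lib_loc = log(1e4), lib_scale = 0.25,
    mean_shape = 0.6, mean_rate = 0.3, nb_size = 10,
    seed = derive_seed(seed, "simulate")))
}
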