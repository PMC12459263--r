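#' Per-batch high-resolution Leiden clustering
#'
#' First clustering stage: within each batch independently, a shared
#' nearest-neighbour graph (Euclidean k-NN, k = `snn_k`, Jaccard weights) is
#' built in the global PCA space and partitioned with the Leiden algorithm at
#' high resolution, so that each resulting fine-grained cluster contains
#' cells of a single batch. Cluster IDs are prefixed with the batch label.
#'
#' @param emb A `bn_embedding` in the `"pca"` space.
#' @param batch Per-cell batch labels (factor or character).
#' @param resolution Leiden resolution (default 3.0); higher values give
#'   finer clusters, promoting the detection of subtle heterogeneity.
#' @param seed Integer seed for the Leiden refinement.
#' @param snn_k Neighbourhood size of the SNN graph (default 15).
#' @return An object of class `bn_initial_clusters`: list with `assignment`
#'   (per-cell cluster ID, character), `resolution`, and `batch_of_cluster`.
#' @export
leiden_per_batch <- function(emb, batch, resolution = 3.0, seed = 0L,
                             snn_k = 15L) {
  stopifnot(inherits(emb, "bn_embedding"))
  if (emb$space != "pca")
    stop("initial clustering expects the PCA embedding", call. = FALSE)
  batch <- factor(as.character(batch), levels = unique(as.character(batch)))
  n <- nrow(emb$coords)
  stopifnot(length(batch) == n)
  assignment <- character(n)
  for (bi in seq_along(levels(batch))) {
    b <- levels(batch)[bi]
    idx <- which(batch == b)
    if (length(idx) < 2L) {
      warning("batch '", b, "' has fewer than 2 cells; one singleton cluster",
              call. = FALSE)
      assignment[idx] <- paste0(b, ".1")
      next
    }
    xb <- emb$coords[idx, , drop = FALSE]
    if (max(apply(xb, 2, function(cc) max(cc) - min(cc))) == 0) {
      # degenerate batch of identical points: no structure, one cluster
      assignment[idx] <- paste0(b, ".1")
      next
    }
    g <- snn_graph(xb, k = snn_k)
    memb <- withr::with_seed(seed + bi, {
      if (igraph::ecount(g) == 0) {
        rep(1L, length(idx))
      } else {
        igraph::membership(igraph::cluster_leiden(
          g, objective_function = "modularity", resolution = resolution,
          n_iterations = 5L))
      }
    })
    assignment[idx] <- paste0(b, ".", as.integer(memb))
  }
  structure(list(assignment = assignment, resolution = resolution,
                 batch_of_cluster = vapply(
                   split(as.character(batch), assignment), `[`, "", 1L)),
            class = "bn_initial_clusters")
}

new_mnn_pairs <- function(i = integer(), j = integer(),
                          batch_a = character(), batch_b = character(),
                          step = integer()) {
  structure(data.frame(i = as.integer(i), j = as.integer(j),
                       batch_a = batch_a, batch_b = batch_b,
                       step = as.integer(step)),
            class = c("bn_mnn_pairs", "data.frame"))
}

#' Mutual nearest-neighbour pairs between two batches
#'
#' A pair of cells (i in batch a, j in batch b) is an MNN pair if and only if
#' j is among the k nearest neighbours of i within batch b *and* i is among
#' the k nearest neighbours of j within batch a. Distances are cosine
#' distances restricted to the first `n_pcs_mnn` principal components. When
#' `a == b`, a cell is excluded from its own neighbour list and each
#' unordered pair is reported once (i < j), so the pair set captures
#' intra-batch as well as inter-batch relationships.
#'
#' @param emb A `bn_embedding` in the `"pca"` space.
#' @param batch Per-cell batch labels.
#' @param a,b Batch labels with `a` at or before `b` in first-appearance
#'   order.
#' @param k Neighbourhood size (default 10).
#' @param n_pcs_mnn Number of leading PCs used for the search (default 10).
#' @return A `bn_mnn_pairs` data frame with columns `i`, `j` (global cell
#'   indices), `batch_a`, `batch_b`, and `step` (0 for direct MNN pairs).
#' @export
find_mnn_pairs <- function(emb, batch, a, b, k = 10L, n_pcs_mnn = 10L) {
  stopifnot(inherits(emb, "bn_embedding"))
  batch <- factor(as.character(batch), levels = unique(as.character(batch)))
  if (!a %in% levels(batch) || !b %in% levels(batch))
    stop("unknown batch label", call. = FALSE)
  if (match(a, levels(batch)) > match(b, levels(batch)))
    stop("batches must be given in first-appearance order (a before b)",
         call. = FALSE)
  if (n_pcs_mnn > ncol(emb$coords))
    stop("n_pcs_mnn exceeds the embedding dimension", call. = FALSE)
  x <- emb$coords[, seq_len(n_pcs_mnn), drop = FALSE]
  ia <- which(batch == a); ib <- which(batch == b)
  same <- identical(a, b)
  if (same && length(ia) < 2L)
    return(new_mnn_pairs())
  d <- cosine_dist(x[ia, , drop = FALSE], x[ib, , drop = FALSE])
  nn_ab <- knn_row_sets(d, k, exclude_self = same)      # neighbours of a-cells in b
  nn_ba <- knn_row_sets(t(d), k, exclude_self = same)   # neighbours of b-cells in a
  out_i <- integer(); out_j <- integer()
  for (p in seq_along(ia)) {
    for (q in nn_ab[[p]]) {
      if (p %in% nn_ba[[q]]) {
        gi <- ia[p]; gj <- ib[q]
        if (same && gi >= gj) next   # i < j canonical form, no self-pairs
        out_i <- c(out_i, gi); out_j <- c(out_j, gj)
      }
    }
  }
  new_mnn_pairs(out_i, out_j, rep(as.character(a), length(out_i)),
                rep(as.character(b), length(out_i)),
                rep(0L, length(out_i)))
}

knn_row_sets <- function(d, k, exclude_self = FALSE) {
  idx <- knn_from_dist(d, k, exclude_self = exclude_self)
  lapply(seq_len(nrow(idx)), function(i) idx[i, ])
}

#' Expand MNN pairs by a nearest-neighbour walk
#'
#' Grows an initial MNN pair set for `T` steps. At each step, every pair
#' (i, j) added in the previous step proposes two candidates: (i', j) where
#' i' is the within-batch 1-nearest neighbour of i, and (i, j') where j' is
#' the within-batch 1-nearest neighbour of j (cosine distance on the same
#' leading PCs as the MNN search; ties broken by cell index, so the walk is
#' deterministic). Candidates already present are skipped and the expansion
#' stops early at a fixed point. The result is the union of all step sets,
#' with each pair tagged by the step that first produced it.
#'
#' @param s0 A `bn_mnn_pairs` set (step-0 pairs).
#' @param emb The `bn_embedding` the pairs were found in.
#' @param batch Per-cell batch labels.
#' @param T Number of expansion steps (default 10).
#' @param n_pcs_mnn Number of leading PCs for the within-batch 1-NN lookup
#'   (default 10, matching the MNN search space).
#' @return A `bn_mnn_pairs` set containing `s0` and all expansion pairs.
#' @export
random_walk_expand <- function(s0, emb, batch, T = 10L, n_pcs_mnn = 10L) {
  stopifnot(inherits(s0, "bn_mnn_pairs"), T >= 0)
  if (T == 0L || nrow(s0) == 0L) return(s0)
  batch <- factor(as.character(batch), levels = unique(as.character(batch)))
  x <- emb$coords[, seq_len(min(n_pcs_mnn, ncol(emb$coords))), drop = FALSE]
  n <- nrow(x)
  nn1 <- integer(n)   # within-batch 1-NN of every cell
  for (b in levels(batch)) {
    idx <- which(batch == b)
    if (length(idx) < 2L) { nn1[idx] <- idx[1]; next }
    d <- cosine_dist(x[idx, , drop = FALSE], x[idx, , drop = FALSE])
    nn <- knn_from_dist(d, 1L, exclude_self = TRUE)
    nn1[idx] <- idx[nn[, 1]]
  }
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (kk in key(s0$i, s0$j)) assign(kk, TRUE, envir = seen)
  all_pairs <- s0
  frontier <- s0
  for (t in seq_len(T)) {
    ci <- c(nn1[frontier$i], frontier$i)
    cj <- c(frontier$j, nn1[frontier$j])
    ba <- c(frontier$batch_a, frontier$batch_a)
    bb <- c(frontier$batch_b, frontier$batch_b)
    keep <- ci != cj
    ci <- ci[keep]; cj <- cj[keep]; ba <- ba[keep]; bb <- bb[keep]
    kk <- key(ci, cj)
    first <- !duplicated(kk)
    is_new <- vapply(kk, function(z) !exists(z, envir = seen, inherits = FALSE),
                     TRUE)
    newpick <- first & is_new
    if (!any(newpick)) break
    for (z in kk[newpick]) assign(z, TRUE, envir = seen)
    # canonical order: intra-batch pairs stored with i < j
    ni <- ci[newpick]; nj <- cj[newpick]
    swap <- ba[newpick] == bb[newpick] & ni > nj
    tmp <- ni[swap]; ni[swap] <- nj[swap]; nj[swap] <- tmp
    add <- new_mnn_pairs(ni, nj, ba[newpick], bb[newpick],
                         rep(t, sum(newpick)))
    all_pairs <- rbind(all_pairs, add)
    frontier <- add
  }
  class(all_pairs) <- c("bn_mnn_pairs", "data.frame")
  all_pairs
}

#' Find and expand MNN pairs over all batch pairs
#'
#' Runs [find_mnn_pairs()] for every ordered batch pair (a at or before b,
#' including a == b) and expands each set with [random_walk_expand()].
#'
#' @inheritParams find_mnn_pairs
#' @param T Number of walk-expansion steps.
#' @return A combined `bn_mnn_pairs` set.
#' @export
find_all_mnn_pairs <- function(emb, batch, k = 10L, T = 10L, n_pcs_mnn = 10L) {
  batch <- factor(as.character(batch), levels = unique(as.character(batch)))
  lv <- levels(batch)
  out <- list()
  for (ai in seq_along(lv)) {
    for (bi in ai:length(lv)) {
      s0 <- find_mnn_pairs(emb, batch, lv[ai], lv[bi], k = k,
                           n_pcs_mnn = n_pcs_mnn)
      out[[length(out) + 1L]] <-
        random_walk_expand(s0, emb, batch, T = T, n_pcs_mnn = n_pcs_mnn)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("bn_mnn_pairs", "data.frame")
  res
}

#' Build the cluster-level similarity graph
#'
#' Nodes are the initial fine-grained clusters; the weight between clusters
#' c and d is the number of MNN pairs with one endpoint in each, normalized
#' by cluster size: divided by `|c|*|d|` (pair capacity, the default) or by
#' `sqrt(|c|*|d|)`. The diagonal counts intra-cluster pairs under the same
#' normalization. The matrix is symmetric and nonnegative, and zero wherever
#' no MNN pair links two clusters.
#'
#' @param pairs A `bn_mnn_pairs` set.
#' @param init A `bn_initial_clusters` assignment covering every paired cell.
#' @param size_norm `"product"` or `"sqrt"`.
#' @return An object of class `bn_cluster_graph`: list with `weight` (dense
#'   symmetric matrix), `nodes`, and `sizes`.
#' @export
build_cluster_graph <- function(pairs, init, size_norm = c("product", "sqrt")) {
  size_norm <- match.arg(size_norm)
  stopifnot(inherits(pairs, "bn_mnn_pairs"),
            inherits(init, "bn_initial_clusters"))
  nodes <- sort(unique(init$assignment))
  sizes <- as.vector(table(factor(init$assignment, levels = nodes)))
  names(sizes) <- nodes
  m <- length(nodes)
  W <- matrix(0, m, m, dimnames = list(nodes, nodes))
  if (nrow(pairs) > 0) {
    ci <- match(init$assignment[pairs$i], nodes)
    cj <- match(init$assignment[pairs$j], nodes)
    if (anyNA(ci) || anyNA(cj))
      stop("every paired cell must carry an initial cluster", call. = FALSE)
    for (p in seq_along(ci)) {
      W[ci[p], cj[p]] <- W[ci[p], cj[p]] + 1
      if (ci[p] != cj[p]) W[cj[p], ci[p]] <- W[cj[p], ci[p]] + 1
    }
    cap <- outer(sizes, sizes)
    if (size_norm == "sqrt") cap <- sqrt(cap)
    W <- W / cap
  }
  structure(list(weight = W, nodes = nodes, sizes = sizes),
            class = "bn_cluster_graph")
}

# Greedy largest-remainder allocation of `g` groups to components (each gets
# at least one), proportional to component node counts.
allocate_groups <- function(comp_sizes, g) {
  nc <- length(comp_sizes)
  alloc <- rep(1L, nc)
  extra <- g - nc
  if (extra > 0) {
    frac <- comp_sizes / sum(comp_sizes) * extra
    add <- floor(frac)
    rem <- extra - sum(add)
    if (rem > 0) {
      ord <- order(-(frac - add), seq_along(frac))
      add[ord[seq_len(rem)]] <- add[ord[seq_len(rem)]] + 1L
    }
    alloc <- alloc + as.integer(add)
  }
  # never allocate more groups to a component than it has nodes
  over <- alloc - comp_sizes
  while (any(over > 0)) {
    donor <- which.max(over)
    alloc[donor] <- comp_sizes[donor]
    slack <- which(alloc < comp_sizes)
    alloc[slack[1]] <- alloc[slack[1]] + (sum(over[over > 0]))
    over <- alloc - comp_sizes
  }
  alloc
}

spectral_embed_kmeans <- function(W, g, seed) {
  m <- nrow(W)
  if (g >= m) return(seq_len(m))
  if (g == 1L) return(rep(1L, m))
  deg <- rowSums(W)
  dhalf <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  L <- diag(m) - (dhalf * W) %*% diag(dhalf, m)
  ev <- eigen((L + t(L)) / 2, symmetric = TRUE)
  U <- ev$vectors[, m:(m - g + 1), drop = FALSE]  # g smallest eigenvalues
  rn <- sqrt(rowSums(U^2))
  U[rn > 0, ] <- U[rn > 0, , drop = FALSE] / rn[rn > 0]
  uniq <- unique(round(U, 10))
  withr::with_seed(seed, {
    if (nrow(uniq) <= g) {
      match(apply(round(U, 10), 1, paste, collapse = ","),
            apply(uniq, 1, paste, collapse = ","))
    } else {
      stats::kmeans(U, centers = g, nstart = 25, iter.max = 200)$cluster
    }
  })
}

#' Spectral partitioning of the cluster graph
#'
#' Second clustering stage: the symmetric-normalized Laplacian of the
#' cluster-similarity graph is eigendecomposed, initial clusters are embedded
#' in the space of the leading eigenvectors (row-normalized), and k-means
#' with seeded initialisation assigns each initial cluster to a global group.
#' When `n_groups = "auto"`, the number of groups is chosen by the largest
#' eigengap among the first `min(20, n_nodes)` Laplacian eigenvalues.
#' Disconnected graph components are partitioned separately whenever
#' `n_groups` is at least the number of components, so components are never
#' merged in that regime.
#'
#' @param g A `bn_cluster_graph`.
#' @param init The `bn_initial_clusters` the graph was built from.
#' @param n_groups Number of global groups, or `"auto"`.
#' @param seed Integer seed for the k-means initialisation.
#' @return An object of class `bn_global_clusters`: list with `assignment`
#'   (per-cell integer label in `0..n_groups-1`), `n_groups`, and
#'   `group_of_cluster` (named map from initial cluster to group).
#' @export
spectral_partition <- function(g, init, n_groups = "auto", seed = 0L) {
  stopifnot(inherits(g, "bn_cluster_graph"),
            inherits(init, "bn_initial_clusters"))
  W <- g$weight
  m <- nrow(W)
  if (m < 1) stop("cluster graph has no nodes", call. = FALSE)
  if (!identical(n_groups, "auto") && n_groups > m)
    stop("n_groups exceeds the number of initial clusters", call. = FALSE)

  deg <- rowSums(W)
  dhalf <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  L <- diag(m) - (dhalf * W) %*% diag(dhalf, m)
  lambda <- sort(eigen((L + t(L)) / 2, symmetric = TRUE,
                       only.values = TRUE)$values)
  if (identical(n_groups, "auto")) {
    mm <- min(20L, m)
    if (mm < 2L) {
      n_groups <- 1L
    } else {
      gaps <- diff(lambda[seq_len(mm)])
      n_groups <- which.max(gaps)
    }
  }
  n_groups <- as.integer(n_groups)

  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected"))
  group <- integer(m)
  if (n_groups >= comp$no) {
    sizes <- as.vector(table(factor(comp$membership,
                                    levels = seq_len(comp$no))))
    alloc <- allocate_groups(sizes, n_groups)
    offset <- 0L
    for (ci in seq_len(comp$no)) {
      nodes_c <- which(comp$membership == ci)
      sub <- spectral_embed_kmeans(W[nodes_c, nodes_c, drop = FALSE],
                                   alloc[ci], seed + ci)
      group[nodes_c] <- offset + as.integer(sub)
      offset <- offset + alloc[ci]
    }
  } else {
    group <- as.integer(spectral_embed_kmeans(W, n_groups, seed))
  }
  # relabel groups to consecutive 0-based integers in node order
  group <- match(group, unique(group)) - 1L
  names(group) <- g$nodes
  assignment <- group[init$assignment]
  names(assignment) <- NULL
  structure(list(assignment = assignment,
                 n_groups = length(unique(group)),
                 group_of_cluster = group),
            class = "bn_global_clusters")
}

#' Run the full two-stage cross-batch clustering
#'
#' Chains [leiden_per_batch()], [find_all_mnn_pairs()],
#' [build_cluster_graph()] and [spectral_partition()].
#'
#' @param emb A `bn_embedding` in PCA space.
#' @param batch Per-cell batch labels.
#' @param cfg A [bn_config()].
#' @return A list with `initial`, `pairs`, `graph`, and `global`
#'   (a `bn_global_clusters`).
#' @export
cross_batch_cluster <- function(emb, batch, cfg = bn_config()) {
  init <- leiden_per_batch(emb, batch, resolution = cfg$leiden_resolution,
                           seed = derive_seed(cfg$rng_seed, "leiden"),
                           snn_k = cfg$snn_k)
  pairs <- find_all_mnn_pairs(emb, batch, k = cfg$knn_k, T = cfg$walk_steps,
                              n_pcs_mnn = cfg$n_pcs_mnn)
  graph <- build_cluster_graph(pairs, init, size_norm = cfg$cluster_size_norm)
  global <- spectral_partition(graph, init, n_groups = cfg$n_spectral_groups,
                               seed = derive_seed(cfg$rng_seed, "spectral"))
  list(initial = init, pairs = pairs, graph = graph, global = global)
}
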