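test_that("per-batch Leiden keeps batches separate and finds blob structure", {
  bl <- blob_embedding(n_per = 25, n_types = 3, n_batches = 2, sep = 10,
                       seed = 2)
  init <- leiden_per_batch(bl$emb, bl$batch, resolution = 3.0, seed = 1)
  expect_s3_class(init, "bn_initial_clusters")
  # each cluster draws cells from exactly one batch
  tab <- table(init$assignment, bl$batch)
  expect_true(all(rowSums(tab > 0) == 1))
  # at least 3 clusters per batch at resolution 3.0 on 3 separated blobs,
  # and merging clusters by majority type recovers the blobs
  for (b in c("B1", "B2"))
    expect_gte(length(unique(init$assignment[bl$batch == b])), 3)
  coarse <- stats::ave(seq_along(init$assignment), init$assignment,
                       FUN = function(ix) {
                         names(which.max(table(bl$type[ix])))[1]
                       })
  expect_equal(metric_ari(coarse, bl$type), 1)
})

test_that("identical points collapse to one cluster per batch", {
  emb <- bn_embedding(matrix(1, 20, 4), paste0("c", 1:20), space = "pca")
  init <- leiden_per_batch(emb, rep(c("A", "B"), each = 10), seed = 3)
  expect_equal(length(unique(init$assignment[1:10])), 1)
})

test_that("forced and saturated MNN configurations behave as defined", {
  # two batches of one cell each: mutual 1-NN is forced
  emb <- bn_embedding(rbind(c(1, 0), c(0.9, 0.1)), c("a", "b"), space = "pca")
  p <- find_mnn_pairs(emb, c("A", "B"), "A", "B", k = 1, n_pcs_mnn = 2) |>
    suppressWarnings()
  expect_equal(nrow(p), 1)
  expect_equal(c(p$i, p$j), c(1L, 2L))

  # saturated neighbourhoods: every cross pair is mutual
  bl <- blob_embedding(n_per = 6, n_types = 2, n_batches = 2, seed = 4)
  p2 <- find_mnn_pairs(bl$emb, bl$batch, "B1", "B2", k = 50, n_pcs_mnn = 5)
  expect_equal(nrow(p2), 12 * 12)
  expect_equal(unique(p2$step), 0L)
})

test_that("MNN pairs match the brute-force mutual-kNN oracle", {
  for (case in 1:8) {
    withr::with_seed(100 + case, {
      na <- sample(10:40, 1); nb <- sample(10:40, 1)
      k <- sample(3:8, 1)
      coords <- matrix(rnorm((na + nb) * 6), na + nb, 6)
      batch <- rep(c("A", "B"), c(na, nb))
    })
    emb <- bn_embedding(coords, paste0("c", seq_len(na + nb)), space = "pca")
    got <- find_mnn_pairs(emb, batch, "A", "B", k = k, n_pcs_mnn = 4)
    want <- oracle_mnn(coords, batch, "A", "B", k, 4)
    expect_setequal(pair_key(got$i, got$j), pair_key(want[, 1], want[, 2]))
    # intra-batch variant against the same oracle
    got_aa <- find_mnn_pairs(emb, batch, "A", "A", k = k, n_pcs_mnn = 4)
    want_aa <- oracle_mnn(coords, batch, "A", "A", k, 4)
    expect_setequal(pair_key(got_aa$i, got_aa$j),
                    pair_key(want_aa[, 1], want_aa[, 2]))
  }
})

test_that("walk expansion is monotone in T, reaches chained cells, stops at fixed points", {
  bl <- blob_embedding(n_per = 15, n_types = 2, n_batches = 2, seed = 6)
  s0 <- find_mnn_pairs(bl$emb, bl$batch, "B1", "B2", k = 3, n_pcs_mnn = 5)
  expect_identical(random_walk_expand(s0, bl$emb, bl$batch, T = 0), s0)
  sizes <- vapply(0:4, function(T)
    nrow(random_walk_expand(s0, bl$emb, bl$batch, T = T)), 1L)
  expect_true(all(diff(sizes) >= 0))
  s_prev <- random_walk_expand(s0, bl$emb, bl$batch, T = 3)
  s_next <- random_walk_expand(s0, bl$emb, bl$batch, T = 4)
  expect_true(all(pair_key(s_prev$i, s_prev$j) %in%
                  pair_key(s_next$i, s_next$j)))
  # fixed point: huge T equals the closure reached much earlier
  s_inf <- random_walk_expand(s0, bl$emb, bl$batch, T = 1000)
  s_50 <- random_walk_expand(s0, bl$emb, bl$batch, T = 50)
  expect_equal(nrow(s_inf), nrow(s_50))
})

test_that("a cell missed by k=1 MNN is reached after one walk step", {
  # batch A: chain c1 - c3 (c3 slightly further from batch B's only cell);
  # with k = 1, S0 = {(c1, c2)}; c3 is c1's within-batch 1-NN, so step 1
  # must add (c3, c2). Verified against a hand re-implementation of the
  # transition rule.
  coords <- rbind(c(1, 0), c(0.95, 0.05), c(0.9, 0.2))
  batch <- c("A", "B", "A")
  emb <- bn_embedding(coords, c("c1", "c2", "c3"), space = "pca")
  s0 <- find_mnn_pairs(emb, batch, "A", "B", k = 1, n_pcs_mnn = 2)
  expect_equal(pair_key(s0$i, s0$j), pair_key(1, 2))
  s1 <- random_walk_expand(s0, emb, batch, T = 1)
  expect_setequal(pair_key(s1$i, s1$j), c(pair_key(1, 2), pair_key(3, 2)))
  expect_equal(s1$step[pair_key(s1$i, s1$j) == pair_key(3, 2)], 1L)
})

test_that("cluster graph weights follow pair-capacity normalization", {
  init <- structure(list(assignment = c(rep("A.1", 3), rep("B.1", 2)),
                         resolution = 3,
                         batch_of_cluster = c(A.1 = "A", B.1 = "B")),
                    class = "bn_initial_clusters")
  pairs <- scBatchNet:::new_mnn_pairs(i = c(1, 1, 2, 3), j = c(4, 5, 4, 5),
                                      batch_a = rep("A", 4),
                                      batch_b = rep("B", 4), step = rep(0L, 4))
  g <- build_cluster_graph(pairs, init)
  expect_equal(g$weight["A.1", "B.1"], 4 / 6)
  expect_identical(g$weight, t(g$weight))
  # empty pair set -> all-zero weights
  g0 <- build_cluster_graph(scBatchNet:::new_mnn_pairs(), init)
  expect_true(all(g0$weight == 0))
  # sqrt variant
  gs <- build_cluster_graph(pairs, init, size_norm = "sqrt")
  expect_equal(gs$weight["A.1", "B.1"], 4 / sqrt(6))
})

test_that("cluster graph is equivariant under cluster relabeling", {
  withr::with_seed(8, {
    assign1 <- sample(paste0("A.", 1:4), 30, replace = TRUE)
    pairs <- scBatchNet:::new_mnn_pairs(i = sample(30, 20, TRUE),
                                        j = sample(30, 20, TRUE),
                                        batch_a = rep("A", 20),
                                        batch_b = rep("A", 20),
                                        step = rep(0L, 20))
  })
  pairs <- pairs[pairs$i != pairs$j, ]
  init1 <- structure(list(assignment = assign1), class = "bn_initial_clusters")
  relab <- c(A.1 = "Z.9", A.2 = "Z.2", A.3 = "Z.5", A.4 = "Z.1")
  init2 <- structure(list(assignment = unname(relab[assign1])),
                     class = "bn_initial_clusters")
  g1 <- build_cluster_graph(pairs, init1)
  g2 <- build_cluster_graph(pairs, init2)
  perm <- match(unname(relab[g1$nodes]), g2$nodes)
  expect_equal(unname(g2$weight[perm, perm]), unname(g1$weight))
})

test_that("spectral partition separates disconnected cliques exactly", {
  nodes <- paste0("A.", 1:6)
  W <- matrix(0, 6, 6, dimnames = list(nodes, nodes))
  W[1:3, 1:3] <- 1; W[4:6, 4:6] <- 1; diag(W) <- 0
  g <- structure(list(weight = W, nodes = nodes,
                      sizes = stats::setNames(rep(5, 6), nodes)),
                 class = "bn_cluster_graph")
  init <- structure(list(assignment = rep(nodes, each = 2)),
                    class = "bn_initial_clusters")
  out <- spectral_partition(g, init, n_groups = 2, seed = 1)
  expect_equal(out$n_groups, 2)
  lab <- out$group_of_cluster
  expect_equal(length(unique(lab[1:3])), 1)
  expect_equal(length(unique(lab[4:6])), 1)
  expect_true(lab[1] != lab[4])
  # identity partition when n_groups equals the node count
  out_id <- spectral_partition(g, init, n_groups = 6, seed = 1)
  expect_equal(length(unique(out_id$group_of_cluster)), 6)
  expect_error(spectral_partition(g, init, n_groups = 7), "exceeds")
})

test_that("planted blocks are recovered and match the exhaustive oracle", {
  withr::with_seed(9, {
    blocks <- rep(1:3, c(3, 3, 2))
    n <- length(blocks)
    W <- matrix(0.01, n, n)
    for (b in 1:3) W[blocks == b, blocks == b] <- 1
    diag(W) <- 0
    W <- W + matrix(runif(n * n, 0, 1e-3), n, n)
    W <- (W + t(W)) / 2
  })
  nodes <- paste0("A.", 1:n)
  dimnames(W) <- list(nodes, nodes)
  g <- structure(list(weight = W, nodes = nodes,
                      sizes = stats::setNames(rep(4, n), nodes)),
                 class = "bn_cluster_graph")
  init <- structure(list(assignment = nodes), class = "bn_initial_clusters")
  got <- spectral_partition(g, init, n_groups = 3, seed = 2)$group_of_cluster
  want <- oracle_best_partition(W, 3)
  expect_equal(metric_ari(got, want), 1)
  # the eigengap heuristic also lands on 3 groups here
  auto <- spectral_partition(g, init, n_groups = "auto", seed = 2)
  expect_equal(auto$n_groups, 3)
})

test_that("end-to-end clustering recovers planted types across batches", {
  ok <- 0
  for (s in 1:5) {
    bl <- blob_embedding(n_per = 30, n_types = 4, n_batches = 3, d = 10,
                         sep = 12, batch_shift = 1.5, seed = 20 + s)
    cl <- cross_batch_cluster(bl$emb, bl$batch,
                              bn_config(n_pcs_global = 10, n_pcs_mnn = 5,
                                        rng_seed = s))
    if (metric_ari(cl$global$assignment, bl$type) >= 0.9) ok <- ok + 1
  }
  expect_gte(ok, 4)
})
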