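test_that("ARI handles perfect, permuted, and anti-correlated labelings", {
  expect_equal(metric_ari(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(metric_ari(c("A", "A", "B", "B"), c(1, 1, 0, 0)), 1)
  expect_equal(metric_ari(c(0, 0, 1, 1), c(0, 1, 0, 1)), -0.5)
  expect_error(metric_ari(1:3, 1:4), "equal length")
})

test_that("NMI handles perfect and zero-information labelings", {
  expect_equal(metric_nmi(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(metric_nmi(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)  # all n_ij = 1
  expect_equal(metric_nmi(rep(1, 5), rep(1, 5)), 1)  # degenerate convention
})

test_that("ARI and NMI match independent textbook implementations", {
  withr::with_seed(13, {
    preds <- list(); truths <- list()
    for (i in 1:200) {
      n <- sample(5:50, 1)
      preds[[i]] <- sample(0:sample(1:5, 1), n, replace = TRUE)
      truths[[i]] <- sample(0:sample(1:5, 1), n, replace = TRUE)
      # guard: metrics need >= 2 cells, allow single-class draws
    }
  })
  want <- skl_label_scores(preds, truths)
  for (i in seq_along(preds)) {
    expect_equal(metric_ari(preds[[i]], truths[[i]]), want[i, 1],
                 tolerance = 1e-10)
    expect_equal(metric_nmi(preds[[i]], truths[[i]]), want[i, 2],
                 tolerance = 1e-10)
  }
  # second, in-R oracle for ARI
  for (i in 1:20)
    expect_equal(metric_ari(preds[[i]], truths[[i]]),
                 mclust::adjustedRandIndex(preds[[i]], truths[[i]]),
                 tolerance = 1e-10)
})

test_that("silhouette matches the exhaustive oracle and its landmarks", {
  # far-separated tight clusters -> near 1
  bl <- blob_embedding(n_per = 15, n_types = 2, n_batches = 1, sep = 50,
                       sd = 0.1, seed = 14)
  expect_gt(metric_asw_celltype(bl$emb, bl$type), 0.98)
  # random labels on one isotropic blob -> about 0.5
  withr::with_seed(15, {
    x <- matrix(rnorm(200 * 3), 200, 3)
    lab <- sample(c("a", "b"), 200, replace = TRUE)
  })
  expect_equal(metric_asw_celltype(x, lab), 0.5, tolerance = 0.03)
  # oracle equivalence on random instances via cluster::silhouette
  for (case in 1:10) {
    withr::with_seed(300 + case, {
      n <- sample(6:50, 1)
      x <- matrix(rnorm(n * 3), n, 3)
      lab <- sample(seq_len(sample(2:4, 1)), n, replace = TRUE)
    })
    if (length(unique(lab)) < 2) next
    sil <- cluster::silhouette(lab, dist(x))
    want <- (mean(sil[, "sil_width"]) + 1) / 2
    expect_equal(metric_asw_celltype(x, lab), want, tolerance = 1e-10)
  }
})

test_that("silhouette is translation- and rotation-invariant", {
  withr::with_seed(16, {
    x <- matrix(rnorm(40 * 3), 40, 3)
    lab <- rep(c("a", "b"), 20)
    qr_q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  })
  v0 <- metric_asw_celltype(x, lab)
  expect_equal(metric_asw_celltype(sweep(x, 2, c(5, -3, 2), "+"), lab), v0,
               tolerance = 1e-10)
  expect_equal(metric_asw_celltype(x %*% qr_q, lab), v0, tolerance = 1e-10)
})

test_that("iLISI deviation vanishes for ideal and single-batch mixing", {
  # single batch: iLISI(i) = 1 = N_i everywhere
  withr::with_seed(17, x <- matrix(rnorm(30 * 2), 30, 2))
  expect_equal(metric_ilisi(x, rep("b1", 30), rep(c("t1", "t2"), 15)), 0)
  # perfectly interleaved two batches: iLISI(i) ~ 2 = N_i
  grid <- cbind(rep(1:10, 10), rep(1:10, each = 10)) / 2
  batch <- rep(c("b1", "b2"), 50)
  expect_lt(metric_ilisi(grid, batch, rep("t", 100), k_lisi = 20), 0.05)
})

test_that("iLISI equals a direct evaluation of its defining formula", {
  withr::with_seed(18, {
    x <- matrix(rnorm(20 * 2), 20, 2)
    batch <- sample(c("b1", "b2"), 20, replace = TRUE)
    types <- sample(c("t1", "t2"), 20, replace = TRUE)
  })
  k <- 7
  # brute-force re-evaluation with explicit neighbour sets
  d <- as.matrix(dist(x))
  il <- numeric(20)
  for (i in 1:20) {
    nbi <- setdiff(order(d[i, ]), i)[1:k]
    p <- table(batch[nbi]) / k
    il[i] <- 1 / sum(p^2)
  }
  Ni <- vapply(types, function(tt) length(unique(batch[types == tt])), 1)
  dev <- abs(il - Ni) / Ni
  want <- mean(vapply(unique(batch), function(b) mean(dev[batch == b]), 1))
  expect_equal(metric_ilisi(x, batch, types, k_lisi = k), want,
               tolerance = 1e-12)
})

test_that("BatchKL vanishes for perfect mixing and finds pure neighbourhoods", {
  grid <- cbind(rep(1:10, 10), rep(1:10, each = 10)) / 2
  batch <- rep(c("b1", "b2"), 50)
  expect_lt(metric_batch_kl(grid, batch, seed = 1, k_kl = 20), 0.02)
  # a cell whose whole neighbourhood is its own batch contributes log 2
  x <- rbind(matrix(rnorm(20, 0, 0.1), 10, 2),
             matrix(rnorm(20, 50, 0.1), 10, 2))
  batch2 <- rep(c("b1", "b2"), each = 10)
  expect_equal(metric_batch_kl(x, batch2, seed = 1, k_kl = 9), log(2),
               tolerance = 1e-10)
  expect_warning(v <- metric_batch_kl(x, rep("b1", 20), seed = 1),
                 "one batch")
  expect_equal(v, 0)
})

test_that("BatchKL is invariant to batch renaming and cell permutation", {
  withr::with_seed(19, {
    x <- matrix(rnorm(60 * 3), 60, 3)
    batch <- sample(c("u", "v", "w"), 60, replace = TRUE)
    perm <- sample(60)
  })
  ids <- sprintf("c%02d", 1:60)
  emb <- bn_embedding(x, ids, space = "corrected")
  v1 <- metric_batch_kl(emb, batch, seed = 4, k_kl = 10)
  ren <- c(u = "x1", v = "x2", w = "x3")
  expect_equal(metric_batch_kl(emb, unname(ren[batch]), seed = 4, k_kl = 10),
               v1, tolerance = 1e-12)
  emb_p <- bn_embedding(x[perm, ], ids[perm], space = "corrected")
  expect_equal(metric_batch_kl(emb_p, batch[perm], seed = 4, k_kl = 10), v1,
               tolerance = 1e-12)
  # iLISI is permutation-invariant too
  types <- rep(c("t1", "t2"), 30)
  expect_equal(metric_ilisi(emb_p, batch[perm], types[perm], k_lisi = 15),
               metric_ilisi(emb, batch, types, k_lisi = 15),
               tolerance = 1e-12)
})

test_that("composite scores reproduce hand-substituted values", {
  expect_identical(biological_conservation(1, 1, 1), 1)
  expect_identical(biological_conservation(0, 0, 0), 0)
  expect_equal(biological_conservation(0.9, 0.8, 0.7), 0.8, tolerance = 1e-15)
  expect_equal(batch_mixing(0, 0), 0.5)
  expect_equal(batch_mixing(3, 3), 0.5)
  expect_equal(batch_mixing(0.3, 1.2), 0.65, tolerance = 1e-15)
  # clipping keeps the composite in range for extreme BatchKL
  expect_equal(batch_mixing(10, 0), 0)
})

test_that("report fields respect their bounds on random instances", {
  withr::with_seed(20, {
    for (case in 1:25) {
      n <- sample(20:60, 1)
      x <- matrix(rnorm(n * 4), n, 4)
      batch <- sample(c("b1", "b2"), n, replace = TRUE)
      types <- sample(c("t1", "t2", "t3"), n, replace = TRUE)
      pred <- sample(0:2, n, replace = TRUE)
      if (length(unique(batch)) < 2 || length(unique(types)) < 2) next
      rep_ <- evaluate_integration(bn_embedding(x, paste0("c", 1:n),
                                                "corrected"),
                                   batch, types, pred, seed = case,
                                   k_lisi = 10, k_kl = 10)
      expect_lte(rep_$ari, 1); expect_gte(rep_$nmi, 0); expect_lte(rep_$nmi, 1)
      expect_gte(rep_$asw_celltype, 0); expect_lte(rep_$asw_celltype, 1)
      expect_gte(rep_$ilisi, 0); expect_gte(rep_$batch_kl, 0)
    }
  })
})
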