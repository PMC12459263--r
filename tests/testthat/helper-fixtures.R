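# Small in-code fixtures shared across test files.

# Gaussian blobs in d dimensions: one blob per type, optionally shifted per
# batch. Returns a list with coords, type, batch.
make_blobs <- function(n_per = 20, n_types = 3, n_batches = 2, d = 5,
                       sep = 8, batch_shift = 0, sd = 0.5, seed = 1) {
  withr::with_seed(seed, {
    centers <- matrix(stats::rnorm(n_types * d), n_types, d)
    centers <- centers / sqrt(rowSums(centers^2)) * sep
    coords <- NULL; type <- character(0); batch <- character(0)
    for (b in seq_len(n_batches)) {
      shift <- stats::rnorm(d, sd = batch_shift)
      for (t in seq_len(n_types)) {
        pts <- sweep(matrix(stats::rnorm(n_per * d, sd = sd), n_per, d), 2,
                     centers[t, ] + shift, "+")
        coords <- rbind(coords, pts)
        type <- c(type, rep(paste0("T", t), n_per))
        batch <- c(batch, rep(paste0("B", b), n_per))
      }
    }
    list(coords = coords, type = type, batch = batch)
  })
}

blob_embedding <- function(..., space = "pca") {
  bl <- make_blobs(...)
  list(emb = bn_embedding(bl$coords,
                          paste0("c", seq_len(nrow(bl$coords))),
                          space = space),
       type = bl$type, batch = bl$batch)
}

# Tiny raw-count dataset with explicit values.
tiny_dataset <- function(counts, batch, type = NULL) {
  bn_dataset(counts, batch = batch, type_label = type,
             layer_state = "raw_counts")
}

# Brute-force mutual-kNN under cosine distance on the first n_pcs
# coordinates; independent of the package's neighbour-search code path.
oracle_mnn <- function(coords, batch, a, b, k, n_pcs) {
  x <- coords[, seq_len(n_pcs), drop = FALSE]
  cosd <- function(u, v) {
    nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
    if (nu == 0 || nv == 0) return(1)
    1 - sum(u * v) / (nu * nv)
  }
  ia <- which(batch == a); ib <- which(batch == b)
  same <- identical(a, b)
  knn_of <- function(i, pool) {
    pool <- setdiff(pool, i)
    d <- vapply(pool, function(j) cosd(x[i, ], x[j, ]), 1.0)
    pool[order(d, pool)][seq_len(min(k, length(pool)))]
  }
  pairs <- NULL
  for (i in ia) for (j in ib) {
    if (same && i >= j) next
    if (j %in% knn_of(i, ib) && i %in% knn_of(j, ia))
      pairs <- rbind(pairs, c(i, j))
  }
  pairs
}

pair_key <- function(i, j) paste(pmin(i, j), pmax(i, j))

# Exhaustive search over all partitions of n nodes into exactly g nonempty
# groups, maximizing total within-group edge weight.
oracle_best_partition <- function(W, g) {
  n <- nrow(W)
  best <- NULL; best_w <- -Inf
  assign_next <- function(lab, next_max) {
    i <- length(lab) + 1
    if (i > n) {
      if (next_max - 1 != g) return()
      w <- 0
      for (a in seq_len(n - 1)) for (b in (a + 1):n)
        if (lab[a] == lab[b]) w <- w + W[a, b]
      if (w > best_w) { best_w <<- w; best <<- lab }
      return()
    }
    for (l in seq_len(min(next_max, g)))
      assign_next(c(lab, l), max(next_max, l + 1))
  }
  assign_next(integer(0), 1)
  best
}

# One shared scaled-down pipeline configuration for fast end-to-end tests.
fast_cfg <- function(seed = 1) {
  bn_config(n_pcs_global = 30, n_hvg = 500, epochs = 5, rng_seed = seed)
}

skl_label_scores <- function(pred_list, truth_list) {
  # Independent textbook ARI/NMI oracle: scikit-learn via the system python.
  stopifnot(length(pred_list) == length(truth_list))
  payload <- jsonlite::toJSON(list(pred = pred_list, truth = truth_list))
  tf <- tempfile(fileext = ".json")
  writeLines(payload, tf)
  script <- paste(
    "import json, sys",
    "from sklearn.metrics import adjusted_rand_score, normalized_mutual_info_score",
    sprintf("d = json.load(open('%s'))", tf),
    "out = [[adjusted_rand_score(t, p), normalized_mutual_info_score(t, p, average_method='arithmetic')]",
    "       for p, t in zip(d['pred'], d['truth'])]",
    "print(json.dumps(out))", sep = "\n")
  res <- system2("python", c("-c", shQuote(script)), stdout = TRUE)
  jsonlite::fromJSON(res)
}
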