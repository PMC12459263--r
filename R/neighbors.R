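# Exact neighbour-search helpers. All searches at desk scale use full
# distance matrices; ties are broken by cell index so results are
# order-deterministic.

# Unit-normalize rows; all-zero rows are left at zero (their cosine distance
# to every other vector is defined as 1).
unit_rows <- function(x) {
  nrm <- sqrt(rowSums(x^2))
  nz <- nrm > 0
  x[nz, ] <- x[nz, , drop = FALSE] / nrm[nz]
  x
}

# Cosine distance matrix between rows of a and rows of b (1 - cosine
# similarity; zero vectors get distance 1 to everything).
cosine_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
  d <- 1 - tcrossprod(unit_rows(a), unit_rows(b))
  d[na == 0, ] <- 1
  d[, nb == 0] <- 1
  pmin(pmax(d, 0), 2)
}

euclidean_dist <- function(a, b = a) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

# Indices of the k smallest entries per row of a distance matrix, excluding
# the columns listed in `exclude` (one per row, NA for none). Ties broken by
# column index.
knn_from_dist <- function(d, k, exclude_self = FALSE) {
  n <- nrow(d); m <- ncol(d)
  if (exclude_self) d[cbind(seq_len(n), seq_len(n))] <- Inf
  k <- min(k, m - as.integer(exclude_self))
  idx <- matrix(NA_integer_, n, k)
  for (i in seq_len(n)) {
    o <- order(d[i, ], seq_len(m))
    idx[i, ] <- o[seq_len(k)]
  }
  idx
}

# Shared-nearest-neighbour graph of one point set: k-NN (Euclidean, self
# included) followed by Jaccard overlap weights between adjacent points,
# pruned below `prune`. Returns an undirected weighted igraph.
snn_graph <- function(x, k = 15L, prune = 1 / 15) {
  n <- nrow(x)
  k <- min(k, n)
  d <- euclidean_dist(x)
  nn <- knn_from_dist(d, k, exclude_self = FALSE)
  memb <- Matrix::sparseMatrix(i = rep(seq_len(n), each = ncol(nn)),
                               j = as.vector(t(nn)), x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(memb)
  adj <- memb + Matrix::t(memb)  # kNN adjacency in either direction
  tri <- Matrix::which(adj > 0, arr.ind = TRUE)
  tri <- tri[tri[, 1] < tri[, 2], , drop = FALSE]
  if (nrow(tri) == 0)
    return(igraph::make_empty_graph(n, directed = FALSE))
  s <- shared[tri]
  w <- s / (2 * ncol(nn) - s)
  keep <- w >= prune
  igraph::graph_from_data_frame(
    data.frame(from = tri[keep, 1], to = tri[keep, 2], weight = w[keep]),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
}
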