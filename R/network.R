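#' Tuplet margin loss
#'
#' The metric-learning objective of the correction network. For one tuplet
#' with anchor-positive distance `d_ap` and anchor-negative distances
#' `d_an`, the loss is `log(1 + sum_i exp(d_ap - d_an[i]))`, evaluated in an
#' overflow-safe log-sum-exp form. Distances are Euclidean distances between
#' embedding vectors. The loss is strictly positive for finite inputs and
#' equals `log(k_tuple)` when all distances coincide.
#'
#' @param d_ap Nonnegative anchor-positive distance.
#' @param d_an Vector of nonnegative anchor-negative distances (>= 1).
#' @return The scalar loss value.
#' @export
tuplet_margin_loss <- function(d_ap, d_an) {
  if (length(d_an) < 1) stop("at least one negative is required", call. = FALSE)
  if (any(c(d_ap, d_an) < 0)) stop("distances must be nonnegative", call. = FALSE)
  z <- d_ap - d_an
  # log(1 + sum exp(z)) = m + log(exp(-m) + sum exp(z - m)), m = max(0, z);
  # the m = 0 branch uses log1p so tiny sums keep the loss strictly positive
  m <- max(0, z)
  if (m == 0) log1p(sum(exp(z))) else m + log(exp(-m) + sum(exp(z - m)))
}

#' Sample supervision tuplets
#'
#' Draws reproducible training tuplets from the global cluster labels. Each
#' tuplet holds one anchor, one positive sharing the anchor's label, and
#' `k_tuple - 1` negatives from distinct other labels. Anchor labels are
#' drawn uniformly from the labels with at least two members, so classes are
#' balanced regardless of their size.
#'
#' @param labels Per-cell cluster labels (any atomic type).
#' @param n_tuplets Number of tuplets to draw.
#' @param k_tuple Tuple size (1 positive + `k_tuple - 1` negatives).
#' @param seed Integer seed; the stream is fully reproducible.
#' @return An integer matrix with `n_tuplets` rows and columns
#'   `anchor`, `positive`, `neg1..neg{k_tuple-1}` holding cell indices.
#' @export
sample_tuplets <- function(labels, n_tuplets, k_tuple = 4L, seed = 0L) {
  labels <- as.character(labels)
  by_lab <- split(seq_along(labels), labels)
  eligible <- names(by_lab)[lengths(by_lab) >= 2L]
  if (length(by_lab) < 2L || length(eligible) < 1L)
    stop("tuplet sampling needs >= 2 distinct labels with a positive ",
         "available; only one global cluster present", call. = FALSE)
  n_neg <- k_tuple - 1L
  withr::with_seed(seed, {
    out <- matrix(NA_integer_, n_tuplets, 2L + n_neg)
    anchors_lab <- sample(eligible, n_tuplets, replace = TRUE)
    for (t in seq_len(n_tuplets)) {
      lab <- anchors_lab[t]
      members <- by_lab[[lab]]
      ap <- sample(members, 2L)
      others <- setdiff(names(by_lab), lab)
      neg_labs <- if (length(others) >= n_neg) sample(others, n_neg)
                  else sample(others, n_neg, replace = TRUE)
      negs <- vapply(neg_labs,
                     function(l) by_lab[[l]][sample.int(length(by_lab[[l]]), 1L)],
                     1L)
      out[t, ] <- c(ap, negs)
    }
    colnames(out) <- c("anchor", "positive", paste0("neg", seq_len(n_neg)))
    out
  })
}

#' Residual correction network specification
#'
#' The network maps the PCA embedding to the corrected space through two
#' stacked residual blocks followed by a linear projection. Each block is
#' five layers — linear(d, d), batch norm, PReLU, linear(d, d), batch norm —
#' with an identity skip connection added after the second batch norm and no
#' activation after the addition.
#'
#' @param input_dim Width of the blocks (= PCA dimension).
#' @param embed_dim Output dimension of the final projection (default 32).
#' @param n_blocks Number of residual blocks (default 2).
#' @return A list of class `bn_network_spec`.
#' @export
network_spec <- function(input_dim, embed_dim = 32L, n_blocks = 2L) {
  stopifnot(input_dim >= 1, embed_dim >= 1, n_blocks >= 1)
  structure(list(input_dim = as.integer(input_dim),
                 embed_dim = as.integer(embed_dim),
                 n_blocks = as.integer(n_blocks)),
            class = "bn_network_spec")
}

# ---- parameter initialisation ------------------------------------------
# Linear layers: Glorot-uniform weights, zero bias. Batch norm: gamma 1,
# beta 0, running stats (0, 1). PReLU: one shared slope per activation,
# init 0.25.
init_linear <- function(fan_in, fan_out) {
  r <- sqrt(6 / (fan_in + fan_out))
  list(W = matrix(stats::runif(fan_in * fan_out, -r, r), fan_in, fan_out),
       b = numeric(fan_out))
}
init_bn <- function(d) list(gamma = rep(1, d), beta = numeric(d),
                            run_mean = numeric(d), run_var = rep(1, d))

init_network <- function(spec, seed = 0L) {
  withr::with_seed(seed, {
    d <- spec$input_dim
    blocks <- lapply(seq_len(spec$n_blocks), function(i)
      list(fc1 = init_linear(d, d), bn1 = init_bn(d), prelu = list(a = 0.25),
           fc2 = init_linear(d, d), bn2 = init_bn(d)))
    structure(list(spec = spec, blocks = blocks,
                   proj = init_linear(d, spec$embed_dim)),
              class = "bn_network")
  })
}

.bn_eps <- 1e-5
.bn_momentum <- 0.1

# Batch-norm forward. In training mode uses mini-batch statistics (population
# variance) and updates the running averages; in inference mode uses the
# running averages.
bn_forward <- function(x, bn, training) {
  if (training) {
    mu <- colMeans(x)
    v <- colMeans(x^2) - mu^2
    bn$run_mean <- (1 - .bn_momentum) * bn$run_mean + .bn_momentum * mu
    bn$run_var <- (1 - .bn_momentum) * bn$run_var + .bn_momentum * v
  } else {
    mu <- bn$run_mean; v <- bn$run_var
  }
  inv <- 1 / sqrt(v + .bn_eps)
  xhat <- sweep(sweep(x, 2, mu), 2, inv, "*")
  y <- sweep(sweep(xhat, 2, bn$gamma, "*"), 2, bn$beta, "+")
  list(y = y, xhat = xhat, inv = inv, bn = bn)
}

bn_backward <- function(dy, cache) {
  n <- nrow(dy)
  xhat <- cache$xhat; inv <- cache$inv; gamma <- cache$bn$gamma
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2, gamma, "*")
  dx <- sweep(dxhat - matrix(colMeans(dxhat), n, ncol(dy), byrow = TRUE) -
                xhat * matrix(colMeans(dxhat * xhat), n, ncol(dy), byrow = TRUE),
              2, inv, "*")
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

prelu_forward <- function(x, a) {
  y <- x
  y[x < 0] <- a * x[x < 0]
  y
}

# Full forward pass. training = TRUE uses mini-batch BN statistics and
# returns the caches needed for backprop (and updated running stats).
net_forward <- function(net, x, training = FALSE) {
  caches <- vector("list", length(net$blocks))
  h <- x
  for (bi in seq_along(net$blocks)) {
    blk <- net$blocks[[bi]]
    z1 <- h %*% blk$fc1$W + matrix(blk$fc1$b, nrow(h), ncol(blk$fc1$W),
                                   byrow = TRUE)
    f1 <- bn_forward(z1, blk$bn1, training)
    if (training) net$blocks[[bi]]$bn1 <- f1$bn
    z3 <- prelu_forward(f1$y, blk$prelu$a)
    z4 <- z3 %*% blk$fc2$W + matrix(blk$fc2$b, nrow(h), ncol(blk$fc2$W),
                                    byrow = TRUE)
    f2 <- bn_forward(z4, blk$bn2, training)
    if (training) net$blocks[[bi]]$bn2 <- f2$bn
    out <- h + f2$y
    caches[[bi]] <- list(h = h, z1 = z1, f1 = f1, y1 = f1$y, z3 = z3,
                         f2 = f2)
    h <- out
  }
  z <- h %*% net$proj$W + matrix(net$proj$b, nrow(h), ncol(net$proj$W),
                                 byrow = TRUE)
  list(z = z, h = h, caches = caches, net = net)
}

# Backward pass given dL/dz; returns gradients in the same structure as the
# parameters.
net_backward <- function(net, fw, dz) {
  grads <- list(proj = list(W = crossprod(fw$h, dz), b = colSums(dz)),
                blocks = vector("list", length(net$blocks)))
  dh <- tcrossprod(dz, net$proj$W)   # dz %*% t(W)
  for (bi in rev(seq_along(net$blocks))) {
    blk <- net$blocks[[bi]]
    cc <- fw$caches[[bi]]
    d_out <- dh
    b2 <- bn_backward(d_out, cc$f2)
    dz4 <- b2$dx
    gW2 <- crossprod(cc$z3, dz4); gb2 <- colSums(dz4)
    dz3 <- dz4 %*% t(blk$fc2$W)
    neg <- cc$y1 < 0
    da <- sum(dz3[neg] * cc$y1[neg])
    dy1 <- dz3
    dy1[neg] <- dy1[neg] * blk$prelu$a
    b1 <- bn_backward(dy1, cc$f1)
    dz1 <- b1$dx
    gW1 <- crossprod(cc$h, dz1); gb1 <- colSums(dz1)
    dh <- d_out + dz1 %*% t(blk$fc1$W)   # skip path + block path
    grads$blocks[[bi]] <- list(
      fc1 = list(W = gW1, b = gb1),
      bn1 = list(gamma = b1$dgamma, beta = b1$dbeta),
      prelu = list(a = da),
      fc2 = list(W = gW2, b = gb2),
      bn2 = list(gamma = b2$dgamma, beta = b2$dbeta))
  }
  grads
}

# Loss and gradient over a mini-batch of tuplets. `z` holds embeddings for
# the stacked rows (anchors, positives, negatives in tuplet-column order).
# Returns mean tuplet loss and dL/dz.
tuplet_batch_loss_grad <- function(z, n_tup, k_tuple) {
  n_neg <- k_tuple - 1L
  ia <- seq_len(n_tup)
  ip <- n_tup + ia
  loss <- 0
  dz <- matrix(0, nrow(z), ncol(z))
  for (t in ia) {
    za <- z[t, ]; zp <- z[ip[t], ]
    diff_ap <- za - zp
    d_ap <- sqrt(sum(diff_ap^2))
    idx_n <- 2L * n_tup + (seq_len(n_neg) - 1L) * n_tup + t
    zn <- z[idx_n, , drop = FALSE]
    diff_an <- -sweep(zn, 2, za)          # za - zn per row
    d_an <- sqrt(rowSums(diff_an^2))
    zexp <- d_ap - d_an
    m <- max(0, zexp)
    denom <- exp(-m) + sum(exp(zexp - m))
    loss <- loss +
      (if (m == 0) log1p(sum(exp(zexp))) else m + log(denom))
    w <- exp(zexp - m) / denom            # dL/dd_an_i = -w_i ; dL/dd_ap = sum w
    g_ap <- if (d_ap > 0) diff_ap / d_ap else numeric(ncol(z))
    dz[t, ] <- dz[t, ] + sum(w) * g_ap
    dz[ip[t], ] <- dz[ip[t], ] - sum(w) * g_ap
    for (q in seq_len(n_neg)) {
      g_an <- if (d_an[q] > 0) diff_an[q, ] / d_an[q] else numeric(ncol(z))
      dz[t, ] <- dz[t, ] - w[q] * g_an
      dz[idx_n[q], ] <- dz[idx_n[q], ] + w[q] * g_an
    }
  }
  list(loss = loss / n_tup, dz = dz / n_tup)
}

# Flatten/apply helpers for the SGD update.
sgd_update <- function(net, grads, vel, lr, momentum) {
  upd <- function(param, grad, v) {
    v_new <- momentum * v - lr * grad
    list(p = param + v_new, v = v_new)
  }
  walk <- function(p, g, v) {
    if (is.list(p)) {
      out_p <- p; out_v <- v
      for (nm in names(p)) {
        if (nm %in% c("run_mean", "run_var")) next
        r <- walk(p[[nm]], g[[nm]], v[[nm]])
        out_p[[nm]] <- r$p; out_v[[nm]] <- r$v
      }
      list(p = out_p, v = out_v)
    } else upd(p, g, v)
  }
  r_blocks <- walk(net$blocks, grads$blocks, vel$blocks)
  r_proj <- walk(net$proj, grads$proj, vel$proj)
  net$blocks <- r_blocks$p
  net$proj <- r_proj$p
  list(net = net, vel = list(blocks = r_blocks$v, proj = r_proj$v))
}

zero_like <- function(p) {
  if (is.list(p)) lapply(p, zero_like) else p * 0
}

#' Train the batch-correction network
#'
#' Optimizes the tuplet margin loss with mini-batch SGD (momentum) over
#' tuplets sampled from the global cluster labels. Each epoch draws one
#' tuplet per cell; per step, the anchors, positives and negatives of
#' `batch_size` tuplets are stacked into one forward pass, so batch-norm
#' statistics are computed over the stacked tuplet rows during training and
#' replaced by running averages at inference.
#'
#' @param emb The PCA `bn_embedding` used as network input.
#' @param labels Per-cell global cluster labels (from
#'   [spectral_partition()]).
#' @param spec A [network_spec()]; its `input_dim` must match the embedding.
#' @param cfg A [bn_config()] supplying `epochs`, `batch_size`,
#'   `learning_rate`, `momentum`, `k_tuple` and the seed.
#' @return A `bn_trained_model`: the network plus the per-epoch mean loss
#'   trajectory (`loss_history`).
#' @export
train_network <- function(emb, labels, spec = NULL, cfg = bn_config()) {
  stopifnot(inherits(emb, "bn_embedding"))
  x <- emb$coords
  if (length(labels) != nrow(x))
    stop("labels must cover all cells", call. = FALSE)
  if (is.null(spec)) spec <- network_spec(ncol(x), cfg$embed_dim)
  if (spec$input_dim != ncol(x))
    stop("network input_dim does not match the embedding dimension",
         call. = FALSE)
  net <- init_network(spec, seed = derive_seed(cfg$rng_seed, "network"))
  vel <- list(blocks = zero_like(net$blocks), proj = zero_like(net$proj))
  loss_history <- numeric(cfg$epochs)
  n <- nrow(x)
  k <- cfg$k_tuple
  tup_seed <- derive_seed(cfg$rng_seed, "tuplets")
  for (ep in seq_len(cfg$epochs)) {
    tuples <- sample_tuplets(labels, n_tuplets = n, k_tuple = k,
                             seed = tup_seed + ep)
    n_steps <- ceiling(nrow(tuples) / cfg$batch_size)
    ep_loss <- 0
    for (s in seq_len(n_steps)) {
      rows <- ((s - 1L) * cfg$batch_size + 1L):min(s * cfg$batch_size,
                                                   nrow(tuples))
      tb <- tuples[rows, , drop = FALSE]
      nb <- nrow(tb)
      stack_idx <- as.vector(tb)           # anchors, positives, negs col-wise
      fw <- net_forward(net, x[stack_idx, , drop = FALSE], training = TRUE)
      net <- fw$net                        # running BN stats updated
      lg <- tuplet_batch_loss_grad(fw$z, nb, k)
      if (!is.finite(lg$loss))
        stop(sprintf("non-finite loss at epoch %d step %d", ep, s),
             call. = FALSE)
      grads <- net_backward(net, fw, lg$dz)
      r <- sgd_update(net, grads, vel, cfg$learning_rate, cfg$momentum)
      net <- r$net; vel <- r$vel
      ep_loss <- ep_loss + lg$loss * nb
    }
    loss_history[ep] <- ep_loss / nrow(tuples)
  }
  structure(list(net = net, spec = spec, loss_history = loss_history,
                 cfg = cfg),
            class = "bn_trained_model")
}

#' Embed cells with a trained network
#'
#' Deterministic inference-mode forward pass (batch norm uses the running
#' averages accumulated during training).
#'
#' @param model A `bn_trained_model` from [train_network()].
#' @param emb The PCA `bn_embedding` to correct.
#' @return A `bn_embedding` in the `"corrected"` space with
#'   `d = spec$embed_dim`.
#' @export
embed_cells <- function(model, emb) {
  stopifnot(inherits(model, "bn_trained_model"), inherits(emb, "bn_embedding"))
  if (ncol(emb$coords) != model$spec$input_dim)
    stop("embedding dimension does not match the network input", call. = FALSE)
  z <- net_forward(model$net, emb$coords, training = FALSE)$z
  colnames(z) <- paste0("BC", seq_len(ncol(z)))
  bn_embedding(z, emb$cell_ids, space = "corrected")
}
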