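# Minimal convolutional-network engine.
#
# Convolutions are lowered to matrix products via im2col gather indices
# (precomputed per layer, applied by a small C++ kernel), with the matching
# col2im scatter-add for the backward pass. Feature vectors use the
# column-major (h, w, c) layout of R arrays throughout, so reshapes are free.
#
# Supported layers: conv2d (+ReLU), maxpool along w, dense (+ReLU),
# per-row dense heads, dropout, softmax cross-entropy loss, L2 weight decay,
# momentum SGD. Everything is deterministic given the seed.

.nn_idx <- function(h, w, c, H, W) ((c - 1L) * W + (w - 1L)) * H + h

# build an im2col plan: gather indices (pad slot = n_in + 1) arranged with
# taps fastest within each output position
.conv_plan <- function(H, W, C, kh, kw, nf, pad = 0L) {
  OH <- H + 2L * pad - kh + 1L
  OW <- W + 2L * pad - kw + 1L
  if (OH < 1L || OW < 1L) stop("convolution output would be empty")
  K <- kh * kw * C
  P <- OH * OW
  n_in <- H * W * C
  gi <- integer(K * P)
  pos <- 0L
  for (ow in seq_len(OW)) for (oh in seq_len(OH)) {
    # tap order: dh fastest, then dw, then c (matches weight layout)
    t <- 0L
    base <- pos * K
    for (c in seq_len(C)) for (dw in seq_len(kw)) for (dh in seq_len(kh)) {
      h <- oh + dh - 1L - pad
      w <- ow + dw - 1L - pad
      t <- t + 1L
      gi[base + t] <- if (h >= 1L && h <= H && w >= 1L && w <= W)
        .nn_idx(h, w, c, H, W) else n_in + 1L
    }
    pos <- pos + 1L
  }
  list(H = H, W = W, C = C, kh = kh, kw = kw, nf = nf, pad = pad,
       OH = OH, OW = OW, K = K, P = P, n_in = n_in, gather = gi)
}

.he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

.layer_conv <- function(plan) {
  list(type = "conv", plan = plan,
       W = .he_init(plan$K, plan$nf, plan$K), b = numeric(plan$nf))
}

.layer_dense <- function(n_in, n_out, activation = c("relu", "linear")) {
  list(type = "dense", activation = match.arg(activation),
       n_in = n_in, n_out = n_out,
       W = .he_init(n_in, n_out, n_in), b = numeric(n_out))
}

.layer_pool_w <- function(H, W, C) {
  list(type = "pool_w", H = H, W = W, C = C, OW = W %/% 2L)
}

# --- forward/backward -------------------------------------------------------

.conv_forward <- function(layer, X) {
  p <- layer$plan
  B <- nrow(X)
  M <- .nn_gather(X, p$gather, p$K, p$P)        # (B*P) x K, im2col
  Z <- M %*% layer$W
  Z <- Z + rep(layer$b, each = nrow(Z))
  A <- Z * (Z > 0)                              # ReLU
  out <- A
  dim(out) <- c(B, p$P * p$nf)                  # (h,w,c)-layout feature vec
  list(out = out, cache = list(M = M, Z = Z, B = B))
}

.conv_backward <- function(layer, cache, dOut) {
  p <- layer$plan
  B <- cache$B
  dA <- dOut
  dim(dA) <- c(B * p$P, p$nf)
  dZ <- dA * (cache$Z > 0)
  dW <- crossprod(cache$M, dZ)
  db <- colSums(dZ)
  dM <- dZ %*% t(layer$W)                       # (B*P) x K
  dX <- .nn_scatter(dM, p$gather, p$K, p$P, p$n_in)
  list(dX = dX, dW = dW, db = db)
}

.pool_forward <- function(layer, X) {
  B <- nrow(X)
  H <- layer$H; W <- layer$W; C <- layer$C; OW <- layer$OW
  A <- X
  dim(A) <- c(B, H, W, C)
  A1 <- A[, , seq_len(OW) * 2L - 1L, , drop = FALSE]
  A2 <- A[, , seq_len(OW) * 2L, , drop = FALSE]
  take1 <- A1 >= A2
  out <- pmax(A1, A2)
  dim(out) <- c(B, H * OW * C)
  list(out = out, cache = list(take1 = take1, B = B))
}

.pool_backward <- function(layer, cache, dOut) {
  B <- cache$B
  H <- layer$H; W <- layer$W; C <- layer$C; OW <- layer$OW
  dO <- dOut
  dim(dO) <- c(B, H, OW, C)
  dX <- array(0, dim = c(B, H, W, C))
  dX[, , seq_len(OW) * 2L - 1L, ] <- dO * cache$take1
  dX[, , seq_len(OW) * 2L, ] <- dO * !cache$take1
  dim(dX) <- c(B, H * W * C)
  list(dX = dX)
}

.dense_forward <- function(layer, X) {
  # per-row heads receive X already reshaped to one row per output site
  Z <- sweep(X %*% layer$W, 2L, layer$b, "+")
  A <- if (layer$activation == "relu") Z * (Z > 0) else Z
  list(out = A, cache = list(X = X, Z = Z))
}

.dense_backward <- function(layer, cache, dOut) {
  dZ <- if (layer$activation == "relu") dOut * (cache$Z > 0) else dOut
  list(dX = dZ %*% t(layer$W), dW = crossprod(cache$X, dZ), db = colSums(dZ))
}

.softmax <- function(Z) {
  m <- Z - apply(Z, 1L, max)
  e <- exp(m)
  e / rowSums(e)
}

# --- network object ---------------------------------------------------------

# layers: list of layer objects; head reshaping for per-row outputs is
# described by net$rows_per_sample (H for the slice-wise variant, 1 for the
# pixel-wise variant)
.net_forward <- function(net, X, train = FALSE, dropout_masks = NULL) {
  caches <- vector("list", length(net$layers))
  cur <- X
  mask_i <- 0L
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    if (ly$type == "conv") {
      fw <- .conv_forward(ly, cur)
    } else if (ly$type == "pool_w") {
      fw <- .pool_forward(ly, cur)
    } else if (ly$type == "reshape_rows") {
      # (B, H * F) -> (B * H, F): rows (b, h) become samples
      B <- nrow(cur)
      fw <- list(out = cur, cache = list(B = B))
      dim(fw$out) <- c(B * ly$H, ly$F)
    } else if (ly$type == "dropout") {
      if (train && net$dropout_rate > 0) {
        mask_i <- mask_i + 1L
        mask <- if (!is.null(dropout_masks)) dropout_masks[[mask_i]] else
          matrix(stats::runif(length(cur)) >= net$dropout_rate,
                 nrow(cur), ncol(cur)) / (1 - net$dropout_rate)
        fw <- list(out = cur * mask, cache = list(mask = mask))
      } else {
        fw <- list(out = cur, cache = list(mask = NULL))
      }
    } else if (ly$type == "dense") {
      fw <- .dense_forward(ly, cur)
    } else stop("unknown layer type")
    caches[[i]] <- fw$cache
    cur <- fw$out
  }
  probs <- .softmax(cur)
  list(probs = probs, logits = cur, caches = caches)
}

# cross-entropy loss + gradients; Y is a one-hot matrix matching probs
.net_backward <- function(net, fwd, Y) {
  n <- nrow(Y)
  dCur <- (fwd$probs - Y) / n
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    ly <- net$layers[[i]]
    cache <- fwd$caches[[i]]
    if (ly$type == "conv") {
      bk <- .conv_backward(ly, cache, dCur)
      grads[[i]] <- list(dW = bk$dW, db = bk$db)
      dCur <- bk$dX
    } else if (ly$type == "pool_w") {
      dCur <- .pool_backward(ly, cache, dCur)$dX
    } else if (ly$type == "reshape_rows") {
      dim(dCur) <- c(cache$B, ly$H * ly$F)
    } else if (ly$type == "dropout") {
      if (!is.null(cache$mask)) dCur <- dCur * cache$mask
    } else if (ly$type == "dense") {
      bk <- .dense_backward(ly, cache, dCur)
      grads[[i]] <- list(dW = bk$dW, db = bk$db)
      dCur <- bk$dX
    }
  }
  grads
}

.net_loss <- function(net, probs, Y) {
  ce <- -mean(rowSums(Y * log(pmax(probs, 1e-12))))
  l2 <- 0
  if (net$l2 > 0) {
    for (ly in net$layers) {
      if (!is.null(ly$W)) l2 <- l2 + sum(ly$W^2)
    }
  }
  ce + 0.5 * net$l2 * l2
}

# one momentum-SGD step in place; velocity stored alongside the layers
.net_sgd_step <- function(net, grads, lr, momentum) {
  for (i in seq_along(net$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    ly <- net$layers[[i]]
    dW <- g$dW + net$l2 * ly$W
    if (is.null(net$vel[[i]])) {
      net$vel[[i]] <- list(W = dW * 0, b = g$db * 0)
    }
    net$vel[[i]]$W <- momentum * net$vel[[i]]$W - lr * dW
    net$vel[[i]]$b <- momentum * net$vel[[i]]$b - lr * g$db
    net$layers[[i]]$W <- ly$W + net$vel[[i]]$W
    net$layers[[i]]$b <- ly$b + net$vel[[i]]$b
  }
  net
}

# flatten / restore all trainable parameters (for gradient checking)
.net_get_params <- function(net) {
  unlist(lapply(net$layers, function(ly) {
    if (is.null(ly$W)) numeric(0) else c(as.vector(ly$W), ly$b)
  }))
}

.net_set_params <- function(net, theta) {
  off <- 0L
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    if (is.null(ly$W)) next
    nw <- length(ly$W); nb <- length(ly$b)
    net$layers[[i]]$W <- matrix(theta[off + seq_len(nw)], nrow(ly$W), ncol(ly$W))
    net$layers[[i]]$b <- theta[off + nw + seq_len(nb)]
    off <- off + nw + nb
  }
  net
}

.net_grad_vector <- function(net, grads, with_l2 = TRUE) {
  unlist(lapply(seq_along(net$layers), function(i) {
    g <- grads[[i]]
    if (is.null(g)) return(numeric(0))
    dW <- g$dW
    if (with_l2 && net$l2 > 0) dW <- dW + net$l2 * net$layers[[i]]$W
    c(as.vector(dW), g$db)
  }))
}
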