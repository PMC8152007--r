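# Minimal convolutional-network engine for 24 x W single-channel window
# images. Sizes here are tiny (W is 4-20 samples), so convolutions are
# evaluated as one BLAS matrix product per layer over an im2col expansion
# whose index map is precomputed at build time. Everything is plain R
# matrices; determinism follows from R's RNG plus a fixed batch order.
#
# Layer vocabulary: valid 2-D convolution (ReLU), one optional 2x2 max-pool
# after the first convolution, a ReLU dense layer with inverted dropout,
# and a softmax head. Kernels shrink automatically to min(3, current dim)
# so the narrow level-3 windows (4 samples wide) remain usable.

.conv_idx <- function(H, W, C, kh, kw) {
  outH <- H - kh + 1L; outW <- W - kw + 1L
  stopifnot(outH >= 1, outW >= 1)
  dh <- rep(seq_len(kh), times = kw * C)
  dw <- rep(rep(seq_len(kw), each = kh), times = C)
  cc <- rep(seq_len(C), each = kh * kw)
  k_off <- (dh - 1L) + (dw - 1L) * H + (cc - 1L) * H * W
  oh <- rep(seq_len(outH), times = outW)
  ow <- rep(seq_len(outW), each = outH)
  p_off <- (oh - 1L) + (ow - 1L) * H
  idx <- outer(k_off, p_off, `+`) + 1L
  list(idx = idx, K = kh * kw * C, P = outH * outW, outH = outH, outW = outW)
}

.pool_idx <- function(H, W, C) {
  outH <- H %/% 2L; outW <- W %/% 2L
  oh <- rep(seq_len(outH), times = outW * C)
  ow <- rep(rep(seq_len(outW), each = outH), times = C)
  cc <- rep(seq_len(C), each = outH * outW)
  idx4 <- lapply(0:3, function(q) {
    a <- q %% 2L; b <- q %/% 2L
    (2L * oh - 2L + a) + (2L * ow - 2L + b) * H + (cc - 1L) * H * W + 1L
  })
  list(idx4 = idx4, outH = outH, outW = outW)
}

# Build an untrained network. Draws initial weights (He normal) from the
# current RNG state; callers seed it.
.net_new <- function(H, W, conv_layers, filters, dense_units, n_classes,
                     dropout_rate) {
  if (H < 1 || W < 1)
    stopf("input of %d x %d is too small for any convolution", H, W)
  layers <- list()
  curH <- as.integer(H); curW <- as.integer(W); curC <- 1L
  for (i in seq_len(conv_layers)) {
    kh <- min(3L, curH); kw <- min(3L, curW)
    ii <- .conv_idx(curH, curW, curC, kh, kw)
    f <- filters[min(i, length(filters))]
    layers[[length(layers) + 1L]] <- list(
      type = "conv", idx = ii$idx, grp = as.vector(ii$idx),
      grp_rows = sort(unique(as.vector(ii$idx))),
      inrows = curH * curW * curC,
      K = ii$K, P = ii$P, outH = ii$outH, outW = ii$outW, cout = f,
      W = matrix(stats::rnorm(f * ii$K, 0, sqrt(2 / ii$K)), f, ii$K),
      b = numeric(f))
    curH <- ii$outH; curW <- ii$outW; curC <- f
    if (i == 1L && curH >= 4L && curW >= 4L) {
      pp <- .pool_idx(curH, curW, curC)
      layers[[length(layers) + 1L]] <- list(
        type = "pool", idx4 = pp$idx4, inrows = curH * curW * curC,
        outH = pp$outH, outW = pp$outW)
      curH <- pp$outH; curW <- pp$outW
    }
  }
  D <- curH * curW * curC
  layers[[length(layers) + 1L]] <- list(
    type = "dense", relu = TRUE,
    W = matrix(stats::rnorm(dense_units * D, 0, sqrt(2 / D)), dense_units, D),
    b = numeric(dense_units))
  layers[[length(layers) + 1L]] <- list(type = "dropout", rate = dropout_rate)
  layers[[length(layers) + 1L]] <- list(
    type = "dense", relu = FALSE,
    W = matrix(stats::rnorm(n_classes * dense_units, 0,
                            sqrt(2 / dense_units)), n_classes, dense_units),
    b = numeric(n_classes))
  list(layers = layers, input = c(H = H, W = W), n_classes = n_classes)
}

# Forward pass. X: (H*W) x N matrix of inputs scaled to [0, 1].
# Returns class probabilities (n_classes x N) and per-layer caches.
.net_forward <- function(net, X, train = FALSE) {
  caches <- vector("list", length(net$layers))
  A <- X
  for (li in seq_along(net$layers)) {
    l <- net$layers[[li]]
    if (l$type == "conv") {
      N <- ncol(A)
      cols <- A[as.vector(l$idx), , drop = FALSE]
      dim(cols) <- c(l$K, l$P * N)
      Z <- l$W %*% cols + l$b
      relu <- Z > 0
      Z[!relu] <- 0
      Za <- array(Z, dim = c(l$cout, l$outH, l$outW, N))
      A <- aperm(Za, c(2, 3, 1, 4))
      dim(A) <- c(l$outH * l$outW * l$cout, N)
      caches[[li]] <- list(cols = cols, relu = relu, N = N)
    } else if (l$type == "pool") {
      parts <- lapply(l$idx4, function(ix) A[ix, , drop = FALSE])
      Mx <- pmax(parts[[1]], parts[[2]], parts[[3]], parts[[4]])
      caches[[li]] <- list(parts = parts, Mx = Mx)
      A <- Mx
    } else if (l$type == "dense") {
      Z <- l$W %*% A + l$b
      if (l$relu) {
        relu <- Z > 0
        Z[!relu] <- 0
      } else relu <- NULL
      caches[[li]] <- list(Ain = A, relu = relu)
      A <- Z
    } else if (l$type == "dropout") {
      if (train && l$rate > 0) {
        keep <- 1 - l$rate
        mask <- (matrix(stats::runif(length(A)), nrow(A)) < keep) / keep
        A <- A * mask
        caches[[li]] <- list(mask = mask)
      } else caches[[li]] <- list(mask = NULL)
    }
  }
  A <- A - rep(apply(A, 2, max), each = nrow(A))
  E <- exp(A)
  probs <- E / rep(colSums(E), each = nrow(E))
  list(probs = probs, caches = caches)
}

.xent <- function(probs, Y) {
  -mean(log(pmax(colSums(probs * Y), 1e-12)))
}

# Backward pass for softmax cross-entropy. Y: one-hot (n_classes x N).
.net_backward <- function(net, caches, probs, Y) {
  N <- ncol(probs)
  delta <- (probs - Y) / N
  grads <- vector("list", length(net$layers))
  for (li in rev(seq_along(net$layers))) {
    l <- net$layers[[li]]; ch <- caches[[li]]
    if (l$type == "dense") {
      dZ <- if (!is.null(ch$relu)) delta * ch$relu else delta
      grads[[li]] <- list(W = dZ %*% t(ch$Ain), b = rowSums(dZ))
      delta <- crossprod(l$W, dZ)
    } else if (l$type == "dropout") {
      if (!is.null(ch$mask)) delta <- delta * ch$mask
    } else if (l$type == "pool") {
      dIn <- matrix(0, l$inrows, ncol(delta))
      claimed <- matrix(FALSE, nrow(delta), ncol(delta))
      for (a in 1:4) {
        sel <- (ch$parts[[a]] == ch$Mx) & !claimed
        if (any(sel)) dIn[l$idx4[[a]], ] <- dIn[l$idx4[[a]], ] + delta * sel
        claimed <- claimed | sel
      }
      delta <- dIn
    } else if (l$type == "conv") {
      N_b <- ch$N
      dA <- array(delta, dim = c(l$outH, l$outW, l$cout, N_b))
      dZ <- aperm(dA, c(3, 1, 2, 4))
      dim(dZ) <- c(l$cout, l$P * N_b)
      dZ[!ch$relu] <- 0
      grads[[li]] <- list(W = dZ %*% t(ch$cols), b = rowSums(dZ))
      dCols <- crossprod(l$W, dZ)
      dim(dCols) <- c(l$K * l$P, N_b)
      rs <- rowsum(dCols, group = l$grp)
      dIn <- matrix(0, l$inrows, N_b)
      dIn[l$grp_rows, ] <- rs
      delta <- dIn
    }
  }
  grads
}

.adam_init <- function(net) {
  lapply(net$layers, function(l) {
    if (!is.null(l$W)) list(mW = l$W * 0, vW = l$W * 0,
                            mb = l$b * 0, vb = l$b * 0)
  })
}

.adam_step <- function(net, grads, st, lr, t,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (li in seq_along(net$layers)) {
    g <- grads[[li]]
    if (is.null(g)) next
    s <- st[[li]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    c1 <- 1 - beta1^t; c2 <- 1 - beta2^t
    net$layers[[li]]$W <- net$layers[[li]]$W -
      lr * (s$mW / c1) / (sqrt(s$vW / c2) + eps)
    net$layers[[li]]$b <- net$layers[[li]]$b -
      lr * (s$mb / c1) / (sqrt(s$vb / c2) + eps)
    st[[li]] <- s
  }
  list(net = net, st = st)
}
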