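# Minimal neural-network primitives on base-R matrices (BLAS-backed).
# Volumes are stored as V x C matrices (V voxels, column-major over the
# grid) with the grid dims carried alongside. Convolutions are im2col
# gathers followed by a single gemm; gradients are hand-derived.

# ---- im2col -----------------------------------------------------------------

conv_out_dim <- function(dims, ksize, stride, pad) {
  as.integer(floor((dims + 2 * pad - ksize) / stride) + 1)
}

# Precompute the gather index for a 3D convolution: a (Vout x K) integer
# matrix of linear voxel indices into the input grid, 0 marking zero-padding.
make_conv_index <- function(dims, ksize, stride = c(1L, 1L, 1L), pad = NULL) {
  dims <- as.integer(dims); ksize <- as.integer(ksize)
  stride <- as.integer(rep(stride, length.out = 3))
  if (is.null(pad)) pad <- (ksize - 1L) %/% 2L
  pad <- as.integer(rep(pad, length.out = 3))
  od <- conv_out_dim(dims, ksize, stride, pad)
  if (any(od < 1L)) stop("volume smaller than receptive field")
  vx <- rep.int(seq_len(od[1]) - 1L, times = od[2] * od[3]) * stride[1] - pad[1]
  vy <- rep.int(rep(seq_len(od[2]) - 1L, each = od[1]), times = od[3]) * stride[2] - pad[2]
  vz <- rep(seq_len(od[3]) - 1L, each = od[1] * od[2]) * stride[3] - pad[3]
  K <- prod(ksize)
  idx <- matrix(0L, length(vx), K)
  col <- 1L
  for (c3 in seq_len(ksize[3]) - 1L) for (c2 in seq_len(ksize[2]) - 1L)
    for (c1 in seq_len(ksize[1]) - 1L) {
      xx <- vx + c1; yy <- vy + c2; zz <- vz + c3
      ok <- xx >= 0L & xx < dims[1] & yy >= 0L & yy < dims[2] & zz >= 0L & zz < dims[3]
      lin <- xx + dims[1] * (yy + dims[2] * zz) + 1L
      lin[!ok] <- 0L
      idx[, col] <- lin
      col <- col + 1L
    }
  attr(idx, "out_dims") <- od
  attr(idx, "ksize") <- ksize
  attr(idx, "idxp") <- as.vector(idx) + 1L   # precomputed gather vector
  idx
}

# x: V x Cin. Returns Vout x (K*Cin) patch matrix.
im2col <- function(x, idx) {
  Vout <- nrow(idx); K <- ncol(idx); Cin <- ncol(x)
  idxp <- attr(idx, "idxp")
  if (is.null(idxp)) idxp <- as.vector(idx) + 1L
  nx <- nrow(x)
  cols <- matrix(0, Vout * K, Cin)
  for (ch in seq_len(Cin)) {
    xv <- c(0, x[, ch])                   # element 1 absorbs padding index 0
    cols[, ch] <- xv[idxp]
  }
  dim(cols) <- c(Vout, K * Cin)
  cols
}

conv3d_forward <- function(x, idx, W, b) {
  cols <- im2col(x, idx)
  y <- cols %*% W
  y <- sweep_add_rowvec(y, b)
  list(y = y, cols = cols)
}

sweep_add_rowvec <- function(m, v) {
  m + matrix(v, nrow(m), length(v), byrow = TRUE)
}

# dY: Vout x Cout. Returns gradients wrt W, b and (optionally) x.
conv3d_backward <- function(dY, cols, idx, W, Cin, need_dx = TRUE, Vin = NULL) {
  dW <- crossprod(cols, dY)
  db <- colSums(dY)
  dx <- NULL
  if (need_dx) {
    dcols <- dY %*% t(W)                  # Vout x (K*Cin)
    Vout <- nrow(idx); K <- ncol(idx)
    dim(dcols) <- c(Vout, K, Cin)
    dx <- matrix(0, Vin, Cin)
    for (k in seq_len(K)) {
      rows <- idx[, k]
      ok <- rows > 0L
      if (!any(ok)) next
      dk <- dcols[, k, , drop = FALSE]
      dim(dk) <- c(Vout, Cin)
      # accumulate; duplicate rows cannot occur within one kernel offset
      dx[rows[ok], ] <- dx[rows[ok], , drop = FALSE] + dk[ok, , drop = FALSE]
    }
  }
  list(dW = dW, db = db, dx = dx)
}

# ---- pooling / upsampling ---------------------------------------------------

# 2x2x2 max pooling (backbone only; no gradient needed there).
maxpool2 <- function(x, dims) {
  dims <- as.integer(dims)
  od <- dims %/% 2L
  a <- array(x, dim = c(dims, ncol(x)))
  a <- a[seq_len(od[1] * 2L), seq_len(od[2] * 2L), seq_len(od[3] * 2L), , drop = FALSE]
  m <- NULL
  for (i in 0:1) for (j in 0:1) for (k in 0:1) {
    s <- a[seq(1L + i, by = 2L, length.out = od[1]),
           seq(1L + j, by = 2L, length.out = od[2]),
           seq(1L + k, by = 2L, length.out = od[3]), , drop = FALSE]
    m <- if (is.null(m)) s else pmax(m, s)
  }
  list(y = matrix(m, prod(od), ncol(x)), out_dims = od)
}

# Sparse trilinear x2 upsampling operator (half-voxel aligned).
make_upsample2 <- function(dims) {
  dims <- as.integer(dims); od <- dims * 2L
  coord <- function(n_out, n_in) {
    xc <- ((seq_len(n_out) - 0.5) / 2) - 0.5
    x0 <- pmin(pmax(floor(xc), 0), n_in - 1)
    x1 <- pmin(x0 + 1, n_in - 1)
    w1 <- xc - floor(xc); w1[xc < 0] <- 0; w1[xc > n_in - 1] <- 0
    list(i0 = x0, i1 = x1, w1 = w1)
  }
  cx <- coord(od[1], dims[1]); cy <- coord(od[2], dims[2]); cz <- coord(od[3], dims[3])
  Vout <- prod(od)
  gx <- rep.int(seq_len(od[1]), times = od[2] * od[3])
  gy <- rep.int(rep(seq_len(od[2]), each = od[1]), times = od[3])
  gz <- rep(seq_len(od[3]), each = od[1] * od[2])
  ii <- integer(0); jj <- integer(0); ww <- numeric(0)
  for (bx in 0:1) for (by in 0:1) for (bz in 0:1) {
    xi <- if (bx == 0) cx$i0[gx] else cx$i1[gx]
    yi <- if (by == 0) cy$i0[gy] else cy$i1[gy]
    zi <- if (bz == 0) cz$i0[gz] else cz$i1[gz]
    wx <- if (bx == 0) 1 - cx$w1[gx] else cx$w1[gx]
    wy <- if (by == 0) 1 - cy$w1[gy] else cy$w1[gy]
    wz <- if (bz == 0) 1 - cz$w1[gz] else cz$w1[gz]
    w <- wx * wy * wz
    keep <- w > 0
    lin <- xi + dims[1] * (yi + dims[2] * zi) + 1
    ii <- c(ii, seq_len(Vout)[keep]); jj <- c(jj, lin[keep]); ww <- c(ww, w[keep])
  }
  U <- Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(Vout, prod(dims)))
  attr(U, "out_dims") <- od
  U
}

upsample_forward <- function(x, U) as.matrix(U %*% x)
upsample_backward <- function(dY, U) as.matrix(Matrix::crossprod(U, dY))

# ---- activations ------------------------------------------------------------

lrelu_forward <- function(x, alpha = 0.1) {
  neg <- x < 0
  y <- x; y[neg] <- alpha * x[neg]
  list(y = y, neg = neg, alpha = alpha)
}
lrelu_backward <- function(dY, cache) {
  dY[cache$neg] <- cache$alpha * dY[cache$neg]
  dY
}

relu_forward <- function(x) { neg <- x < 0; y <- x; y[neg] <- 0; list(y = y, neg = neg) }
relu_backward <- function(dY, cache) { dY[cache$neg] <- 0; dY }

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# ---- batch normalization (column-wise, non-affine) --------------------------

bn_state <- function(d) list(mean = numeric(d), var = rep(1, d), n = 0)

# Instance-style normalization over the node dimension: the branches process
# one sequence at a time, so the per-sample statistics are used in both
# training and evaluation (deterministic at inference, and no train/eval
# distribution gap). Running statistics are still tracked during training
# for diagnostics.
bn_forward <- function(x, state, training, momentum = 0.1, eps = 1e-5) {
  mu <- colMeans(x)
  xc <- sweep_add_rowvec(x, -mu)
  v <- colMeans(xc^2)
  ivar <- 1 / sqrt(v + eps)
  xhat <- xc * matrix(ivar, nrow(x), ncol(x), byrow = TRUE)
  if (training) {
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var  <- (1 - momentum) * state$var + momentum * v
    state$n <- state$n + 1
  }
  list(y = xhat, cache = list(xhat = xhat, ivar = ivar), state = state)
}

bn_backward <- function(dY, cache) {
  n <- nrow(dY)
  xhat <- cache$xhat
  ivar <- cache$ivar
  dmean <- colMeans(dY)
  dproj <- colMeans(dY * xhat)
  (dY - matrix(dmean, n, ncol(dY), byrow = TRUE) -
     xhat * matrix(dproj, n, ncol(dY), byrow = TRUE)) *
    matrix(ivar, n, ncol(dY), byrow = TRUE)
}

# ---- weight init and Adam ---------------------------------------------------

he_init <- function(nr, nc, fan_in = nr) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0, lr_scale = NULL) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (weight_decay > 0) g <- g + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    lr_nm <- if (!is.null(lr_scale) && !is.null(lr_scale[[nm]]))
      lr * lr_scale[[nm]] else lr
    params[[nm]] <- params[[nm]] -
      lr_nm * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# flat named list utilities for gradients
zero_like <- function(params) lapply(params, function(p) p * 0)
acc_grads <- function(a, b) { for (nm in names(b)) if (!is.null(b[[nm]]))
  a[[nm]] <- a[[nm]] + b[[nm]]; a }
scale_grads <- function(g, s) lapply(g, function(x) x * s)

# global-norm gradient clipping
clip_grads <- function(g, max_norm) {
  tot <- sqrt(sum(vapply(g, function(x) sum(x^2), numeric(1))))
  if (is.finite(tot) && tot > max_norm) g <- scale_grads(g, max_norm / tot)
  g
}
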