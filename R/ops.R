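# Low-level tensor operators with hand-derived backward passes.
#
# Activations are dense arrays with dim (H, W, N, C): spatial rows/cols,
# batch, channels. Channels-last makes channel concatenation a plain c()
# and lets every convolution reduce to K*K BLAS matrix products (one per
# kernel offset), which is what keeps the pure-R engine usable on a CPU.

t4 <- function(x) {
  d <- dim(x)
  stopifnot(length(d) == 4L)
  d
}

#' @noRd
as_mat <- function(x, nrow) {
  dim(x) <- c(nrow, length(x) %/% nrow)
  x
}

# ---- convolution (odd kernel, stride 1, zero "same" padding) ----
#
# Implemented as K*K flat matrix products over a zero-padded copy of the
# input: each kernel offset contributes block_matrix %*% W[dy, dx, , ] to
# the (H*W*N) x Cout output accumulator. The backward pass reuses the same
# scheme: the input gradient is the correlation of the padded output
# gradient with the spatially flipped kernel.

zero_pad <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1L] + 2L * p, d[2L] + 2L * p, d[3L], d[4L]))
  xp[p + seq_len(d[1L]), p + seq_len(d[2L]), , ] <- x
  xp
}

kernel_slice <- function(W, dy, dx) {
  Wk <- W[dy, dx, , , drop = FALSE]
  dim(Wk) <- dim(W)[3:4]
  Wk
}

conv_fwd <- function(x, W, b) {
  d <- t4(x)
  K <- dim(W)[1L]
  cin <- dim(W)[3L]
  cout <- dim(W)[4L]
  stopifnot(d[4L] == cin)
  p <- (K - 1L) %/% 2L
  H <- d[1L]; Wd <- d[2L]; N <- d[3L]
  hwn <- H * Wd * N
  xp <- zero_pad(x, p)
  out <- matrix(0, hwn, cout)
  for (dy in seq_len(K)) {
    for (dx in seq_len(K)) {
      blk <- xp[dy:(dy + H - 1L), dx:(dx + Wd - 1L), , , drop = FALSE]
      dim(blk) <- c(hwn, cin)
      out <- out + blk %*% kernel_slice(W, dy, dx)
    }
  }
  out <- out + rep(b, each = hwn)
  dim(out) <- c(H, Wd, N, cout)
  out
}

conv_bwd <- function(x, W, dy_out) {
  d <- t4(x)
  K <- dim(W)[1L]
  cin <- dim(W)[3L]
  cout <- dim(W)[4L]
  p <- (K - 1L) %/% 2L
  H <- d[1L]; Wd <- d[2L]; N <- d[3L]
  hwn <- H * Wd * N
  gm <- dy_out
  dim(gm) <- c(hwn, cout)
  xp <- zero_pad(x, p)
  gp <- zero_pad(dy_out, p)
  dW <- array(0, dim(W))
  dxm <- matrix(0, hwn, cin)
  for (dy in seq_len(K)) {
    for (dx in seq_len(K)) {
      blk <- xp[dy:(dy + H - 1L), dx:(dx + Wd - 1L), , , drop = FALSE]
      dim(blk) <- c(hwn, cin)
      dW[dy, dx, , ] <- crossprod(blk, gm)
      blkg <- gp[dy:(dy + H - 1L), dx:(dx + Wd - 1L), , , drop = FALSE]
      dim(blkg) <- c(hwn, cout)
      dxm <- dxm + tcrossprod(blkg, kernel_slice(W, K + 1L - dy, K + 1L - dx))
    }
  }
  db <- colSums(gm)
  dim(dxm) <- d
  list(dx = dxm, dW = dW, db = db)
}

# ---- 2x2 transposed convolution, stride 2 ----

convt2_fwd <- function(x, W, b) {
  d <- t4(x)
  cout <- dim(W)[4L]
  H <- d[1L]; Wd <- d[2L]; N <- d[3L]
  out <- array(0, c(2L * H, 2L * Wd, N, cout))
  m <- as_mat(x, H * Wd * N)
  for (a in 0:1) for (bb in 0:1) {
    r <- m %*% kernel_slice(W, a + 1L, bb + 1L)
    dim(r) <- c(H, Wd, N, cout)
    out[seq(1L + a, 2L * H, 2L), seq(1L + bb, 2L * Wd, 2L), , ] <- r
  }
  out + rep(b, each = 4L * H * Wd * N)
}

convt2_bwd <- function(x, W, dy_out) {
  d <- t4(x)
  H <- d[1L]; Wd <- d[2L]; N <- d[3L]
  m <- as_mat(x, H * Wd * N)
  dx <- array(0, d)
  dW <- array(0, dim(W))
  dxm <- matrix(0, H * Wd * N, d[4L])
  for (a in 0:1) for (bb in 0:1) {
    g <- dy_out[seq(1L + a, 2L * H, 2L), seq(1L + bb, 2L * Wd, 2L), , , drop = FALSE]
    g <- as_mat(g, H * Wd * N)
    dW[a + 1L, bb + 1L, , ] <- crossprod(m, g)
    dxm <- dxm + tcrossprod(g, kernel_slice(W, a + 1L, bb + 1L))
  }
  dim(dxm) <- d
  db <- colSums(as_mat(dy_out, 4L * H * Wd * N))
  list(dx = dxm, dW = dW, db = db)
}

# ---- max pooling ----

maxpool2_fwd <- function(x) {
  d <- t4(x)
  H <- d[1L]; Wd <- d[2L]
  stopifnot(H %% 2L == 0L, Wd %% 2L == 0L)
  io <- seq(1L, H, 2L); ie <- seq(2L, H, 2L)
  jo <- seq(1L, Wd, 2L); je <- seq(2L, Wd, 2L)
  cand <- list(
    x[io, jo, , , drop = FALSE], x[ie, jo, , , drop = FALSE],
    x[io, je, , , drop = FALSE], x[ie, je, , , drop = FALSE]
  )
  out <- cand[[1L]]
  idx <- array(1L, dim(out))
  for (k in 2:4) {
    better <- cand[[k]] > out
    out[better] <- cand[[k]][better]
    idx[better] <- k
  }
  list(out = out, idx = idx)
}

maxpool2_bwd <- function(dy_out, idx, in_dim) {
  H <- in_dim[1L]; Wd <- in_dim[2L]
  dx <- array(0, in_dim)
  io <- seq(1L, H, 2L); ie <- seq(2L, H, 2L)
  jo <- seq(1L, Wd, 2L); je <- seq(2L, Wd, 2L)
  sel <- list(list(io, jo), list(ie, jo), list(io, je), list(ie, je))
  for (k in 1:4) {
    g <- dy_out
    g[idx != k] <- 0
    dx[sel[[k]][[1L]], sel[[k]][[2L]], , ] <- dx[sel[[k]][[1L]], sel[[k]][[2L]], , , drop = FALSE] + g
  }
  dx
}

# 3x3 max pool, stride 1, same padding (inception pooling branch)
maxpool3s1_fwd <- function(x) {
  d <- t4(x)
  H <- d[1L]; Wd <- d[2L]
  out <- array(-Inf, d)
  idx <- array(0L, d)
  k <- 0L
  for (oy in -1:1) for (ox in -1:1) {
    k <- k + 1L
    y_out <- max(1L, 1L - oy):min(H, H - oy)
    x_out <- max(1L, 1L - ox):min(Wd, Wd - ox)
    shifted <- array(-Inf, d)
    shifted[y_out, x_out, , ] <- x[y_out + oy, x_out + ox, , , drop = FALSE]
    better <- shifted > out
    out[better] <- shifted[better]
    idx[better] <- k
  }
  list(out = out, idx = idx)
}

maxpool3s1_bwd <- function(dy_out, idx, in_dim) {
  H <- in_dim[1L]; Wd <- in_dim[2L]
  dx <- array(0, in_dim)
  k <- 0L
  for (oy in -1:1) for (ox in -1:1) {
    k <- k + 1L
    y_out <- max(1L, 1L - oy):min(H, H - oy)
    x_out <- max(1L, 1L - ox):min(Wd, Wd - ox)
    g <- dy_out[y_out, x_out, , , drop = FALSE]
    g[idx[y_out, x_out, , , drop = FALSE] != k] <- 0
    dx[y_out + oy, x_out + ox, , ] <- dx[y_out + oy, x_out + ox, , , drop = FALSE] + g
  }
  dx
}

# ---- batch normalization (per channel over H, W, N) ----

bn_fwd <- function(x, gamma, beta, rmean, rvar, training, momentum = 0.9, eps = 1e-3) {
  d <- t4(x)
  m <- prod(d[1:3])
  xm <- as_mat(x, m)
  if (training) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2L, mu)
    va <- colMeans(xc * xc)
    new_rmean <- momentum * rmean + (1 - momentum) * mu
    new_rvar <- momentum * rvar + (1 - momentum) * va
  } else {
    mu <- rmean
    va <- rvar
    xc <- sweep(xm, 2L, mu)
    new_rmean <- rmean
    new_rvar <- rvar
  }
  inv_sd <- 1 / sqrt(va + eps)
  xhat <- sweep(xc, 2L, inv_sd, `*`)
  y <- sweep(sweep(xhat, 2L, gamma, `*`), 2L, beta, `+`)
  dim(y) <- d
  list(out = y, cache = list(xhat = xhat, inv_sd = inv_sd, dim = d),
       rmean = new_rmean, rvar = new_rvar)
}

bn_bwd <- function(dy_out, gamma, cache) {
  d <- cache$dim
  m <- prod(d[1:3])
  g <- as_mat(dy_out, m)
  xhat <- cache$xhat
  dgamma <- colSums(g * xhat)
  dbeta <- colSums(g)
  # dx = gamma * inv_sd * (g - mean(g) - xhat * mean(g * xhat))
  gm <- colMeans(g)
  gxm <- colMeans(g * xhat)
  dx <- sweep(g, 2L, gm) - sweep(xhat, 2L, gxm, `*`)
  dx <- sweep(dx, 2L, gamma * cache$inv_sd, `*`)
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- pointwise and structural ops ----

relu_fwd <- function(x) {
  x[x < 0] <- 0
  x
}

relu_bwd <- function(dy_out, out) {
  dy_out[out <= 0] <- 0
  dy_out
}

sigmoid_fwd <- function(x) 1 / (1 + exp(-x))

sigmoid_bwd <- function(dy_out, out) dy_out * out * (1 - out)

softmax_fwd <- function(x) {
  d <- t4(x)
  m <- as_mat(x, prod(d[1:3]))
  mx <- m[, 1L]
  for (ch in seq_len(ncol(m))[-1L]) mx <- pmax(mx, m[, ch])
  m <- m - mx
  e <- exp(m)
  y <- e / rowSums(e)
  dim(y) <- d
  y
}

softmax_bwd <- function(dy_out, out) {
  d <- t4(out)
  n <- prod(d[1:3])
  g <- as_mat(dy_out, n)
  y <- as_mat(out, n)
  dot <- rowSums(g * y)
  dx <- y * (g - dot)
  dim(dx) <- d
  dx
}

# global average pool over H, W -> (1, 1, N, C)
gap_fwd <- function(x) {
  d <- t4(x)
  hw <- d[1L] * d[2L]
  m <- as_mat(x, hw)       # hw x (N*C)
  out <- colMeans(m)
  dim(out) <- c(1L, 1L, d[3L], d[4L])
  out
}

gap_bwd <- function(dy_out, in_dim) {
  hw <- in_dim[1L] * in_dim[2L]
  dx <- rep(as.vector(dy_out), each = hw) / hw
  dim(dx) <- in_dim
  dx
}

# x scaled by a one-channel spatial map psi (attention gating)
scale_spatial_fwd <- function(x, psi) {
  x * as.vector(psi)
}

scale_spatial_bwd <- function(dy_out, x, psi) {
  d <- t4(x)
  dx <- dy_out * as.vector(psi)
  prod_ <- as_mat(dy_out * x, prod(d[1:3]))
  dpsi <- rowSums(prod_)
  dim(dpsi) <- c(d[1:3], 1L)
  list(dx = dx, dscale = dpsi)
}

# x scaled per (sample, channel) by s with dim (1, 1, N, C) (SE recalibration)
scale_channel_fwd <- function(x, s) {
  d <- t4(x)
  x * rep(as.vector(s), each = d[1L] * d[2L])
}

scale_channel_bwd <- function(dy_out, x, s) {
  d <- t4(x)
  hw <- d[1L] * d[2L]
  dx <- dy_out * rep(as.vector(s), each = hw)
  ds <- colSums(as_mat(dy_out * x, hw))
  dim(ds) <- c(1L, 1L, d[3L], d[4L])
  list(dx = dx, dscale = ds)
}
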