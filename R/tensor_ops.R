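# Low-level dense-tensor primitives.  All feature maps are channels-first
# (C, D, H, W) double arrays; spatial convolutions are expressed as small
# sets of shifted BLAS matrix products, which keeps everything in vectorized
# R.  Each *_bwd function is the exact adjoint of its forward and is
# verified against finite differences in the test suite.

EPS_NORM <- 1e-5

seq_range <- function(a, b) if (a > b) integer(0) else a:b

## ---- 3x3x3 (or any odd k) convolution, stride 1, "same" padding, no bias ----

conv3d_fwd <- function(x, w, return_patches = FALSE) {
  dx <- dim(x)
  k <- dim(w)[3]
  cout <- dim(w)[1]
  X <- cpp_im2col3(x, dx, k)
  out <- matrix(w, cout) %*% X
  dim(out) <- c(cout, dx[2], dx[3], dx[4])
  if (return_patches) list(y = out, X = X) else out
}

# weight gradient from the forward's cached patch matrix; input gradient as
# a convolution of gout with the transposed, flipped kernel
conv3d_bwd <- function(X, w, gout, need_gx = TRUE) {
  k <- dim(w)[3]
  cout <- dim(w)[1]
  gm <- gout
  dim(gm) <- c(cout, length(gout) %/% cout)
  gw <- tcrossprod(gm, X)
  dim(gw) <- dim(w)
  gx <- NULL
  if (need_gx) {
    wt <- aperm(w[, , k:1, k:1, k:1, drop = FALSE], c(2, 1, 3, 4, 5))
    gx <- conv3d_fwd(gout, wt)
  }
  list(gx = gx, gw = gw)
}

## ---- pointwise (1x1x1) convolution, used by the output head ----

conv1_fwd <- function(x, w, b = NULL) {
  d <- dim(x)
  y <- w %*% as_cmat(x)
  if (!is.null(b)) y <- y + b
  dim(y) <- c(nrow(w), d[2], d[3], d[4])
  y
}

conv1_bwd <- function(x, w, gout, has_bias = TRUE) {
  d <- dim(x)
  g <- as_cmat(gout)
  xm <- as_cmat(x)
  gx <- t(w) %*% g
  dim(gx) <- d
  list(gx = gx, gw = g %*% t(xm), gb = if (has_bias) rowSums(g) else NULL)
}

## ---- factor-2 space/depth reshuffles (patch embedding, merging, upsampling) ----

# Channel block o (1..8) of the output holds the input sub-grid with offsets
# (dz, dy, dx); dz varies fastest.  depth_to_space is the exact inverse.
s2d_offsets <- local({
  g <- expand.grid(dz = 0:1, dy = 0:1, dx = 0:1)
  as.matrix(g)
})

space_to_depth <- function(x) {
  d <- dim(x); C <- d[1]
  if (any(d[2:4] %% 2L != 0L))
    stopf("spatial extents must be even to halve, got (%s)",
          paste(d[2:4], collapse = ", "))
  d2 <- d[2:4] %/% 2L
  out <- array(0, c(8L * C, d2))
  for (o in 1:8) {
    off <- s2d_offsets[o, ]
    out[((o - 1L) * C + 1L):(o * C), , , ] <-
      x[, seq(1L + off[1], d[2], 2L), seq(1L + off[2], d[3], 2L),
        seq(1L + off[3], d[4], 2L)]
  }
  out
}

depth_to_space <- function(y) {
  d <- dim(y); C <- d[1] %/% 8L
  out <- array(0, c(C, 2L * d[2], 2L * d[3], 2L * d[4]))
  for (o in 1:8) {
    off <- s2d_offsets[o, ]
    out[, seq(1L + off[1], 2L * d[2], 2L), seq(1L + off[2], 2L * d[3], 2L),
        seq(1L + off[3], 2L * d[4], 2L)] <-
      y[((o - 1L) * C + 1L):(o * C), , , , drop = FALSE]
  }
  out
}

# strided k=2 convolution: y = W %*% s2d(x) + b, W is (Cout x 8*Cin)
down_conv_fwd <- function(x, w, b = NULL) {
  s <- space_to_depth(x)
  d <- dim(s)
  y <- w %*% as_cmat(s)
  if (!is.null(b)) y <- y + b
  dim(y) <- c(nrow(w), d[2], d[3], d[4])
  list(y = y, s = s)
}

down_conv_bwd <- function(s, w, gout, has_bias = TRUE) {
  g <- as_cmat(gout)
  gs <- t(w) %*% g
  dim(gs) <- dim(s)
  list(gx = depth_to_space_inv(gs), gw = g %*% t(as_cmat(s)),
       gb = if (has_bias) rowSums(g) else NULL)
}

# adjoint of space_to_depth is the inverse reshuffle (a permutation)
depth_to_space_inv <- depth_to_space

# transposed k=2 stride-2 convolution: weight (8*Cout x Cin), no bias
up_conv_fwd <- function(x, w) {
  d <- dim(x)
  y8 <- w %*% as_cmat(x)
  dim(y8) <- c(nrow(w), d[2], d[3], d[4])
  depth_to_space(y8)
}

up_conv_bwd <- function(x, w, gout) {
  g8 <- space_to_depth(gout)
  gm <- as_cmat(g8)
  gx <- t(w) %*% gm
  dim(gx) <- dim(x)
  list(gx = gx, gw = gm %*% t(as_cmat(x)))
}

## ---- box-sum pooling (zero padding), the engine of the average-pool mixer ----

# Separable K-wide box sum along each spatial axis; self-adjoint under
# zero padding, which makes the pooling backward a single forward call.
sumpool3d <- function(x, k) {
  r <- (k - 1L) %/% 2L
  if (r == 0L) return(x)
  d <- dim(x)
  y <- x
  for (axis in 2:4) {
    n <- d[axis]
    acc <- y
    for (s in seq_len(min(r, n - 1L))) {
      lo <- 1L:(n - s); hi <- (1L + s):n
      if (axis == 2L) {
        acc[, lo, , ] <- acc[, lo, , , drop = FALSE] + y[, hi, , , drop = FALSE]
        acc[, hi, , ] <- acc[, hi, , , drop = FALSE] + y[, lo, , , drop = FALSE]
      } else if (axis == 3L) {
        acc[, , lo, ] <- acc[, , lo, , drop = FALSE] + y[, , hi, , drop = FALSE]
        acc[, , hi, ] <- acc[, , hi, , drop = FALSE] + y[, , lo, , drop = FALSE]
      } else {
        acc[, , , lo] <- acc[, , , lo, drop = FALSE] + y[, , , hi, drop = FALSE]
        acc[, , , hi] <- acc[, , , hi, drop = FALSE] + y[, , , lo, drop = FALSE]
      }
    }
    y <- acc
  }
  y
}

.pool_cache <- new.env(parent = emptyenv())

# per-voxel count of in-bounds neighbors, broadcast over channels
pool_counts <- function(d, k) {
  key <- paste(c(d, k), collapse = "x")
  hit <- .pool_cache[[key]]
  if (!is.null(hit)) return(hit)
  ones <- array(1, c(1L, d[2], d[3], d[4]))
  cnt3 <- sumpool3d(ones, k)[1, , , , drop = TRUE]
  full <- array(rep(as.numeric(cnt3), each = d[1]), d)
  .pool_cache[[key]] <- full
  full
}

avgpool3d_fwd <- function(x, k) {
  sumpool3d(x, k) / pool_counts(dim(x), k)
}

avgpool3d_bwd <- function(gout, k) {
  sumpool3d(gout / pool_counts(dim(gout), k), k)
}

## ---- normalizations ----

# layer norm across channels, one token per column; w/b length C or NULL
layer_norm_fwd <- function(x, w = NULL, b = NULL) {
  d <- dim(x)
  xm <- as_cmat(x)
  C <- d[1]
  mu <- colMeans(xm)
  xc <- xm - rep(mu, each = C)
  sd_ <- sqrt(colMeans(xc * xc) + EPS_NORM)
  xhat <- xc / rep(sd_, each = C)
  y <- if (is.null(w)) xhat else xhat * w + b
  dim(y) <- d
  list(y = y, xhat = xhat, sd = sd_)
}

layer_norm_bwd <- function(cache, w, gout) {
  d <- dim(gout)
  C <- d[1]
  g <- as_cmat(gout)
  xhat <- cache$xhat
  if (is.null(w)) {
    gw <- NULL; gb <- NULL; gxh <- g
  } else {
    gw <- rowSums(g * xhat)
    gb <- rowSums(g)
    gxh <- g * w
  }
  m1 <- colMeans(gxh)
  m2 <- colMeans(gxh * xhat)
  gx <- (gxh - rep(m1, each = C) - xhat * rep(m2, each = C)) /
    rep(cache$sd, each = C)
  dim(gx) <- d
  list(gx = gx, gw = gw, gb = gb)
}

# instance norm: per channel over all voxels, no affine parameters
instance_norm_fwd <- function(x) {
  d <- dim(x)
  xm <- as_cmat(x)
  mu <- rowMeans(xm)
  xc <- xm - mu
  sd_ <- sqrt(rowMeans(xc * xc) + EPS_NORM)
  xhat <- xc / sd_
  y <- xhat
  dim(y) <- d
  list(y = y, xhat = xhat, sd = sd_)
}

instance_norm_bwd <- function(cache, gout) {
  d <- dim(gout)
  g <- as_cmat(gout)
  xhat <- cache$xhat
  m1 <- rowMeans(g)
  m2 <- rowMeans(g * xhat)
  gx <- (g - m1 - xhat * m2) / cache$sd
  dim(gx) <- d
  gx
}

## ---- activations ----

lrelu_fwd <- function(x, slope = 0.01) {
  y <- x
  neg <- x < 0
  y[neg] <- slope * x[neg]
  y
}
lrelu_bwd <- function(x, gout, slope = 0.01) {
  g <- gout
  neg <- x < 0
  g[neg] <- slope * gout[neg]
  g
}

gelu_fwd <- function(x) x * stats::pnorm(x)
gelu_bwd <- function(x, gout) gout * (stats::pnorm(x) + x * stats::dnorm(x))

sigmoid <- function(x) 1 / (1 + exp(-x))

relu_fwd <- function(x) pmax(x, 0)
relu_bwd <- function(x, gout) gout * (x > 0)

## ---- token-space linear layer ----

linear_fwd <- function(x, w, b = NULL) {
  y <- w %*% x
  if (!is.null(b)) y <- y + b
  y
}

linear_bwd <- function(x, w, gout, has_bias = TRUE) {
  list(gx = t(w) %*% gout, gw = gout %*% t(x),
       gb = if (has_bias) rowSums(gout) else NULL)
}
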