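# Token mixers: the parameter-free spatial average-pooling operator, the
# windowed self-attention baseline it replaces, and squeeze-and-excitation
# channel recalibration.

#' Average-pooling token mixer
#'
#' Replaces self-attention: every voxel of every channel becomes the mean of
#' its `kernel^3` neighborhood.  Positions falling outside the volume are
#' excluded from both numerator and denominator, so a constant field is an
#' exact fixed point (including corners and edges).  The operator has no
#' trainable parameters and costs linear time in the number of voxels.
#'
#' @param x A `(C, D, H, W)` feature map array.
#' @param kernel Odd positive integer neighborhood width (default 3, the
#'   smallest centered 3D neighborhood).
#' @param subtract_identity If `TRUE`, return `pool(x) - x`, the residual
#'   form used by the PoolFormer lineage; the default is plain averaging.
#' @return A feature map with the same channels and spatial extents.
#' @examples
#' x <- array(1:9, c(1, 1, 3, 3))
#' average_pool_mixer(x, kernel = 3)[1, 1, 2, 2]  # 5, the full-window mean
#' @export
average_pool_mixer <- function(x, kernel = 3L, subtract_identity = FALSE) {
  check_feature_map(x)
  if (any(dim(x)[2:4] < 1L)) stopf("empty spatial extent")
  if (kernel < 1L || kernel %% 2L == 0L)
    stopf("pooling kernel must be an odd positive integer, got %s", kernel)
  y <- avgpool3d_fwd(x, as.integer(kernel))
  if (subtract_identity) y <- y - x
  y
}

#' Trainable-parameter count of a pooling mixer
#'
#' Always zero: the operator merely averages neighboring tokens.
#'
#' @param kernel Kernel width (ignored; any configuration is parameter-free).
#' @return `0L`.
#' @export
pool_mixer_parameters <- function(kernel = 3L) 0L

## ---- windowed self-attention ----------------------------------------------

#' Initialize windowed self-attention weights
#'
#' Creates query/key/value and output projections plus the learned
#' relative-position-bias table of a 3D shifted-window attention layer.
#'
#' @param dim Token embedding width; must be divisible by `heads`.
#' @param heads Number of attention heads.
#' @param window Configured window width per axis (the bias table is sized
#'   `(2 * window - 1)^3` rows regardless of the runtime window, which is
#'   clipped to the spatial extent).
#' @param init `"random"` (truncated normal, sd 0.02) or `"zero"`.
#' @return A parameter list (`qkv_w`, `qkv_b`, `proj_w`, `proj_b`, `rpb`).
#' @export
init_window_attention <- function(dim, heads, window = 7L, init = "random") {
  if (dim %% heads != 0L)
    stopf("attention dim %d is not divisible by %d heads", dim, heads)
  tbl <- (2L * window - 1L)^3
  gen <- function(n) if (init == "zero") numeric(n) else rtruncnorm2(n)
  list(
    qkv_w  = matrix(gen(3L * dim * dim), 3L * dim, dim),
    qkv_b  = numeric(3L * dim),
    proj_w = matrix(gen(dim * dim), dim, dim),
    proj_b = numeric(dim),
    rpb    = matrix(gen(tbl * heads), tbl, heads)
  )
}

# cached geometry for one (extent, window, shift) combination: padding,
# window partition permutation, relative-position index, shift mask
.attn_cache <- new.env(parent = emptyenv())

attn_geometry <- function(ext, window, shifted, table_window) {
  key <- paste(c(ext, window, shifted, table_window), collapse = "_")
  hit <- .attn_cache[[key]]
  if (!is.null(hit)) return(hit)

  ws <- pmin(window, ext)              # clip windows to the extent
  shift <- ifelse(shifted & ext > ws, ws %/% 2L, 0L)
  padded <- as.integer(ceiling(ext / ws) * ws)
  nwin <- padded %/% ws
  L <- prod(ws)

  # relative-position index into the (2*table_window-1)^3-row bias table
  coords <- as.matrix(expand.grid(z = seq_len(ws[1]), y = seq_len(ws[2]),
                                  x = seq_len(ws[3])))
  span <- 2L * table_window - 1L
  rel_idx <- matrix(0L, L, L)
  for (ax in 1:3) {
    rel <- outer(coords[, ax], coords[, ax], "-") + table_window - 1L
    rel_idx <- rel_idx * span + rel
  }
  rel_idx <- rel_idx + 1L

  # attention mask for cyclic-shifted windows: tokens from different
  # pre-shift regions must not attend to each other
  mask <- NULL
  if (any(shift > 0L)) {
    region <- array(0, c(1L, padded))
    axis_id <- function(n, w, s) {
      id <- integer(n)
      if (s > 0L) {
        id[seq_len(n) > n - w] <- 1L
        id[seq_len(n) > n - s] <- 2L
      }
      id
    }
    idz <- axis_id(padded[1], ws[1], shift[1])
    idy <- axis_id(padded[2], ws[2], shift[2])
    idx_ <- axis_id(padded[3], ws[3], shift[3])
    region[1, , , ] <- outer(outer(idz * 9L, idy * 3L, "+"), idx_, "+")
    region <- roll3(region, -shift)
    rw <- partition_windows(region, ws)    # (1, L, nw)
    nw <- dim(rw)[3]
    mask <- array(0, c(L, L, nw))
    for (w_ in seq_len(nw)) {
      ids <- rw[1, , w_]
      mask[, , w_] <- ifelse(outer(ids, ids, "!="), -1e9, 0)
    }
    if (all(mask == 0)) mask <- NULL
  }

  out <- list(ws = ws, shift = shift, padded = padded, nwin = nwin, L = L,
              rel_idx = rel_idx, mask = mask)
  .attn_cache[[key]] <- out
  out
}

# cyclic shift of the spatial axes of a (C, D, H, W) array
roll3 <- function(x, by) {
  d <- dim(x)
  idx <- lapply(1:3, function(ax) {
    n <- d[ax + 1L]
    s <- ((-by[ax]) %% n)
    if (s == 0L) seq_len(n) else c((s + 1L):n, 1L:s)
  })
  x[, idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

pad_end3 <- function(x, target) {
  d <- dim(x)
  if (all(d[2:4] == target)) return(x)
  out <- array(0, c(d[1], target))
  out[, seq_len(d[2]), seq_len(d[3]), seq_len(d[4])] <- x
  out
}

# (C, Dp, Hp, Wp) -> (C, L, nw); token order: z fastest within a window
partition_windows <- function(x, ws) {
  d <- dim(x)
  nw3 <- d[2:4] %/% ws
  dim(x) <- c(d[1], ws[1], nw3[1], ws[2], nw3[2], ws[3], nw3[3])
  x <- aperm(x, c(1, 2, 4, 6, 3, 5, 7))
  dim(x) <- c(d[1], prod(ws), prod(nw3))
  x
}

unpartition_windows <- function(xw, ws, padded) {
  d1 <- dim(xw)[1]
  nw3 <- padded %/% ws
  dim(xw) <- c(d1, ws[1], ws[2], ws[3], nw3[1], nw3[2], nw3[3])
  xw <- aperm(xw, c(1, 2, 5, 3, 6, 4, 7))
  dim(xw) <- c(d1, padded)
  xw
}

#' Apply windowed multi-head self-attention
#'
#' The baseline token mixer: tokens attend within non-overlapping (optionally
#' cyclically shifted) local windows, with a learned relative-position bias.
#' Spatial extents that are not window multiples are zero-padded and masked
#' implicitly by the window clipping; extents smaller than the window shrink
#' the runtime window (shift disabled on such axes).
#'
#' @param x `(C, D, H, W)` feature map with `C == dim`.
#' @param params Weights from [init_window_attention()].
#' @param heads Number of heads.
#' @param window Configured window width.
#' @param shifted Use the shifted-window variant (second block of a stage).
#' @param return_attention Also return the per-window attention matrices
#'   (rows sum to 1), for inspection and testing.
#' @return The mixed feature map, or a list `(y, attention)` when
#'   `return_attention` is `TRUE`.
#' @export
window_attention_mixer <- function(x, params, heads, window = 7L,
                                   shifted = FALSE, return_attention = FALSE) {
  res <- attn_fwd(x, params, heads, window, shifted,
                  keep_attention = return_attention)
  if (return_attention) list(y = res$y, attention = res$attention) else res$y
}

attn_fwd <- function(x, params, heads, window, shifted,
                     keep_attention = FALSE) {
  d <- dim(x); dm <- d[1]
  if (nrow(params$proj_w) != dm)
    stopf("attention weights are for dim %d, input has %d channels",
          nrow(params$proj_w), dm)
  tw <- as.integer(round((nrow(params$rpb)^(1 / 3) + 1) / 2))
  geo <- attn_geometry(d[2:4], rep(as.integer(window), 3L), shifted, tw)
  hd <- dm %/% heads
  scale <- 1 / sqrt(hd)

  xp <- pad_end3(x, geo$padded)
  if (any(geo$shift > 0L)) xp <- roll3(xp, -geo$shift)
  xw <- partition_windows(xp, geo$ws)          # (dm, L, nw)
  L <- geo$L; nw <- dim(xw)[3]

  qkv <- params$qkv_w %*% matrix(xw, dm) + params$qkv_b
  dim(qkv) <- c(3L * dm, L, nw)

  bias <- lapply(seq_len(heads), function(h)
    matrix(params$rpb[geo$rel_idx, h], L, L))

  yw <- array(0, c(dm, L, nw))
  attn_keep <- if (keep_attention) array(0, c(L, L, heads, nw)) else NULL
  for (w_ in seq_len(nw)) {
    for (h in seq_len(heads)) {
      rq <- (h - 1L) * hd + seq_len(hd)
      q <- qkv[rq, , w_, drop = TRUE]; dim(q) <- c(hd, L)
      k <- qkv[dm + rq, , w_, drop = TRUE]; dim(k) <- c(hd, L)
      v <- qkv[2L * dm + rq, , w_, drop = TRUE]; dim(v) <- c(hd, L)
      a <- crossprod(q, k) * scale + bias[[h]]
      if (!is.null(geo$mask)) a <- a + geo$mask[, , w_]
      a <- a - apply(a, 1, max)                 # stable softmax by row
      p <- exp(a)
      p <- p / rowSums(p)
      if (keep_attention) attn_keep[, , h, w_] <- p
      yw[rq, , w_] <- v %*% t(p)
    }
  }
  y <- params$proj_w %*% matrix(yw, dm) + params$proj_b
  dim(y) <- c(dm, L, nw)
  yp <- unpartition_windows(y, geo$ws, geo$padded)
  if (any(geo$shift > 0L)) yp <- roll3(yp, geo$shift)
  out <- yp[, seq_len(d[2]), seq_len(d[3]), seq_len(d[4]), drop = FALSE]
  list(y = out, cache = list(xw = xw, qkv = qkv, yw = yw, geo = geo,
                             heads = heads, hd = hd, scale = scale,
                             bias = bias, d = d),
       attention = attn_keep)
}

attn_bwd <- function(params, cache, gout) {
  geo <- cache$geo; d <- cache$d; dm <- d[1]
  heads <- cache$heads; hd <- cache$hd; scale <- cache$scale
  L <- geo$L

  gp <- pad_end3(gout, geo$padded)
  if (any(geo$shift > 0L)) gp <- roll3(gp, -geo$shift)
  gw_ <- partition_windows(gp, geo$ws)          # grad wrt proj output
  nw <- dim(gw_)[3]

  gmat <- matrix(gw_, dm)
  g_proj_w <- gmat %*% t(matrix(cache$yw, dm))
  g_proj_b <- rowSums(gmat)
  gyw <- t(params$proj_w) %*% gmat
  dim(gyw) <- c(dm, L, nw)

  gqkv <- array(0, c(3L * dm, L, nw))
  gA_sum <- array(0, c(L, L, heads))
  qkv <- cache$qkv
  for (w_ in seq_len(nw)) {
    for (h in seq_len(heads)) {
      rq <- (h - 1L) * hd + seq_len(hd)
      q <- qkv[rq, , w_, drop = TRUE]; dim(q) <- c(hd, L)
      k <- qkv[dm + rq, , w_, drop = TRUE]; dim(k) <- c(hd, L)
      v <- qkv[2L * dm + rq, , w_, drop = TRUE]; dim(v) <- c(hd, L)
      a <- crossprod(q, k) * scale + cache$bias[[h]]
      if (!is.null(geo$mask)) a <- a + geo$mask[, , w_]
      a <- a - apply(a, 1, max)
      p <- exp(a); p <- p / rowSums(p)

      go <- gyw[rq, , w_, drop = TRUE]; dim(go) <- c(hd, L)
      gv <- go %*% p
      gP <- crossprod(go, v)                    # (L, L)
      gA <- p * (gP - rowSums(gP * p))
      gA_sum[, , h] <- gA_sum[, , h] + gA
      gq <- scale * (k %*% t(gA))
      gk <- scale * (q %*% gA)
      gqkv[rq, , w_] <- gq
      gqkv[dm + rq, , w_] <- gk
      gqkv[2L * dm + rq, , w_] <- gv
    }
  }
  g_rpb <- matrix(0, nrow(params$rpb), heads)
  idx_vec <- as.vector(geo$rel_idx)
  for (h in seq_len(heads)) {
    acc <- rowsum(as.vector(gA_sum[, , h]), idx_vec)
    g_rpb[as.integer(rownames(acc)), h] <- acc[, 1]
  }
  gq_mat <- matrix(gqkv, 3L * dm)
  g_qkv_w <- gq_mat %*% t(matrix(cache$xw, dm))
  g_qkv_b <- rowSums(gq_mat)
  gxw <- t(params$qkv_w) %*% gq_mat
  dim(gxw) <- c(dm, L, nw)
  gxp <- unpartition_windows(gxw, geo$ws, geo$padded)
  if (any(geo$shift > 0L)) gxp <- roll3(gxp, geo$shift)
  gx <- gxp[, seq_len(d[2]), seq_len(d[3]), seq_len(d[4]), drop = FALSE]
  list(gx = gx,
       gparams = list(qkv_w = g_qkv_w, qkv_b = g_qkv_b,
                      proj_w = g_proj_w, proj_b = g_proj_b, rpb = g_rpb))
}

## ---- squeeze-and-excitation -------------------------------------------------

#' Initialize a squeeze-and-excitation block
#'
#' @param channels Number of feature channels.
#' @param reduction Bottleneck reduction ratio; must divide `channels`.
#' @param init `"random"` or `"zero"`.
#' @return Parameter list (`w1`, `b1`, `w2`, `b2`).
#' @export
init_se <- function(channels, reduction = 4L, init = "random") {
  if (channels %% reduction != 0L || channels %/% reduction < 1L)
    stopf("SE reduction %d must divide channel count %d and leave >= 1",
          reduction, channels)
  mid <- channels %/% reduction
  gen <- function(n) if (init == "zero") numeric(n) else rtruncnorm2(n)
  list(w1 = matrix(gen(mid * channels), mid, channels), b1 = numeric(mid),
       w2 = matrix(gen(channels * mid), channels, mid), b2 = numeric(channels))
}

#' Squeeze-and-excitation channel recalibration
#'
#' Computes a per-channel descriptor by global spatial averaging, passes it
#' through a two-layer bottleneck (rectifier, then logistic gate), and
#' rescales each channel of the input by its gate in `(0, 1)`.
#'
#' @param x `(C, D, H, W)` feature map.
#' @param weights Parameters from [init_se()].
#' @param return_gates Also return the gate vector.
#' @return The recalibrated feature map (or list with `gates`).
#' @export
se_recalibrate <- function(x, weights, return_gates = FALSE) {
  check_feature_map(x)
  if (ncol(weights$w1) != dim(x)[1])
    stopf("SE block expects %d channels, input has %d",
          ncol(weights$w1), dim(x)[1])
  f <- se_fwd(x, weights)
  if (return_gates) list(y = f$y, gates = f$g) else f$y
}

se_fwd <- function(x, p) {
  d <- dim(x)
  xm <- as_cmat(x)
  z <- rowMeans(xm)
  a1 <- as.vector(p$w1 %*% z + p$b1)
  h <- pmax(a1, 0)
  g <- sigmoid(as.vector(p$w2 %*% h + p$b2))
  y <- xm * g
  dim(y) <- d
  list(y = y, z = z, a1 = a1, h = h, g = g)
}

se_bwd <- function(x, p, cache, gout) {
  d <- dim(x)
  xm <- as_cmat(x)
  gm <- as_cmat(gout)
  gg <- rowSums(gm * xm)
  gx <- gm * cache$g
  ga2 <- gg * cache$g * (1 - cache$g)
  gw2 <- outer(ga2, cache$h)
  gb2 <- ga2
  gh <- as.vector(t(p$w2) %*% ga2)
  ga1 <- gh * (cache$a1 > 0)
  gw1 <- outer(ga1, cache$z)
  gb1 <- ga1
  gz <- as.vector(t(p$w1) %*% ga1)
  gx <- gx + gz / ncol(xm)          # rowMeans adjoint, recycled by column
  dim(gx) <- d
  list(gx = gx, gparams = list(w1 = gw1, b1 = gb1, w2 = gw2, b2 = gb2))
}
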