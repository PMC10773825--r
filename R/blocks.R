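# Block-level composition: MetaFormer-style transformer blocks (norm ->
# token mixer -> residual, norm -> feed-forward -> residual), patch
# embedding/merging, and the convolutional residual blocks of the U-shaped
# encoder/decoder.

#' Initialize a transformer block
#'
#' Builds the parameters of one MetaFormer-style block: two layer norms, a
#' token mixer, and a two-layer feed-forward network with expansion
#' `mlp_ratio` and GELU activation.  With `mixer = "pooling"` the mixer
#' itself is parameter-free; `pool_proj`/`pool_bias_table` optionally retain
#' the attention module's output projection and relative-position-bias
#' table so that a pooling block is a weight-layout drop-in for an
#' attention block (the table is never used by the forward pass).
#'
#' @param dim Channel width of the block.
#' @param mixer `"pooling"` or `"attention"`.
#' @param mlp_ratio Feed-forward expansion factor (default 4).
#' @param heads,window Attention hyperparameters (attention mixer only,
#'   plus the bias table when retained).
#' @param pool_kernel,subtract_identity Pooling hyperparameters.
#' @param pool_proj,pool_bias_table Retain the mixer output projection /
#'   bias table in a pooling block (both default `FALSE`: the pure
#'   MetaFormer form, whose mixer contributes zero parameters).
#' @param shifted Use shifted windows (attention mixer only).
#' @param init `"random"` or `"zero"`.
#' @return An object of class `mixer_block` with `$config` and `$params`.
#' @export
init_mixer_block <- function(dim, mixer = c("pooling", "attention"),
                             mlp_ratio = 4, heads = 3L, window = 7L,
                             pool_kernel = 3L, subtract_identity = FALSE,
                             pool_proj = FALSE, pool_bias_table = FALSE,
                             shifted = FALSE, init = "random") {
  mixer <- match.arg(mixer)
  hidden <- as.integer(round(mlp_ratio * dim))
  gen <- function(n) if (init == "zero") numeric(n) else rtruncnorm2(n)
  p <- list(norm1_w = rep(1, dim), norm1_b = numeric(dim))
  if (mixer == "attention") {
    p$attn <- init_window_attention(dim, heads, window, init)
  } else {
    if (pool_proj) {
      p$proj_w <- matrix(gen(dim * dim), dim, dim)
      p$proj_b <- numeric(dim)
    }
    if (pool_bias_table)
      p$rpb <- matrix(gen((2L * window - 1L)^3 * heads), (2L * window - 1L)^3,
                      heads)
  }
  p$norm2_w <- rep(1, dim); p$norm2_b <- numeric(dim)
  p$mlp_w1 <- matrix(gen(hidden * dim), hidden, dim)
  p$mlp_b1 <- numeric(hidden)
  p$mlp_w2 <- matrix(gen(dim * hidden), dim, hidden)
  p$mlp_b2 <- numeric(dim)
  structure(list(config = list(dim = dim, mixer = mixer, heads = heads,
                               window = window, pool_kernel = pool_kernel,
                               subtract_identity = subtract_identity,
                               pool_proj = pool_proj, shifted = shifted,
                               hidden = hidden),
                 params = p),
            class = "mixer_block")
}

#' Apply a transformer block
#'
#' Two residual sub-layers: `x + mixer(norm(x))` followed by
#' `x + mlp(norm(x))`.  Output shape equals input shape.
#'
#' @param x `(C, D, H, W)` feature map with `C` equal to the block `dim`.
#' @param block A `mixer_block` from [init_mixer_block()].
#' @return The transformed feature map.
#' @export
mixer_block <- function(x, block) {
  check_feature_map(x, channels = block$config$dim, what = "block input")
  block_fwd(x, block$params, block$config)$y
}

block_fwd <- function(x, p, cfg) {
  n1 <- layer_norm_fwd(x, p$norm1_w, p$norm1_b)
  cache <- list(x = x, n1 = n1)
  if (cfg$mixer == "attention") {
    at <- attn_fwd(n1$y, p$attn, cfg$heads, cfg$window, cfg$shifted)
    m <- at$y
    cache$attn <- at$cache
  } else {
    pm <- avgpool3d_fwd(n1$y, cfg$pool_kernel)
    if (isTRUE(cfg$subtract_identity)) pm <- pm - n1$y
    if (isTRUE(cfg$pool_proj)) {
      d <- dim(pm)
      cache$pm <- pm
      m <- p$proj_w %*% as_cmat(pm) + p$proj_b
      dim(m) <- d
    } else m <- pm
  }
  x2 <- x + m
  n2 <- layer_norm_fwd(x2, p$norm2_w, p$norm2_b)
  d2 <- dim(x2)
  a1 <- p$mlp_w1 %*% as_cmat(n2$y) + p$mlp_b1
  g1 <- gelu_fwd(a1)
  y2 <- p$mlp_w2 %*% g1 + p$mlp_b2
  dim(y2) <- d2
  cache$x2 <- x2; cache$n2 <- n2; cache$a1 <- a1; cache$g1 <- g1
  list(y = x2 + y2, cache = cache)
}

block_bwd <- function(p, cfg, cache, gout) {
  d <- dim(gout)
  gp <- list()
  # feed-forward branch
  gy2 <- as_cmat(gout)
  gp$mlp_b2 <- rowSums(gy2)
  gp$mlp_w2 <- gy2 %*% t(cache$g1)
  gg1 <- t(p$mlp_w2) %*% gy2
  ga1 <- gelu_bwd(cache$a1, gg1)
  gp$mlp_b1 <- rowSums(ga1)
  gp$mlp_w1 <- ga1 %*% t(as_cmat(cache$n2$y))
  gn2 <- t(p$mlp_w1) %*% ga1
  dim(gn2) <- d
  ln2 <- layer_norm_bwd(cache$n2, p$norm2_w, gn2)
  gp$norm2_w <- ln2$gw; gp$norm2_b <- ln2$gb
  gx2 <- gout + ln2$gx
  # mixer branch
  gm <- gx2
  if (cfg$mixer == "attention") {
    ab <- attn_bwd(p$attn, cache$attn, gm)
    gp$attn <- ab$gparams
    gn1 <- ab$gx
  } else {
    if (isTRUE(cfg$pool_proj)) {
      gmm <- as_cmat(gm)
      gp$proj_b <- rowSums(gmm)
      gp$proj_w <- gmm %*% t(as_cmat(cache$pm))
      gpm <- t(p$proj_w) %*% gmm
      dim(gpm) <- d
    } else gpm <- gm
    gn1 <- avgpool3d_bwd(gpm, cfg$pool_kernel)
    if (isTRUE(cfg$subtract_identity)) gn1 <- gn1 - gpm
  }
  ln1 <- layer_norm_bwd(cache$n1, p$norm1_w, gn1)
  gp$norm1_w <- ln1$gw; gp$norm1_b <- ln1$gb
  if (!is.null(p$rpb)) gp$rpb <- matrix(0, nrow(p$rpb), ncol(p$rpb))
  gx <- gx2 + ln1$gx
  list(gx = gx, gparams = gp[names(p)])
}

## ---- patch embedding --------------------------------------------------------

#' Initialize the patch embedding layer
#'
#' A strided linear (k=2, stride 2) projection that halves each spatial
#' extent and maps `in_channels` to the embedding width `C`.
#'
#' @param in_channels Input channel count.
#' @param C Embedding width.
#' @param init `"random"` or `"zero"`.
#' @return Parameter list (`w`: `C x 8*in_channels`, `b`: length `C`).
#' @export
init_patch_embed <- function(in_channels, C, init = "random") {
  gen <- function(n) if (init == "zero") numeric(n) else rtruncnorm2(n)
  list(w = matrix(gen(C * 8L * in_channels), C, 8L * in_channels),
       b = numeric(C))
}

#' Embed a volume into patch tokens
#'
#' @param volume `(in_channels, D, H, W)` feature map; all extents must be
#'   even.
#' @param weights Parameters from [init_patch_embed()].
#' @return A `(C, D/2, H/2, W/2)` token grid.
#' @export
patch_embed <- function(volume, weights) {
  check_feature_map(volume, channels = ncol(weights$w) %/% 8L,
                    what = "patch embedding input")
  if (any(dim(volume)[2:4] %% 2L != 0L))
    stopf("patch embedding requires even spatial extents, got (%s)",
          paste(dim(volume)[2:4], collapse = ", "))
  down_conv_fwd(volume, weights$w, weights$b)$y
}

## ---- patch merging ----------------------------------------------------------

#' Initialize a patch-merging layer
#'
#' Concatenates each 2x2x2 token neighborhood (8*dim channels), layer-
#' normalizes, and linearly reduces to `2*dim` channels, halving every
#' spatial extent while doubling the width.
#'
#' @param dim Input channel width.
#' @param init `"random"` or `"zero"`.
#' @return Parameter list (`norm_w`, `norm_b`, `red_w`).
#' @export
init_patch_merge <- function(dim, init = "random") {
  gen <- function(n) if (init == "zero") numeric(n) else rtruncnorm2(n)
  list(norm_w = rep(1, 8L * dim), norm_b = numeric(8L * dim),
       red_w = matrix(gen(2L * dim * 8L * dim), 2L * dim, 8L * dim))
}

#' Merge patches, halving resolution and doubling channels
#'
#' @param x `(C, D, H, W)` token grid; odd extents are zero-padded by one
#'   before merging.
#' @param weights Parameters from [init_patch_merge()].
#' @return A `(2C, ceil(D/2), ceil(H/2), ceil(W/2))` token grid.
#' @export
patch_merge <- function(x, weights) {
  check_feature_map(x, channels = ncol(weights$red_w) %/% 8L,
                    what = "patch merging input")
  merge_fwd(x, weights)$y
}

merge_fwd <- function(x, p) {
  d <- dim(x)
  target <- d[2:4] + d[2:4] %% 2L
  xp <- pad_end3(x, target)
  s <- space_to_depth(xp)
  n <- layer_norm_fwd(s, p$norm_w, p$norm_b)
  ds <- dim(s)
  y <- p$red_w %*% as_cmat(n$y)
  dim(y) <- c(nrow(p$red_w), ds[2], ds[3], ds[4])
  list(y = y, cache = list(d = d, target = target, s = s, n = n))
}

merge_bwd <- function(p, cache, gout) {
  g <- as_cmat(gout)
  gn <- t(p$red_w) %*% g
  dim(gn) <- dim(cache$s)
  g_red <- g %*% t(as_cmat(cache$n$y))
  ln <- layer_norm_bwd(cache$n, p$norm_w, gn)
  gxp <- depth_to_space_inv(ln$gx)
  d <- cache$d
  gx <- gxp[, seq_len(d[2]), seq_len(d[3]), seq_len(d[4]), drop = FALSE]
  list(gx = gx,
       gparams = list(norm_w = ln$gw, norm_b = ln$gb, red_w = g_red))
}

## ---- convolutional residual blocks -----------------------------------------

# Two bias-free 3x3x3 convolutions with non-affine instance norms and leaky
# ReLU, plus a projected identity (1x1x1 conv + norm) when channel counts
# differ.  This is the ResNet-style unit used on every skip path and in the
# decoder.
init_res_block <- function(in_channels, out_channels, init = "random") {
  gen <- function(n, fan_out) {
    if (init == "zero") numeric(n) else stats::rnorm(n, 0, sqrt(2 / fan_out))
  }
  p <- list(
    w1 = array(gen(out_channels * in_channels * 27L, out_channels * 27L),
               c(out_channels, in_channels, 3L, 3L, 3L)),
    w2 = array(gen(out_channels * out_channels * 27L, out_channels * 27L),
               c(out_channels, out_channels, 3L, 3L, 3L)))
  if (in_channels != out_channels)
    p$w3 <- matrix(gen(out_channels * in_channels, out_channels),
                   out_channels, in_channels)
  p
}

res_fwd <- function(x, p) {
  c1 <- conv3d_fwd(x, p$w1, return_patches = TRUE)
  i1 <- instance_norm_fwd(c1$y)
  a1 <- lrelu_fwd(i1$y)
  c2 <- conv3d_fwd(a1, p$w2, return_patches = TRUE)
  i2 <- instance_norm_fwd(c2$y)
  if (!is.null(p$w3)) {
    c3 <- conv1_fwd(x, p$w3)
    i3 <- instance_norm_fwd(c3)
    s <- i2$y + i3$y
  } else {
    i3 <- NULL
    s <- i2$y + x
  }
  list(y = lrelu_fwd(s),
       cache = list(x = x, X1 = c1$X, X2 = c2$X, i1 = i1, i2 = i2, i3 = i3,
                    s = s))
}

res_bwd <- function(p, cache, gout) {
  gs <- lrelu_bwd(cache$s, gout)
  gi2 <- instance_norm_bwd(cache$i2, gs)
  b2 <- conv3d_bwd(cache$X2, p$w2, gi2)
  ga1 <- lrelu_bwd(cache$i1$y, b2$gx)
  gi1 <- instance_norm_bwd(cache$i1, ga1)
  b1 <- conv3d_bwd(cache$X1, p$w1, gi1)
  gx <- b1$gx
  gp <- list(w1 = b1$gw, w2 = b2$gw)
  if (!is.null(p$w3)) {
    gi3 <- instance_norm_bwd(cache$i3, gs)
    b3 <- conv1_bwd(cache$x, p$w3, gi3, has_bias = FALSE)
    gx <- gx + b3$gx
    gp$w3 <- b3$gw
  } else {
    gx <- gx + gs
  }
  list(gx = gx, gparams = gp)
}
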