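# Network assembly and parameter accounting.  A network is a plain R object:
# a validated configuration plus a nested list of parameter arrays whose
# layout mirrors the architecture (patch embedding, four token-mixer stages
# with patch merging, five convolutional encoder blocks, five decoder
# blocks, optional squeeze-and-excitation, output head).

#' Model configuration
#'
#' The full architectural genotype from which a network is deterministically
#' built.  Stage channel widths are `C, 2C, 4C, 8C` with a `16C` bottleneck;
#' the spatial extent is halved by the patch embedding and after each of the
#' four stages, so `roi` must be divisible by 32.
#'
#' `pool_proj` and `pool_bias_table` control whether pooling-mixer blocks
#' retain the attention module's output projection and relative-position
#' bias table in their weight layout.  Both default to `TRUE`, the
#' configuration whose parameter totals match the reference counts of the
#' four published variants (see [reference_parameter_counts()]); set both to
#' `FALSE` for the pure MetaFormer block in which the mixer contributes zero
#' parameters.
#'
#' @param feature_size Embedding width `C` of stage 1 (e.g. 24-84).
#' @param in_channels,out_channels Input volume channels / output classes.
#' @param mixer `"attention"` (windowed self-attention baseline) or
#'   `"pooling"` (parameter-free average pooling).
#' @param use_se Insert squeeze-and-excitation blocks after every encoder
#'   conv block and every decoder block.
#' @param depths Blocks per stage (default `c(2, 2, 2, 2)`).
#' @param heads Attention heads per stage (default `c(3, 6, 12, 24)`).
#' @param window Attention window width (default 7).
#' @param pool_kernel Odd pooling kernel width (default 3).
#' @param subtract_identity Pooling mixer computes `pool(x) - x`.
#' @param pool_proj,pool_bias_table See description.
#' @param mlp_ratio Feed-forward expansion (default 4).
#' @param se_reduction SE bottleneck ratio (default 4; must divide `C`).
#' @param roi Training patch extent `(D, H, W)`, divisible by 32.
#' @param head `"softmax"` (mutually exclusive classes, e.g. organ labels)
#'   or `"sigmoid"` (overlapping region channels, e.g. nested tumor
#'   regions).
#' @return A validated `model_config` list.
#' @export
model_config <- function(feature_size = 48L, in_channels = 1L,
                         out_channels = 14L,
                         mixer = c("attention", "pooling"), use_se = FALSE,
                         depths = c(2L, 2L, 2L, 2L),
                         heads = c(3L, 6L, 12L, 24L), window = 7L,
                         pool_kernel = 3L, subtract_identity = FALSE,
                         pool_proj = TRUE, pool_bias_table = TRUE,
                         mlp_ratio = 4, se_reduction = 4L,
                         roi = c(96L, 96L, 96L),
                         head = c("softmax", "sigmoid")) {
  mixer <- match.arg(mixer)
  head <- match.arg(head)
  if (length(depths) != 4L || any(depths < 1L))
    stopf("depths must give a positive block count for each of 4 stages")
  if (length(roi) == 1L) roi <- rep(roi, 3L)
  if (any(roi %% 32L != 0L))
    stopf("roi must be divisible by 32 (five successive halvings), got (%s)",
          paste(roi, collapse = ", "))
  if (pool_kernel %% 2L == 0L)
    stopf("pool_kernel must be odd, got %d", pool_kernel)
  dims <- feature_size * 2L^(0:3)
  if (any(dims %% heads != 0L))
    stopf("stage widths (%s) must be divisible by heads (%s)",
          paste(dims, collapse = ","), paste(heads, collapse = ","))
  if (use_se && feature_size %% se_reduction != 0L)
    stopf("feature_size %d not divisible by se_reduction %d",
          feature_size, se_reduction)
  structure(list(feature_size = as.integer(feature_size),
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 mixer = mixer, use_se = use_se,
                 depths = as.integer(depths), heads = as.integer(heads),
                 window = as.integer(window),
                 pool_kernel = as.integer(pool_kernel),
                 subtract_identity = subtract_identity,
                 pool_proj = pool_proj, pool_bias_table = pool_bias_table,
                 mlp_ratio = mlp_ratio, se_reduction = as.integer(se_reduction),
                 roi = as.integer(roi), head = head),
            class = "model_config")
}

#' Preset: multi-modal brain MRI configuration
#'
#' Four input modalities, three overlapping tumor-region output channels
#' (whole tumor, tumor core, enhancing tumor) with a sigmoid head, 128^3
#' patches, `C = 48` by default.
#'
#' @param feature_size Embedding width (default 48).
#' @param ... Passed to [model_config()].
#' @return A `model_config`.
#' @export
brain_model_config <- function(feature_size = 48L, ...) {
  model_config(feature_size = feature_size, in_channels = 4L,
               out_channels = 3L, head = "sigmoid",
               roi = c(128L, 128L, 128L), ...)
}

#' Preset: abdominal CT configuration
#'
#' One input channel, 14 softmax classes (13 organs plus background),
#' 96^3 region of interest.
#'
#' @param feature_size Embedding width (default 24).
#' @param ... Passed to [model_config()].
#' @return A `model_config`.
#' @export
abdomen_model_config <- function(feature_size = 24L, ...) {
  model_config(feature_size = feature_size, in_channels = 1L,
               out_channels = 14L, head = "softmax",
               roi = c(96L, 96L, 96L), ...)
}

# per-block forward configuration for stage i, block b
block_config <- function(cfg, stage, blk) {
  list(dim = cfg$feature_size * 2L^(stage - 1L), mixer = cfg$mixer,
       heads = cfg$heads[stage], window = cfg$window,
       pool_kernel = cfg$pool_kernel,
       subtract_identity = cfg$subtract_identity,
       pool_proj = cfg$pool_proj,
       shifted = (cfg$mixer == "attention") && (blk %% 2L == 0L),
       hidden = as.integer(round(cfg$mlp_ratio * cfg$feature_size *
                                   2L^(stage - 1L))))
}

#' Build a network from a configuration
#'
#' Deterministically assembles the full parameter tree.  With
#' `init = "random"`, weights are drawn under `seed` (truncated normal for
#' transformer weights, fan-out-scaled normal for convolutions, zeros for
#' biases); with `init = "shapes"`, only parameter shapes are allocated,
#' which is sufficient for parameter accounting of large models.
#'
#' @param config A [model_config()].
#' @param seed Integer seed for weight initialization.
#' @param init `"random"` or `"shapes"`.
#' @return An object of class `seg_network` (`$config`, `$params`).
#' @export
build_network <- function(config, seed = 1L, init = c("random", "shapes")) {
  init <- match.arg(init)
  stopifnot(inherits(config, "model_config"))
  C <- config$feature_size
  shapes_only <- init == "shapes"

  tn <- function(...) {            # truncated-normal transformer weight
    d <- as.integer(c(...))
    if (shapes_only) return(param_shape(d))
    out <- array(rtruncnorm2(prod(d)), d)
    if (length(d) == 2L) dim(out) <- d
    out
  }
  fo <- function(...) {            # fan-out-scaled conv weight
    d <- as.integer(c(...))
    if (shapes_only) return(param_shape(d))
    fan_out <- d[1] * prod(d[-(1:2)])
    array(stats::rnorm(prod(d), 0, sqrt(2 / fan_out)), d)
  }
  zeros <- function(n) if (shapes_only) param_shape(n) else numeric(n)
  ones <- function(n) if (shapes_only) param_shape(n) else rep(1, n)

  build <- function() {
    p <- list()
    p$patch_embed <- list(w = tn(C, 8L * config$in_channels), b = zeros(C))
    p$stages <- lapply(1:4, function(i) {
      d <- C * 2L^(i - 1L)
      tbl <- (2L * config$window - 1L)^3
      blocks <- lapply(seq_len(config$depths[i]), function(b) {
        bp <- list(norm1_w = ones(d), norm1_b = zeros(d))
        if (config$mixer == "attention") {
          bp$attn <- list(qkv_w = tn(3L * d, d), qkv_b = zeros(3L * d),
                          proj_w = tn(d, d), proj_b = zeros(d),
                          rpb = tn(tbl, config$heads[i]))
        } else {
          if (config$pool_proj) {
            bp$proj_w <- tn(d, d); bp$proj_b <- zeros(d)
          }
          if (config$pool_bias_table) bp$rpb <- tn(tbl, config$heads[i])
        }
        bp$norm2_w <- ones(d); bp$norm2_b <- zeros(d)
        hid <- as.integer(round(config$mlp_ratio * d))
        bp$mlp_w1 <- tn(hid, d); bp$mlp_b1 <- zeros(hid)
        bp$mlp_w2 <- tn(d, hid); bp$mlp_b2 <- zeros(d)
        bp
      })
      list(blocks = blocks,
           merge = list(norm_w = ones(8L * d), norm_b = zeros(8L * d),
                        red_w = tn(2L * d, 8L * d)))
    })
    res_p <- function(cin, cout) {
      if (shapes_only) {
        rp <- list(w1 = param_shape(cout, cin, 27L),
                   w2 = param_shape(cout, cout, 27L))
        if (cin != cout) rp$w3 <- param_shape(cout, cin)
        return(rp)
      }
      rp <- list(w1 = fo(cout, cin, 3, 3, 3), w2 = fo(cout, cout, 3, 3, 3))
      if (cin != cout)
        rp$w3 <- matrix(stats::rnorm(cout * cin, 0, sqrt(2 / cout)),
                        cout, cin)
      rp
    }
    p$enc1 <- res_p(config$in_channels, C)
    p$enc2 <- res_p(C, C)
    p$enc3 <- res_p(2L * C, 2L * C)
    p$enc4 <- res_p(4L * C, 4L * C)
    p$bottleneck <- res_p(16L * C, 16L * C)
    up_p <- function(cin, cout) {
      list(up_w = if (shapes_only) param_shape(8L * cout, cin)
           else matrix(rtruncnorm2(8L * cout * cin), 8L * cout, cin),
           res = res_p(2L * cout, cout))
    }
    p$dec5 <- up_p(16L * C, 8L * C)
    p$dec4 <- up_p(8L * C, 4L * C)
    p$dec3 <- up_p(4L * C, 2L * C)
    p$dec2 <- up_p(2L * C, C)
    p$dec1 <- up_p(C, C)
    if (config$use_se) {
      se_p <- function(ch) {
        mid <- ch %/% config$se_reduction
        if (shapes_only)
          list(w1 = param_shape(mid, ch), b1 = param_shape(mid),
               w2 = param_shape(ch, mid), b2 = param_shape(ch))
        else init_se(ch, config$se_reduction)
      }
      p$se_enc <- lapply(C * c(1L, 1L, 2L, 4L, 16L), se_p)
      p$se_dec <- lapply(C * c(8L, 4L, 2L, 1L, 1L), se_p)
    }
    p$head <- list(w = if (shapes_only) param_shape(config$out_channels, C)
                   else matrix(rtruncnorm2(config$out_channels * C),
                               config$out_channels, C),
                   b = zeros(config$out_channels))
    p
  }
  params <- if (shapes_only) build() else with_seed(seed, build())
  structure(list(config = config, params = params, seed = seed),
            class = "seg_network")
}

#' @export
print.seg_network <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<seg_network> %s mixer%s | C=%d in=%d out=%d | %s head\n",
              cfg$mixer, if (cfg$use_se) " + SE" else "",
              cfg$feature_size, cfg$in_channels, cfg$out_channels, cfg$head))
  cat(sprintf("  trainable parameters: %s\n",
              format(count_parameters(x)$total, big.mark = ",")))
  invisible(x)
}

#' Count trainable parameters
#'
#' Exact integer tally of trainable parameters, grouped by architectural
#' component.  Counts depend only on the configuration, never on the region
#' of interest or the initialization seed.
#'
#' @param net A `seg_network` (built with values or shapes).
#' @return A `parameter_report`: list with `$components` (data.frame of
#'   `component`, `parameters`) and `$total`.
#' @export
count_parameters <- function(net) {
  stopifnot(inherits(net, "seg_network"))
  p <- net$params
  comp <- c(
    patch_embed = tree_size(p$patch_embed),
    stats::setNames(vapply(1:4, function(i) tree_size(p$stages[[i]]),
                           numeric(1)), paste0("stage", 1:4)),
    encoder1 = tree_size(p$enc1), encoder2 = tree_size(p$enc2),
    encoder3 = tree_size(p$enc3), encoder4 = tree_size(p$enc4),
    bottleneck = tree_size(p$bottleneck),
    decoder5 = tree_size(p$dec5), decoder4 = tree_size(p$dec4),
    decoder3 = tree_size(p$dec3), decoder2 = tree_size(p$dec2),
    decoder1 = tree_size(p$dec1),
    se = tree_size(p$se_enc) + tree_size(p$se_dec),
    head = tree_size(p$head))
  structure(list(components = data.frame(component = names(comp),
                                         parameters = unname(comp)),
                 total = sum(comp),
                 config = net$config),
            class = "parameter_report")
}

#' @export
print.parameter_report <- function(x, ...) {
  df <- x$components
  df$parameters <- format(df$parameters, big.mark = ",")
  print(df, row.names = FALSE)
  cat(sprintf("total: %s\n", format(x$total, big.mark = ",")))
  invisible(x)
}

#' Parameters inside the token mixers only
#'
#' Sums qkv/projection/bias-table parameters across all transformer blocks.
#' Zero for a pooling network built in its pure MetaFormer form.
#'
#' @param net A `seg_network`.
#' @return Integer-valued total.
#' @export
mixer_parameters <- function(net) {
  tot <- 0
  for (st in net$params$stages) for (bp in st$blocks) {
    tot <- tot + tree_size(bp$attn) +
      tree_size(bp$proj_w) + tree_size(bp$proj_b) + tree_size(bp$rpb)
  }
  tot
}
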