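# End-to-end network execution.  The forward pass mirrors the U-shaped
# design: a token-mixer encoder produces hidden states at five resolutions,
# convolutional residual blocks project the raw input and each hidden state
# onto the skip paths, and the decoder upsamples with transposed
# convolutions, concatenating skips and refining with residual blocks.
# net_bwd() is the hand-derived adjoint of net_fwd(); gradients are checked
# against finite differences in the test suite.

net_fwd <- function(net, x, keep = FALSE) {
  cfg <- net$config
  p <- net$params
  check_feature_map(x, channels = cfg$in_channels, what = "input volume")
  if (any(dim(x)[2:4] %% 32L != 0L))
    stopf("input extents (%s) must be divisible by 32",
          paste(dim(x)[2:4], collapse = ", "))
  K <- list()   # caches

  pe <- down_conv_fwd(x, p$patch_embed$w, p$patch_embed$b)
  K$pe_s <- pe$s
  hn <- vector("list", 5L)   # normalized hidden states
  Kstage <- vector("list", 4L)
  Khn <- vector("list", 5L)
  h <- pe$y
  hnorm <- layer_norm_fwd(h)
  hn[[1]] <- hnorm$y; Khn[[1]] <- hnorm
  for (i in 1:4) {
    bl <- vector("list", cfg$depths[i])
    for (b in seq_len(cfg$depths[i])) {
      bc <- block_config(cfg, i, b)
      bf <- block_fwd(h, p$stages[[i]]$blocks[[b]], bc)
      h <- bf$y
      bl[[b]] <- bf$cache
    }
    mf <- merge_fwd(h, p$stages[[i]]$merge)
    h <- mf$y
    Kstage[[i]] <- list(blocks = bl, merge = mf$cache)
    hnorm <- layer_norm_fwd(h)
    hn[[i + 1L]] <- hnorm$y; Khn[[i + 1L]] <- hnorm
  }

  se_apply <- function(xin, sp, slot) {
    if (is.null(sp)) return(list(y = xin, cache = NULL))
    sf <- se_fwd(xin, sp)
    list(y = sf$y, cache = c(sf["z"], sf["a1"], sf["h"], sf["g"],
                             list(x = xin)))
  }
  sep <- function(lst, i) if (cfg$use_se) lst[[i]] else NULL

  enc_in <- list(x, hn[[1]], hn[[2]], hn[[3]], hn[[5]])
  enc_p <- list(p$enc1, p$enc2, p$enc3, p$enc4, p$bottleneck)
  enc_out <- vector("list", 5L)
  Kenc <- vector("list", 5L)
  Ksee <- vector("list", 5L)
  for (i in 1:5) {
    rf <- res_fwd(enc_in[[i]], enc_p[[i]])
    se <- se_apply(rf$y, sep(p$se_enc, i), i)
    enc_out[[i]] <- se$y
    Kenc[[i]] <- rf$cache
    Ksee[[i]] <- se$cache
  }

  dec_p <- list(p$dec5, p$dec4, p$dec3, p$dec2, p$dec1)
  skips <- list(hn[[4]], enc_out[[4]], enc_out[[3]], enc_out[[2]],
                enc_out[[1]])
  Kdec <- vector("list", 5L)
  Ksed <- vector("list", 5L)
  d <- enc_out[[5]]
  for (i in 1:5) {
    up <- up_conv_fwd(d, dec_p[[i]]$up_w)
    skip <- skips[[i]]
    cat_in <- array(0, c(dim(up)[1] + dim(skip)[1], dim(up)[2:4]))
    cat_in[seq_len(dim(up)[1]), , , ] <- up
    cat_in[dim(up)[1] + seq_len(dim(skip)[1]), , , ] <- skip
    rf <- res_fwd(cat_in, dec_p[[i]]$res)
    se <- se_apply(rf$y, sep(p$se_dec, i), i)
    Kdec[[i]] <- list(up_in = d, cat_in = cat_in, res = rf$cache,
                      n_up = dim(up)[1])
    Ksed[[i]] <- se$cache
    d <- se$y
  }
  logits <- conv1_fwd(d, p$head$w, p$head$b)
  cache <- if (keep) list(x = x, Kstage = Kstage, Khn = Khn, pe_s = pe$s,
                          Kenc = Kenc, Ksee = Ksee, Kdec = Kdec,
                          Ksed = Ksed, d_final = d, enc_in = enc_in)
  else NULL
  list(logits = logits, cache = cache)
}

net_bwd <- function(net, cache, glogits) {
  cfg <- net$config
  p <- net$params
  gp <- tree_map(p, function(leaf) {
    if (is.null(dim(leaf))) numeric(length(leaf)) else array(0, dim(leaf))
  })

  hb <- conv1_bwd(cache$d_final, p$head$w, glogits)
  gp$head$w <- hb$gw; gp$head$b <- hb$gb
  gd <- hb$gx

  se_back <- function(gy, sp, kc) {
    if (is.null(sp)) return(list(gx = gy, gparams = NULL))
    se_bwd(kc$x, sp, kc, gy)
  }
  sep <- function(lst, i) if (cfg$use_se) lst[[i]] else NULL

  dec_p <- list(p$dec5, p$dec4, p$dec3, p$dec2, p$dec1)
  dec_nm <- c("dec5", "dec4", "dec3", "dec2", "dec1")
  gskips <- vector("list", 5L)
  for (i in 5:1) {
    sb <- se_back(gd, sep(p$se_dec, i), cache$Ksed[[i]])
    if (!is.null(sb$gparams)) gp$se_dec[[i]] <- sb$gparams
    rb <- res_bwd(dec_p[[i]]$res, cache$Kdec[[i]]$res, sb$gx)
    gp[[dec_nm[i]]]$res <- rb$gparams
    n_up <- cache$Kdec[[i]]$n_up
    gup <- rb$gx[seq_len(n_up), , , , drop = FALSE]
    gskips[[i]] <- rb$gx[n_up + seq_len(dim(rb$gx)[1] - n_up), , , ,
                         drop = FALSE]
    ub <- up_conv_bwd(cache$Kdec[[i]]$up_in, dec_p[[i]]$up_w, gup)
    gp[[dec_nm[i]]]$up_w <- ub$gw
    gd <- ub$gx
  }
  # gd now reaches the bottleneck encoder output (enc_out[[5]])
  genc_out <- list(gskips[[5]], gskips[[4]], gskips[[3]], gskips[[2]], gd)

  enc_p <- list(p$enc1, p$enc2, p$enc3, p$enc4, p$bottleneck)
  enc_nm <- c("enc1", "enc2", "enc3", "enc4", "bottleneck")
  ghn <- vector("list", 5L)    # grads wrt normalized hidden states
  for (i in 1:5) {
    sb <- se_back(genc_out[[i]], sep(p$se_enc, i), cache$Ksee[[i]])
    if (!is.null(sb$gparams)) gp$se_enc[[i]] <- sb$gparams
    rb <- res_bwd(enc_p[[i]], cache$Kenc[[i]], sb$gx)
    gp[[enc_nm[i]]] <- rb$gparams
    if (i == 1L) next                    # gradient wrt raw input: discarded
    ghn[[i]] <- rb$gx
  }
  # hidden-state grads: hn[[1]]<-enc2, hn[[2]]<-enc3, hn[[3]]<-enc4,
  # hn[[4]]<-decoder5 skip, hn[[5]]<-bottleneck
  ghidden_n <- list(ghn[[2]], ghn[[3]], ghn[[4]], gskips[[1]], ghn[[5]])

  gh <- NULL  # gradient flowing backwards through the stage chain
  for (i in 4:1) {
    gtop <- layer_norm_bwd(cache$Khn[[i + 1L]], NULL, ghidden_n[[i + 1L]])$gx
    gh <- if (is.null(gh)) gtop else gh + gtop
    mb <- merge_bwd(p$stages[[i]]$merge, cache$Kstage[[i]]$merge, gh)
    gp$stages[[i]]$merge <- mb$gparams
    gh <- mb$gx
    for (b in cfg$depths[i]:1) {
      bc <- block_config(cfg, i, b)
      bb <- block_bwd(p$stages[[i]]$blocks[[b]], bc,
                      cache$Kstage[[i]]$blocks[[b]], gh)
      gp$stages[[i]]$blocks[[b]] <- bb$gparams
      gh <- bb$gx
    }
  }
  gh <- gh + layer_norm_bwd(cache$Khn[[1]], NULL, ghidden_n[[1]])$gx
  pb <- down_conv_bwd(cache$pe_s, p$patch_embed$w, gh)
  gp$patch_embed$w <- pb$gw; gp$patch_embed$b <- pb$gb
  gp
}

#' Run a forward pass
#'
#' Processes a volume through the full encoder-decoder network, producing
#' one logit map per output channel at the input resolution.
#'
#' @param net A `seg_network` built with `init = "random"` (weights, not
#'   shapes).
#' @param volume `(in_channels, D, H, W)` array with extents divisible
#'   by 32.
#' @return A `(out_channels, D, H, W)` array of logits.
#' @export
forward_pass <- function(net, volume) {
  if (inherits(net$params$patch_embed$w, "param_shape"))
    stopf("network was built at shape level; rebuild with init = \"random\"")
  net_fwd(net, volume, keep = FALSE)$logits
}
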