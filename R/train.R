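# Seeded training loop: random patch -> forward -> soft Dice loss ->
# backward -> AdamW step.  Defaults mirror the reference protocol (batch
# size 1, learning rate 1e-4); short smoke runs use a larger rate, set
# explicitly by the caller.

adamw_init <- function(params) {
  zero <- function(x) if (is.null(dim(x))) numeric(length(x))
  else array(0, dim(x))
  list(t = 0L, m = tree_map(params, zero), v = tree_map(params, zero))
}

adamw_step <- function(params, grads, state, lr, weight_decay = 1e-5,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  step_leaf <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    upd <- (m / bc1) / (sqrt(v / bc2) + eps)
    p <- p - lr * (upd + weight_decay * p)
    list(p = p, m = m, v = v)
  }
  rec <- function(p, g, m, v) {
    if (!is.list(p)) return(step_leaf(p, g, m, v))
    out_p <- p; out_m <- m; out_v <- v
    for (i in seq_along(p)) {
      r <- rec(p[[i]], g[[i]], m[[i]], v[[i]])
      out_p[[i]] <- r$p; out_m[[i]] <- r$m; out_v[[i]] <- r$v
    }
    list(p = out_p, m = out_m, v = out_v)
  }
  r <- rec(params, grads, state$m, state$v)
  list(params = r$p, state = list(t = state$t, m = r$m, v = r$v))
}

# build the training target for one label patch under the given head
make_target <- function(label_patch, config) {
  if (config$head == "sigmoid") {
    masks <- brats_region_masks(label_patch)
    tgt <- array(0, c(3L, dim(label_patch)))
    tgt[1, , , ] <- masks$WT; tgt[2, , , ] <- masks$TC; tgt[3, , , ] <- masks$ET
    tgt
  } else {
    labels_to_onehot(label_patch, 0:(config$out_channels - 1L))
  }
}

#' Train a network on in-memory samples
#'
#' Step-bounded optimization with batch size 1: each step crops a random
#' patch from the next sample (cycled), computes the soft Dice loss under
#' the network's head, backpropagates, and applies an AdamW update.  All
#' randomness (crops, initialization already fixed in `net`) flows from
#' `seed`, so two runs with identical inputs produce identical losses.
#'
#' @param net A `seg_network` with materialized weights.
#' @param samples List of samples, each `list(image, label)` with a
#'   channels-first image.
#' @param steps Number of optimization steps.
#' @param lr Learning rate (reference default `1e-4`).
#' @param weight_decay AdamW decoupled weight decay.
#' @param patch_size Patch extent (default: the config `roi`).
#' @param normalize `"none"`, `"nonzero_zscore"` or `"window_scale"`,
#'   applied to each patch.
#' @param lr_schedule `"constant"` or `"cosine"` decay over `steps`.
#' @param smooth Dice smoothing constant.
#' @param seed Master seed for the run.
#' @param verbose Print the loss every few steps.
#' @return List with `$net` (trained), `$losses` (per-step), `$log`
#'   (data.frame step/lr/loss).
#' @export
train_model <- function(net, samples, steps = 100L, lr = 1e-4,
                        weight_decay = 1e-5, patch_size = NULL,
                        normalize = "none",
                        lr_schedule = c("constant", "cosine"),
                        smooth = 1e-5, seed = 1L, verbose = FALSE) {
  lr_schedule <- match.arg(lr_schedule)
  cfg <- net$config
  patch_size <- as.integer(rep(patch_size %||% cfg$roi, length.out = 3L))
  if (any(patch_size %% 32L != 0L))
    stopf("patch size must be divisible by 32")
  stopifnot(length(samples) >= 1L)
  params <- net$params
  state <- adamw_init(params)
  losses <- numeric(steps)
  lrs <- numeric(steps)
  with_seed(seed, {
    for (s in seq_len(steps)) {
      smp <- samples[[((s - 1L) %% length(samples)) + 1L]]
      cp <- random_crop_patch(smp$image, smp$label, patch_size)
      img <- cp$image
      if (normalize != "none") img <- normalize_intensity(img, normalize)
      tgt <- make_target(cp$label, cfg)
      net$params <- params
      fw <- net_fwd(net, img, keep = TRUE)
      sl <- segmentation_loss(fw$logits, tgt, cfg$head, smooth = smooth)
      losses[s] <- sl$loss
      grads <- net_bwd(net, fw$cache, sl$glogits)
      lr_s <- if (lr_schedule == "cosine")
        lr * 0.5 * (1 + cos(pi * (s - 1) / steps)) else lr
      lrs[s] <- lr_s
      upd <- adamw_step(params, grads, state, lr_s, weight_decay)
      params <- upd$params
      state <- upd$state
      if (verbose && (s %% 10L == 0L || s == 1L))
        message(sprintf("step %4d  lr %.2e  dice loss %.4f", s, lr_s,
                        losses[s]))
    }
  })
  net$params <- params
  list(net = net, losses = losses,
       log = data.frame(step = seq_len(steps), lr = lrs, loss = losses))
}

#' Save / load a network checkpoint
#'
#' A checkpoint is a single file holding the weights plus the embedded
#' configuration (also serialized as JSON for interoperability).
#'
#' @param net A `seg_network`.
#' @param path Destination file (`.rds`).
#' @param extra Optional named list stored alongside.
#' @return `path` invisibly.
#' @export
save_checkpoint <- function(net, path, extra = list()) {
  obj <- list(config = unclass(net$config),
              config_json = jsonlite::toJSON(unclass(net$config),
                                             auto_unbox = TRUE),
              params = net$params, extra = extra)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  cfg <- structure(obj$config, class = "model_config")
  structure(list(config = cfg, params = obj$params, extra = obj$extra),
            class = "seg_network")
}
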