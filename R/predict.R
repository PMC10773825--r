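# Sliding-window whole-volume inference and evaluation tables.

#' Sliding-window prediction
#'
#' Tiles the volume with patch-sized windows (stride `roi * (1 - overlap)`,
#' final tile flush with the far edge), averages logits over overlapping
#' tiles, and converts them into labels under the network head: per-region
#' sigmoid thresholding at 0.5 for overlapping-region heads (then layered
#' into labels 2/1/4), channel argmax for softmax heads.  Volumes smaller
#' than the window are zero-padded and the output is cropped back.
#'
#' @param net A trained `seg_network`.
#' @param image `(in_channels, D, H, W)` array.
#' @param overlap Fractional tile overlap in `[0, 1)` (default 0.5).
#' @param roi Window extent (default: config `roi`).
#' @return List with `$logits` (`out_channels` first) and `$labels`
#'   (`D, H, W` integer array).
#' @export
predict_volume <- function(net, image, overlap = 0.5, roi = NULL) {
  cfg <- net$config
  check_feature_map(image, channels = cfg$in_channels, what = "volume")
  roi <- as.integer(rep(roi %||% cfg$roi, length.out = 3L))
  d0 <- dim(image)[2:4]
  target <- pmax(d0, roi)
  img <- image
  if (any(target > d0)) {
    img <- array(0, c(dim(image)[1], target))
    img[, seq_len(d0[1]), seq_len(d0[2]), seq_len(d0[3])] <- image
  }
  d <- dim(img)[2:4]
  stride <- pmax(1L, as.integer(round(roi * (1 - overlap))))
  starts <- lapply(1:3, function(ax) {
    s <- unique(c(seq(1L, d[ax] - roi[ax] + 1L, by = stride[ax]),
                  d[ax] - roi[ax] + 1L))
    s
  })
  acc <- array(0, c(cfg$out_channels, d))
  cnt <- array(0, c(1L, d))
  for (z in starts[[1]]) for (y in starts[[2]]) for (x_ in starts[[3]]) {
    iz <- z:(z + roi[1] - 1L); iy <- y:(y + roi[2] - 1L)
    ix <- x_:(x_ + roi[3] - 1L)
    tile <- img[, iz, iy, ix, drop = FALSE]
    lg <- net_fwd(net, tile, keep = FALSE)$logits
    acc[, iz, iy, ix] <- acc[, iz, iy, ix, drop = FALSE] + lg
    cnt[, iz, iy, ix] <- cnt[, iz, iy, ix, drop = FALSE] + 1
  }
  logits <- acc / rep(cnt[1, , , ], each = cfg$out_channels)
  logits <- logits[, seq_len(d0[1]), seq_len(d0[2]), seq_len(d0[3]),
                   drop = FALSE]
  labels <- decide_labels(logits, cfg$head)
  list(logits = logits, labels = labels)
}

#' Convert logits to label decisions
#'
#' @param logits `(K, D, H, W)` logit array.
#' @param head `"sigmoid"` (K = 3 nested region channels WT/TC/ET) or
#'   `"softmax"` (K mutually exclusive classes labelled `0..K-1`).
#' @return `(D, H, W)` integer label array.
#' @export
decide_labels <- function(logits, head) {
  k <- dim(logits)[1]
  if (head == "sigmoid") {
    p <- sigmoid(logits)
    masks <- list(WT = p[1, , , ] >= 0.5, TC = p[2, , , ] >= 0.5,
                  ET = p[3, , , ] >= 0.5)
    region_masks_to_labels(masks)
  } else {
    d <- dim(logits)[2:4]
    lm <- matrix(as_cmat(logits), nrow = k)
    arg <- max.col(t(lm), ties.method = "first") - 1L
    array(as.integer(arg), d)
  }
}

#' Per-subject, per-class Dice evaluation
#'
#' For the brain regime the three overlapping regions (WT, TC, ET) are
#' compared; for the abdominal regime each organ label (background
#' excluded) is compared one-vs-rest.
#'
#' @param predictions Named list of predicted `(D, H, W)` label arrays.
#' @param references Named list of reference label arrays (same names).
#' @param task `"brain"` or `"abdomen"`.
#' @param n_classes Organ count for the abdominal regime (default 13).
#' @return data.frame: one row per subject, one column per class, plus
#'   `mean`.
#' @export
evaluate_predictions <- function(predictions, references,
                                 task = c("brain", "abdomen"),
                                 n_classes = 13L) {
  task <- match.arg(task)
  ids <- names(predictions)
  unmatched <- c(setdiff(ids, names(references)),
                 setdiff(names(references), ids))
  if (length(unmatched) > 0L)
    stopf("unmatched identifier(s): %s", paste(unmatched, collapse = ", "))
  rows <- lapply(ids, function(id) {
    p <- predictions[[id]]; r <- references[[id]]
    if (task == "brain") {
      pm <- brats_region_masks(p); rm_ <- brats_region_masks(r)
      vals <- vapply(c("TC", "WT", "ET"), function(reg)
        dice_score(pm[[reg]], rm_[[reg]]), numeric(1))
    } else {
      vals <- vapply(seq_len(n_classes), function(c_)
        dice_score(p == c_, r == c_), numeric(1))
      names(vals) <- paste0("organ", seq_len(n_classes))
    }
    c(vals, mean = mean(vals))
  })
  out <- as.data.frame(do.call(rbind, rows))
  out <- cbind(id = ids, out)
  rownames(out) <- NULL
  out
}
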