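# Soft Dice loss, Dice metric, overlapping tumor-region construction, and
# cross-validation aggregation arithmetic.

#' Soft Dice loss
#'
#' `1 - 2*sum(p*g) / (sum(p^2) + sum(g^2))`, computed per class and averaged.
#' A small smoothing constant is added to numerator and denominator to
#' guard the empty/empty case; set `smooth = 0` for the exact formula.
#'
#' @param prediction Numeric array of per-voxel predictions in `[0, 1]`.
#'   If 4D, the first dimension indexes classes; otherwise a single class.
#' @param ground_truth Binary array congruent with `prediction`.
#' @param smooth Smoothing constant (default `1e-5`).
#' @return The loss, in `[0, 1]` for predictions in `[0, 1]`.
#' @examples
#' soft_dice_loss(c(1, 1, 0, 0), c(1, 0, 1, 0), smooth = 0)  # 0.5
#' @export
soft_dice_loss <- function(prediction, ground_truth, smooth = 1e-5) {
  if (!identical(dim(prediction) %||% length(prediction),
                 dim(ground_truth) %||% length(ground_truth)))
    stopf("prediction and ground truth shapes differ")
  if (!all(ground_truth %in% c(0, 1)))
    stopf("ground truth must be binary")
  per_class <- function(p, g) {
    num <- 2 * sum(p * g) + smooth
    den <- sum(p * p) + sum(g * g) + smooth
    if (den == 0) return(0)        # both empty, exact formula: perfect
    1 - num / den
  }
  if (!is.null(dim(prediction)) && length(dim(prediction)) == 4L) {
    k <- dim(prediction)[1]
    mean(vapply(seq_len(k), function(c_)
      per_class(prediction[c_, , , ], ground_truth[c_, , , ]), numeric(1)))
  } else {
    per_class(prediction, ground_truth)
  }
}

#' Dice overlap score
#'
#' `2|p & g| / (|p| + |g|)` for binarized masks; when both masks are empty
#' the score is defined as `empty_value` (1 by convention).
#'
#' @param prediction,ground_truth Binary arrays of equal shape.
#' @param empty_value Score when both masks are empty (default 1).
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_score <- function(prediction, ground_truth, empty_value = 1) {
  if (length(prediction) != length(ground_truth))
    stopf("prediction and ground truth sizes differ")
  p <- as.logical(prediction); g <- as.logical(ground_truth)
  tot <- sum(p) + sum(g)
  if (tot == 0) return(empty_value)
  2 * sum(p & g) / tot
}

#' Overlapping tumor-region masks from a label volume
#'
#' Multi-modal brain tumor labels use 0 (background), 1 (necrotic /
#' non-enhancing core), 2 (peritumoral edema) and 4 (enhancing tumor); the
#' evaluated regions are nested unions: whole tumor `WT = {1, 2, 4}`,
#' tumor core `TC = {1, 4}`, enhancing tumor `ET = {4}`.
#'
#' @param labels Integer array with values in the label set.
#' @param regions Named list of label subsets (defaults to WT/TC/ET).
#' @param label_set Permitted label values.
#' @return Named list of 0/1 arrays, one per region, with
#'   `ET <= TC <= WT` nesting by construction.
#' @export
brats_region_masks <- function(labels,
                               regions = list(WT = c(1, 2, 4),
                                              TC = c(1, 4), ET = 4),
                               label_set = c(0, 1, 2, 4)) {
  bad <- setdiff(unique(as.vector(labels)), label_set)
  if (length(bad) > 0L)
    stopf("unexpected label value(s): %s", paste(sort(bad), collapse = ", "))
  lapply(regions, function(r) {
    m <- array(as.numeric(labels %in% r), dim(labels) %||% length(labels))
    m
  })
}

#' Convert region masks back to a label volume
#'
#' Inverse of [brats_region_masks()] for nested predictions: edema where
#' only the whole tumor fires, necrotic core where the core fires without
#' enhancement, enhancing tumor where the innermost mask fires.
#'
#' @param masks Named list or `(3, D, H, W)` array ordered WT, TC, ET.
#' @return Integer label array over `{0, 1, 2, 4}`.
#' @export
region_masks_to_labels <- function(masks) {
  if (is.list(masks)) {
    wt <- masks$WT; tc <- masks$TC; et <- masks$ET
  } else {
    wt <- masks[1, , , ]; tc <- masks[2, , , ]; et <- masks[3, , , ]
  }
  lab <- array(0L, dim(wt) %||% length(wt))
  lab[wt > 0] <- 2L
  lab[tc > 0] <- 1L
  lab[et > 0] <- 4L
  lab
}

#' Aggregate cross-validation Dice results
#'
#' Given a complete fold-by-class grid of Dice values, computes the
#' per-class mean over folds, the per-fold mean over classes, and the grand
#' average (mean of the per-class averages).
#'
#' @param per_fold_per_class Numeric matrix or data.frame with folds as
#'   rows and classes as columns.
#' @return A list with `$class_means`, `$fold_means`, `$grand`, and
#'   `$table` (classes x folds with an appended average row and column).
#' @export
aggregate_cv_results <- function(per_fold_per_class) {
  m <- as.matrix(per_fold_per_class)
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)
    cells <- apply(idx, 1, function(r)
      sprintf("fold %s / class %s",
              rownames(m)[r[1]] %||% r[1], colnames(m)[r[2]] %||% r[2]))
    stopf("missing Dice value(s): %s", paste(cells, collapse = "; "))
  }
  if (is.null(rownames(m))) rownames(m) <- paste0("fold", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("class", seq_len(ncol(m)))
  class_means <- colMeans(m)
  fold_means <- rowMeans(m)
  grand <- mean(class_means)
  tab <- rbind(cbind(t(m), Avg = class_means),
               Avg = c(fold_means, grand))
  list(class_means = class_means, fold_means = fold_means, grand = grand,
       table = tab)
}

## ---- heads and training loss ------------------------------------------------

# channel-wise one-hot encoding of an integer label volume
labels_to_onehot <- function(labels, classes) {
  d <- dim(labels)
  out <- array(0, c(length(classes), d))
  for (i in seq_along(classes)) out[i, , , ] <- as.numeric(labels == classes[i])
  out
}

# loss and logit gradient for one prediction/target pair
segmentation_loss <- function(logits, target, head, smooth = 1e-5,
                              with_grad = TRUE) {
  k <- dim(logits)[1]
  if (head == "sigmoid") {
    p <- sigmoid(logits)
  } else {
    mx <- apply(logits, c(2, 3, 4), max)
    e <- exp(logits - rep(mx, each = k))
    ssum <- apply(e, c(2, 3, 4), sum)
    p <- e / rep(ssum, each = k)
  }
  loss <- 0
  gp <- if (with_grad) array(0, dim(p)) else NULL
  for (c_ in seq_len(k)) {
    pc <- p[c_, , , ]; gc_ <- target[c_, , , ]
    num <- 2 * sum(pc * gc_) + smooth
    den <- sum(pc * pc) + sum(gc_ * gc_) + smooth
    loss <- loss + (1 - num / den)
    if (with_grad)
      gp[c_, , , ] <- (-2 * gc_ * den + 2 * pc * num) / (den * den) / k
  }
  loss <- loss / k
  if (!with_grad) return(list(loss = loss, p = p))
  if (head == "sigmoid") {
    glogits <- gp * p * (1 - p)
  } else {
    inner <- apply(gp * p, c(2, 3, 4), sum)
    glogits <- p * (gp - rep(inner, each = k))
  }
  list(loss = loss, glogits = glogits, p = p)
}
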