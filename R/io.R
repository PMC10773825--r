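# Volume input/output, dataset manifests, patch cropping, intensity
# normalization, and the five-fold split protocol.  All in-memory volumes
# are channels-first (C, D, H, W) arrays; NIfTI affines pass
# through untouched via the on-disk reference file.

#' Read a subject volume (and optional label map)
#'
#' Accepts one single- or multi-channel NIfTI image (4D files are treated
#' as channel-last and permuted) or a vector of single-channel files that
#' are stacked in the given order (for brain MRI: T1, T1Gd, T2, T2-FLAIR).
#'
#' @param record A list with `$image` (path or character vector of paths),
#'   optional `$label` (path) and `$id`.
#' @param label_set Optional permitted label values; violations raise an
#'   error naming the offending value.
#' @return A list with `$image` (`C, D, H, W` array), `$label`
#'   (`D, H, W` integer array or `NULL`), `$id`, and `$reference` (path of
#'   the first image file, used for affine-preserving write-back).
#' @export
read_volume <- function(record, label_set = NULL) {
  paths <- record$image
  missing <- paths[!file.exists(paths)]
  if (!is.null(record$label) && !file.exists(record$label))
    missing <- c(missing, record$label)
  if (length(missing) > 0L)
    stopf("missing file(s): %s", paste(missing, collapse = ", "))
  vols <- lapply(paths, function(pp) {
    a <- RNifti::readNifti(pp)
    array(as.numeric(a), dim(a))
  })
  if (length(vols) == 1L) {
    a <- vols[[1]]
    d <- dim(a)
    img <- if (length(d) == 4L) aperm(a, c(4, 1, 2, 3))
    else array(a, c(1L, d))
  } else {
    d <- dim(vols[[1]])
    if (length(d) != 3L) stopf("multi-file records must hold 3D channels")
    for (v in vols) if (!identical(dim(v), d))
      stopf("channel extents disagree: (%s) vs (%s)",
            paste(d, collapse = ","), paste(dim(v), collapse = ","))
    img <- array(0, c(length(vols), d))
    for (i in seq_along(vols)) img[i, , , ] <- vols[[i]]
  }
  lab <- NULL
  if (!is.null(record$label)) {
    lab_img <- RNifti::readNifti(record$label)
    lab <- array(as.numeric(lab_img), dim(lab_img))
    if (length(dim(lab)) == 4L && dim(lab)[4] == 1L) dim(lab) <- dim(lab)[1:3]
    if (!identical(as.integer(dim(lab)), as.integer(dim(img)[2:4])))
      stopf("label extent (%s) does not match image extent (%s)",
            paste(dim(lab), collapse = ","),
            paste(dim(img)[2:4], collapse = ","))
    lab <- array(as.integer(round(lab)), dim(lab))
    if (!is.null(label_set)) {
      bad <- setdiff(unique(as.vector(lab)), label_set)
      if (length(bad) > 0L)
        stopf("label file %s contains unexpected value(s): %s",
              record$label, paste(sort(bad), collapse = ", "))
    }
  }
  list(id = record$id %||% basename(paths[1]), image = img, label = lab,
       reference = paths[1])
}

#' Write a segmentation label volume as NIfTI
#'
#' @param labels `(D, H, W)` integer array.
#' @param reference Path of a NIfTI file whose affine/header to reuse, or
#'   a list with `$reference` as returned by [read_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_segmentation <- function(labels, reference, path) {
  if (is.list(reference)) reference <- reference$reference
  ref_img <- RNifti::readNifti(reference)
  rd <- dim(ref_img)[1:3]
  if (!identical(as.integer(dim(labels)), as.integer(rd)))
    stopf("label extent (%s) does not match reference extent (%s)",
          paste(dim(labels), collapse = ","), paste(rd, collapse = ","))
  out <- array(as.integer(labels), dim(labels))
  img <- RNifti::asNifti(out, reference = ref_img, datatype = "int16")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Normalize image intensities
#'
#' `nonzero_zscore` (MRI regime): per channel, nonzero voxels are shifted
#' and scaled to mean 0 / sd 1; exact zeros (background) stay zero.
#' `window_scale` (CT regime): intensities are clipped to `window` and
#' mapped linearly onto `[0, 1]`.
#'
#' @param image `(C, D, H, W)` array.
#' @param scheme Normalization scheme.
#' @param window Length-2 intensity window for `window_scale`.
#' @return The normalized array.
#' @export
normalize_intensity <- function(image,
                                scheme = c("nonzero_zscore", "window_scale"),
                                window = c(-175, 250)) {
  scheme <- match.arg(scheme)
  check_feature_map(image)
  if (!all(is.finite(image))) stopf("image contains non-finite values")
  if (scheme == "window_scale") {
    lo <- window[1]; hi <- window[2]
    out <- pmin(pmax(image, lo), hi)
    out <- (out - lo) / (hi - lo)
    dim(out) <- dim(image)
    return(out)
  }
  out <- image
  for (c_ in seq_len(dim(image)[1])) {
    ch <- image[c_, , , ]
    nz <- ch != 0
    if (!any(nz)) {
      warning(sprintf("channel %d is identically zero; left unchanged", c_))
      next
    }
    mu <- mean(ch[nz])
    sd_ <- stats::sd(ch[nz])
    if (!is.finite(sd_) || sd_ == 0) sd_ <- 1
    ch[nz] <- (ch[nz] - mu) / sd_
    out[c_, , , ] <- ch
  }
  out
}

#' Randomly crop an aligned image/label patch
#'
#' Image and label are cropped with identical offsets drawn uniformly;
#' volumes smaller than the patch are first padded symmetrically with the
#' background value.
#'
#' @param image `(C, D, H, W)` array.
#' @param label `(D, H, W)` array or `NULL`.
#' @param size Patch extent `(D, H, W)`.
#' @param seed Optional seed making the draw reproducible; `NULL` uses the
#'   current RNG stream.
#' @return List with `$image`, `$label`, `$offset` (0-based corner).
#' @export
random_crop_patch <- function(image, label = NULL, size, seed = NULL) {
  check_feature_map(image)
  size <- as.integer(rep(size, length.out = 3L))
  d <- dim(image)[2:4]
  pad_lo <- pmax(0L, (size - d + 1L) %/% 2L)
  pad_hi <- pmax(0L, size - d - pad_lo)
  if (any(pad_lo + pad_hi > 0L)) {
    nd <- d + pad_lo + pad_hi
    im2 <- array(0, c(dim(image)[1], nd))
    im2[, pad_lo[1] + seq_len(d[1]), pad_lo[2] + seq_len(d[2]),
        pad_lo[3] + seq_len(d[3])] <- image
    image <- im2
    if (!is.null(label)) {
      lb2 <- array(0L, nd)
      lb2[pad_lo[1] + seq_len(d[1]), pad_lo[2] + seq_len(d[2]),
          pad_lo[3] + seq_len(d[3])] <- label
      label <- lb2
    }
    d <- nd
  }
  offset <- with_seed(seed, {
    vapply(1:3, function(ax) sample.int(d[ax] - size[ax] + 1L, 1L) - 1L,
           integer(1))
  })
  img_p <- image[, offset[1] + seq_len(size[1]), offset[2] + seq_len(size[2]),
                 offset[3] + seq_len(size[3]), drop = FALSE]
  lab_p <- if (is.null(label)) NULL else
    label[offset[1] + seq_len(size[1]), offset[2] + seq_len(size[2]),
          offset[3] + seq_len(size[3])]
  list(image = img_p, label = lab_p, offset = offset)
}

#' Assign subjects to cross-validation folds
#'
#' Shuffles records once under `seed` and partitions them into `k`
#' near-equal validation folds (each fold's validation share is about
#' `1/k`, i.e. 20% for the five-fold protocol).
#'
#' @param manifest A manifest (from [read_manifest()] /
#'   [generate_manifest()]) or a character vector of identifiers.
#' @param k Number of folds (default 5).
#' @param seed Shuffle seed.
#' @return A data.frame with columns `id` and `fold` (1..k); records with
#'   `fold == i` form the validation set of fold `i`.
#' @export
make_cv_folds <- function(manifest, k = 5L, seed = 1L) {
  ids <- if (is.character(manifest)) manifest
  else vapply(manifest$records, function(r) r$id, character(1))
  if (anyDuplicated(ids)) stopf("record identifiers must be unique")
  n <- length(ids)
  if (k < 2L) stopf("k must be at least 2")
  if (k > n) stopf("cannot make %d folds from %d records", k, n)
  perm <- with_seed(seed, sample.int(n))
  fold <- integer(n)
  fold[perm] <- rep_len(seq_len(k), n)
  data.frame(id = ids, fold = fold, stringsAsFactors = FALSE)
}

## ---- manifests --------------------------------------------------------------

#' Write a dataset manifest
#'
#' @param records List of records (`$id`, `$image`, `$label`).
#' @param path Output JSON path.
#' @param name Task name.
#' @param regime `"brain4ch"` or `"abdomen1ch"`.
#' @param channels Channel count.
#' @param label_set Integer label values.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(records, path, name = "synthetic",
                           regime = "brain4ch", channels = 4L,
                           label_set = c(0L, 1L, 2L, 4L)) {
  obj <- list(name = name, regime = regime, channels = channels,
              label_set = label_set,
              training = lapply(records, function(r)
                list(id = r$id, image = r$image, label = r$label)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a dataset manifest
#'
#' Paths are resolved relative to the manifest's directory; all referenced
#' files must exist.
#'
#' @param path Manifest JSON path.
#' @return List with `$name`, `$regime`, `$channels`, `$label_set`,
#'   `$records`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stopf("manifest not found: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  base <- dirname(normalizePath(path))
  resolve <- function(pp) {
    pp <- unlist(pp)
    ifelse(grepl("^(/|[A-Za-z]:)", pp), pp, file.path(base, pp))
  }
  records <- lapply(obj$training, function(r)
    list(id = r$id, image = resolve(r$image),
         label = if (is.null(r$label)) NULL else resolve(r$label)))
  missing <- unlist(lapply(records, function(r)
    Filter(Negate(file.exists), c(r$image, r$label))))
  if (length(missing) > 0L)
    stopf("manifest references missing file(s): %s",
          paste(missing, collapse = ", "))
  ids <- vapply(records, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stopf("duplicate identifiers in manifest")
  list(name = obj$name, regime = obj$regime,
       channels = as.integer(obj$channels),
       label_set = as.integer(unlist(obj$label_set)), records = records)
}
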