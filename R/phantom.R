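# Seedable phantom generators emulating the two dataset regimes: nested
# tumor-like label structure inside a brain-like foreground on four MRI-like
# channels, and disjoint organ-like blobs on a single CT-like channel.
# The generators exist to exercise the pipeline end to end with separable
# class contrasts, not to model imaging physics.

# squared normalized distance to an ellipsoid (<= 1 means inside)
ellipsoid_dist2 <- function(d, center, radii) {
  gz <- (seq_len(d[1]) - center[1]) / radii[1]
  gy <- (seq_len(d[2]) - center[2]) / radii[2]
  gx <- (seq_len(d[3]) - center[3]) / radii[3]
  outer(outer(gz^2, gy^2, "+"), gx^2, "+")
}

# per-tissue channel means for the four MRI-like channels
# rows: brain tissue, necrotic core (1), edema (2), enhancing tumor (4)
BRAIN_CONTRAST <- matrix(c(
  0.50, 0.50, 0.40, 0.40,   # normal brain
  0.30, 0.25, 0.60, 0.50,   # label 1: necrotic / non-enhancing core
  0.45, 0.40, 0.75, 0.90,   # label 2: peritumoral edema
  0.60, 0.95, 0.50, 0.65),  # label 4: enhancing tumor
  nrow = 4, byrow = TRUE,
  dimnames = list(c("brain", "necrotic", "edema", "enhancing"),
                  c("T1", "T1Gd", "T2", "FLAIR")))

#' Generate a brain-tumor-like phantom
#'
#' A brain-shaped ellipsoid foreground containing three concentric
#' randomized ellipsoids: an edema shell (label 2) around a necrotic shell
#' (label 1) around an enhancing center (label 4), so the evaluated nested
#' regions are nonempty by construction.  Four channels receive distinct
#' per-tissue mean intensities plus additive Gaussian noise; the volume is
#' fully determined by `seed`.
#'
#' @param extent Spatial extent `(D, H, W)`, each at least 32.
#' @param noise_sd Additive Gaussian noise level (default 0.05).
#' @param contrast 4x4 tissue-by-channel intensity matrix.
#' @param tumor_radius_frac Outer tumor radius as a fraction of the
#'   smallest extent (default drawn in `[0.18, 0.24]`).
#' @param seed Integer seed.
#' @return List with `$image` (`4, D, H, W`), `$label` (`D, H, W` over
#'   `{0, 1, 2, 4}`), and `$spec` describing the geometry.
#' @export
generate_brain_phantom <- function(extent = c(64L, 64L, 64L),
                                   noise_sd = 0.05,
                                   contrast = BRAIN_CONTRAST,
                                   tumor_radius_frac = NULL, seed = 1L) {
  extent <- as.integer(rep(extent, length.out = 3L))
  if (any(extent < 32L)) stopf("phantom extent must be at least 32 per axis")
  with_seed(seed, {
    ctr <- extent / 2 + stats::runif(3, -0.03, 0.03) * extent
    brain_r <- extent * stats::runif(3, 0.38, 0.44)
    frac <- tumor_radius_frac %||% stats::runif(1, 0.18, 0.24)
    r_wt <- frac * min(extent)
    if (2 * r_wt > min(extent))
      stopf("tumor radius %.1f does not fit the volume", r_wt)
    # tumor center well inside the brain
    tc <- ctr + stats::runif(3, -0.12, 0.12) * extent
    brain <- ellipsoid_dist2(extent, ctr, brain_r) <= 1
    d_wt <- ellipsoid_dist2(extent, tc, rep(r_wt, 3))
    d_tc <- ellipsoid_dist2(extent, tc, rep(0.70 * r_wt, 3))
    d_et <- ellipsoid_dist2(extent, tc, rep(0.45 * r_wt, 3))
    lab <- array(0L, extent)
    lab[brain] <- 0L
    lab[d_wt <= 1] <- 2L
    lab[d_tc <= 1] <- 1L
    lab[d_et <= 1] <- 4L
    lab[!brain & d_wt > 1] <- 0L
    img <- array(0, c(4L, extent))
    tissue_row <- c("0" = NA, "1" = 2L, "2" = 3L, "4" = 4L)
    for (ch in 1:4) {
      plane <- array(0, extent)
      plane[brain] <- contrast[1, ch]
      for (lv in c(1L, 2L, 4L)) {
        row <- c("1" = 2L, "2" = 3L, "4" = 4L)[as.character(lv)]
        plane[lab == lv] <- contrast[row, ch]
      }
      if (noise_sd > 0) {
        fg <- plane != 0
        plane[fg] <- plane[fg] + stats::rnorm(sum(fg), 0, noise_sd)
      }
      img[ch, , , ] <- plane
    }
    list(image = img, label = lab,
         spec = list(regime = "brain4ch", extent = extent, seed = seed,
                     noise_sd = noise_sd, tumor_center = tc,
                     tumor_radius = r_wt))
  })
}

#' Generate a multi-organ abdominal-like phantom
#'
#' `n_organs` pairwise-disjoint ellipsoidal blobs with labels `1..n_organs`
#' inside a body-shaped foreground on a single channel; each organ gets a
#' distinct mean intensity plus Gaussian noise.  Placement uses bounded
#' rejection sampling and errors out if a blob cannot be placed.
#'
#' @param extent Spatial extent `(D, H, W)`, each at least 32.
#' @param n_organs Number of organ blobs (at most 13).
#' @param noise_sd Additive Gaussian noise level.
#' @param seed Integer seed.
#' @param max_tries Placement attempts per organ before giving up.
#' @return List with `$image` (`1, D, H, W`), `$label` (`D, H, W` over
#'   `{0..n_organs}`), `$spec`.
#' @export
generate_abdomen_phantom <- function(extent = c(64L, 64L, 64L),
                                     n_organs = 13L, noise_sd = 0.05,
                                     seed = 1L, max_tries = 200L) {
  extent <- as.integer(rep(extent, length.out = 3L))
  if (any(extent < 32L)) stopf("phantom extent must be at least 32 per axis")
  if (n_organs < 1L || n_organs > 13L)
    stopf("n_organs must be between 1 and 13, got %d", n_organs)
  with_seed(seed, {
    ctr <- extent / 2
    body_r <- extent * c(0.46, 0.42, 0.42)
    body <- ellipsoid_dist2(extent, ctr, body_r) <= 1
    lab <- array(0L, extent)
    organ_means <- 0.35 + 0.05 * sample.int(13L)[seq_len(n_organs)]
    for (o in seq_len(n_organs)) {
      placed <- FALSE
      for (try_ in seq_len(max_tries)) {
        radii <- stats::runif(3, 0.05, 0.11) * extent
        cen <- ctr + stats::runif(3, -0.28, 0.28) * extent
        inside <- ellipsoid_dist2(extent, cen, radii) <= 1
        if (!any(inside)) next
        if (!all(body[inside])) next          # keep organs inside the body
        if (any(lab[inside] != 0L)) next      # pairwise disjoint
        lab[inside] <- o
        placed <- TRUE
        break
      }
      if (!placed)
        stopf("could not place organ %d after %d attempts", o, max_tries)
    }
    plane <- array(0, extent)
    plane[body] <- 0.20                        # soft-tissue background
    for (o in seq_len(n_organs)) plane[lab == o] <- organ_means[o]
    if (noise_sd > 0) {
      fg <- plane != 0
      plane[fg] <- plane[fg] + stats::rnorm(sum(fg), 0, noise_sd)
    }
    img <- array(plane, c(1L, extent))
    list(image = img, label = lab,
         spec = list(regime = "abdomen1ch", extent = extent, seed = seed,
                     n_organs = n_organs, noise_sd = noise_sd))
  })
}

#' Generate a phantom dataset on disk with its manifest
#'
#' Writes `n_subjects` image/label NIfTI pairs (multi-channel images as a
#' single 4D file, channel-last) plus a JSON manifest consumable by
#' [read_manifest()].  Per-subject seeds are derived deterministically from
#' the master seed, so distinct subjects differ while the whole dataset is
#' reproducible.
#'
#' @param n_subjects Number of subjects.
#' @param out_dir Output directory (created if needed).
#' @param regime `"brain4ch"` or `"abdomen1ch"`.
#' @param extent Per-subject extent.
#' @param noise_sd Noise level.
#' @param n_organs Organ count for the abdominal regime.
#' @param seed Master seed.
#' @return The manifest (as returned by [read_manifest()]).
#' @export
generate_manifest <- function(n_subjects, out_dir,
                              regime = c("brain4ch", "abdomen1ch"),
                              extent = c(64L, 64L, 64L), noise_sd = 0.05,
                              n_organs = 13L, seed = 1L) {
  regime <- match.arg(regime)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sub_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                          n_subjects))
  records <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    id <- sprintf("%s_%03d", sub("[0-9]+ch$", "", regime), i)
    ph <- if (regime == "brain4ch")
      generate_brain_phantom(extent, noise_sd, seed = sub_seeds[i])
    else generate_abdomen_phantom(extent, n_organs, noise_sd,
                                  seed = sub_seeds[i])
    img_path <- file.path(out_dir, paste0(id, "_img.nii.gz"))
    lab_path <- file.path(out_dir, paste0(id, "_lab.nii.gz"))
    im <- ph$image
    arr <- if (dim(im)[1] == 1L) array(im[1, , , ], dim(im)[2:4])
    else aperm(im, c(2, 3, 4, 1))       # channel-last on disk
    RNifti::writeNifti(RNifti::asNifti(arr), img_path)
    RNifti::writeNifti(RNifti::asNifti(array(as.integer(ph$label),
                                             dim(ph$label)),
                                       datatype = "int16"), lab_path)
    records[[i]] <- list(id = id, image = basename(img_path),
                         label = basename(lab_path))
  }
  label_set <- if (regime == "brain4ch") c(0L, 1L, 2L, 4L)
  else 0:as.integer(n_organs)
  channels <- if (regime == "brain4ch") 4L else 1L
  mpath <- file.path(out_dir, "manifest.json")
  write_manifest(records, mpath, name = paste0("synthetic_", regime),
                 regime = regime, channels = channels, label_set = label_set)
  read_manifest(mpath)
}
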