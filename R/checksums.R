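# Architecture checksum harness: regression-tests built networks against
# reference trainable-parameter totals for the four published variants, and
# against the internal-consistency deltas those totals imply.

#' Reference parameter totals
#'
#' Published trainable-parameter counts for the four network variants:
#' the windowed-attention baseline and the pooling-mixer network, each with
#' and without squeeze-and-excitation, across six embedding widths in the
#' single-channel 14-class configuration and at `C = 48` in the
#' four-channel 3-region configuration.  These serve purely as regression
#' targets for [architecture_checksum()]; the package computes its own
#' totals by enumerating built parameter trees.
#'
#' @return A data.frame with columns `mixer`, `use_se`, `feature_size`,
#'   `in_channels`, `out_channels`, `reference`.
#' @export
reference_parameter_counts <- function() {
  ab <- expand.grid(feature_size = c(24L, 36L, 48L, 60L, 72L, 84L),
                    mixer = c("attention", "pooling"),
                    use_se = c(FALSE, TRUE), stringsAsFactors = FALSE)
  ab$in_channels <- 1L
  ab$out_channels <- 14L
  ref_ab <- c(
    # attention, no SE (sizes 24..84)
    15703304, 35072996, 62187296, 97046204, 139649720, 189997844,
    # pooling, no SE
    15407384, 34408796, 61007936, 95204804, 136999400, 186391724,
    # attention + SE
    15809336, 35310668, 62609024, 97704404, 140596808, 191286236,
    # pooling + SE
    15513416, 34646468, 61429664, 95863004, 137946488, 187680116)
  ab$reference <- ref_ab
  br <- data.frame(feature_size = 48L,
                   mixer = c("attention", "attention", "pooling", "pooling"),
                   use_se = c(FALSE, TRUE, FALSE, TRUE),
                   in_channels = 4L, out_channels = 3L,
                   reference = c(62191941, 62613669, 61012581, 61434309),
                   stringsAsFactors = FALSE)
  rbind(ab[, c("mixer", "use_se", "feature_size", "in_channels",
               "out_channels", "reference")], br)
}

#' Compute parameter totals over a configuration grid
#'
#' Builds each requested configuration at shape level and tallies its
#' trainable parameters.
#'
#' @param feature_sizes Integer vector of embedding widths.
#' @param mixers Character vector from `c("attention", "pooling")`.
#' @param use_se Logical vector of SE settings.
#' @param in_channels,out_channels Channel configuration.
#' @param head Output head type.
#' @return A data.frame with one row per configuration and a `total` column.
#' @export
count_grid <- function(feature_sizes = c(24L, 36L, 48L, 60L, 72L, 84L),
                       mixers = c("attention", "pooling"),
                       use_se = c(FALSE, TRUE),
                       in_channels = 1L, out_channels = 14L,
                       head = "softmax") {
  grid <- expand.grid(feature_size = feature_sizes, mixer = mixers,
                      use_se = use_se, stringsAsFactors = FALSE)
  grid$in_channels <- in_channels
  grid$out_channels <- out_channels
  grid$total <- vapply(seq_len(nrow(grid)), function(i) {
    cfg <- model_config(feature_size = grid$feature_size[i],
                        in_channels = in_channels,
                        out_channels = out_channels,
                        mixer = grid$mixer[i], use_se = grid$use_se[i],
                        head = head, roi = c(96L, 96L, 96L))
    count_parameters(build_network(cfg, init = "shapes"))$total
  }, numeric(1))
  grid
}

#' Checksum computed parameter totals against the reference table
#'
#' Matches each computed total to the reference row with the same
#' configuration and also verifies the internal-consistency deltas implied
#' by pairs of reference rows: the SE increment must be identical across
#' mixers at fixed width, the attention-minus-pooling increment identical
#' across channel configurations at fixed width, and the channel-
#' configuration increment identical across mixers.
#'
#' @param totals A data.frame with columns `mixer`, `use_se`,
#'   `feature_size`, `in_channels`, `out_channels`, `total` (as produced by
#'   [count_grid()]).  Configurations without a reference row are skipped
#'   with a warning.
#' @param reference Reference table (defaults to
#'   [reference_parameter_counts()]).
#' @return A list with `$table` (per-configuration expected/computed/pass),
#'   `$deltas` (delta-consistency checks), and `$pass`.
#' @export
architecture_checksum <- function(totals,
                                  reference = reference_parameter_counts()) {
  stopifnot(is.data.frame(totals), "total" %in% names(totals))
  key <- function(d) paste(d$mixer, d$use_se, d$feature_size,
                           d$in_channels, d$out_channels)
  ref_idx <- match(key(totals), key(reference))
  if (anyNA(ref_idx))
    warning(sprintf("%d configuration(s) have no reference total; skipped",
                    sum(is.na(ref_idx))))
  keep <- !is.na(ref_idx)
  tab <- data.frame(
    mixer = totals$mixer[keep], use_se = totals$use_se[keep],
    feature_size = totals$feature_size[keep],
    in_channels = totals$in_channels[keep],
    out_channels = totals$out_channels[keep],
    expected = reference$reference[ref_idx[keep]],
    computed = totals$total[keep])
  tab$pass <- tab$expected == tab$computed

  # delta consistency over the computed totals
  deltas <- list()
  g <- totals
  pick <- function(mix, se, C, inc = 1L, outc = 14L) {
    r <- g$total[g$mixer == mix & g$use_se == se & g$feature_size == C &
                   g$in_channels == inc & g$out_channels == outc]
    if (length(r) == 1L) r else NA_real_
  }
  for (C in unique(g$feature_size)) {
    se_d <- c(attention = pick("attention", TRUE, C) -
                pick("attention", FALSE, C),
              pooling = pick("pooling", TRUE, C) - pick("pooling", FALSE, C))
    se_d <- se_d[!is.na(se_d)]
    if (length(se_d) > 1L)
      deltas[[paste0("se_delta_C", C)]] <-
        list(values = se_d, pass = length(unique(se_d)) == 1L)
    mix_d <- c(cfg_1_14 = pick("attention", FALSE, C) -
                 pick("pooling", FALSE, C),
               cfg_4_3 = pick("attention", FALSE, C, 4L, 3L) -
                 pick("pooling", FALSE, C, 4L, 3L))
    mix_d <- mix_d[!is.na(mix_d)]
    if (length(mix_d) > 1L)
      deltas[[paste0("mixer_delta_C", C)]] <-
        list(values = mix_d, pass = length(unique(mix_d)) == 1L)
    ch_d <- c(attention = pick("attention", FALSE, C, 4L, 3L) -
                pick("attention", FALSE, C),
              pooling = pick("pooling", FALSE, C, 4L, 3L) -
                pick("pooling", FALSE, C))
    ch_d <- ch_d[!is.na(ch_d)]
    if (length(ch_d) > 1L)
      deltas[[paste0("channel_delta_C", C)]] <-
        list(values = ch_d, pass = length(unique(ch_d)) == 1L)
  }
  pass <- all(tab$pass) && all(vapply(deltas, `[[`, logical(1), "pass"))
  structure(list(table = tab, deltas = deltas, pass = pass),
            class = "architecture_checksum")
}

#' @export
print.architecture_checksum <- function(x, ...) {
  tab <- x$table
  tab$expected <- format(tab$expected, big.mark = ",")
  tab$computed <- format(tab$computed, big.mark = ",")
  print(tab, row.names = FALSE)
  for (nm in names(x$deltas)) {
    d <- x$deltas[[nm]]
    cat(sprintf("%s: %s [%s]\n", nm,
                paste(format(d$values, big.mark = ","), collapse = " / "),
                if (d$pass) "consistent" else "MISMATCH"))
  }
  cat(if (x$pass) "all checksums pass\n" else "CHECKSUM FAILURE\n")
  invisible(x)
}
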