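# Synthetic phantom generators for the two dataset regimes.

test_that("brain phantoms have nested tumor regions on four channels", {
  ph <- generate_brain_phantom(extent = c(48, 48, 48), seed = 11)
  expect_identical(dim(ph$image), c(4L, 48L, 48L, 48L))
  expect_true(all(ph$label %in% c(0L, 1L, 2L, 4L)))
  m <- brats_region_masks(ph$label)
  expect_gt(sum(m$ET), 0)
  expect_lt(sum(m$ET), sum(m$TC))
  expect_lt(sum(m$TC), sum(m$WT))
  # determinism and seed sensitivity
  ph2 <- generate_brain_phantom(extent = c(48, 48, 48), seed = 11)
  expect_identical(ph$image, ph2$image)
  expect_identical(ph$label, ph2$label)
  ph3 <- generate_brain_phantom(extent = c(48, 48, 48), seed = 12)
  expect_false(identical(ph$label, ph3$label))
})

test_that("noise-free brain phantoms are exactly constant per tissue class", {
  ph <- generate_brain_phantom(extent = c(32, 32, 32), noise_sd = 0,
                               seed = 2)
  for (ch in 1:4) {
    plane <- ph$image[ch, , , ]
    for (lv in c(1L, 2L, 4L)) {
      vals <- unique(plane[ph$label == lv])
      expect_lte(length(vals), 1L)
    }
  }
})

test_that("abdominal phantoms place disjoint organs with distinct labels", {
  ph <- generate_abdomen_phantom(extent = c(48, 48, 48), n_organs = 13L,
                                 seed = 21)
  expect_identical(dim(ph$image), c(1L, 48L, 48L, 48L))
  hist <- table(ph$label)
  expect_identical(sort(as.integer(names(hist))), 0:13)  # 14 populated bins
  expect_true(all(hist > 0))
  ph2 <- generate_abdomen_phantom(extent = c(48, 48, 48), n_organs = 13L,
                                  seed = 21)
  expect_identical(ph$image, ph2$image)
  expect_error(generate_abdomen_phantom(n_organs = 14L), "between")
})

test_that("generated datasets load, differ per subject, and feed the fold split", {
  td <- withr::local_tempdir()
  man <- generate_manifest(10L, td, regime = "brain4ch",
                           extent = c(32L, 32L, 32L), seed = 5L)
  expect_identical(length(man$records), 10L)
  ids <- vapply(man$records, `[[`, character(1), "id")
  expect_identical(anyDuplicated(ids), 0L)
  v1 <- read_volume(man$records[[1]], label_set = man$label_set)
  v2 <- read_volume(man$records[[2]], label_set = man$label_set)
  expect_identical(dim(v1$image), c(4L, 32L, 32L, 32L))
  expect_false(identical(v1$image, v2$image))   # derived seeds differ
  folds <- make_cv_folds(man, k = 5L, seed = 1L)
  expect_true(all(table(folds$fold) == 2))
})
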