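# Soft Dice loss, Dice score, region construction, CV aggregation.

test_that("soft Dice loss reproduces hand-computed values", {
  expect_equal(soft_dice_loss(c(1, 1, 0, 0), c(1, 0, 1, 0), smooth = 0), 0.5)
  g <- c(1, 0, 1, 1, 0)
  expect_equal(soft_dice_loss(g, g, smooth = 0), 0)           # p = g
  expect_equal(soft_dice_loss(c(1, 1, 0, 0), c(0, 0, 1, 1), smooth = 0), 1)
  expect_error(soft_dice_loss(c(1, 0), c(1, 0, 1)), "shapes differ")
  expect_error(soft_dice_loss(c(1, 0), c(2, 0)), "binary")
})

test_that("the loss is bounded, permutation-invariant, and complements the score", {
  set.seed(40)
  for (rep in 1:20) {
    n <- 50
    p <- runif(n)
    g <- rbinom(n, 1, 0.5)
    l <- soft_dice_loss(p, g)
    expect_gte(l, 0); expect_lte(l, 1)
    perm <- sample(n)
    expect_equal(soft_dice_loss(p[perm], g[perm]), l)
    pb <- rbinom(n, 1, 0.5)
    if (sum(pb) + sum(g) > 0)
      expect_equal(1 - dice_score(pb, g), soft_dice_loss(pb, g, smooth = 0),
                   tolerance = 1e-12)
  }
})

test_that("Dice score counts overlap and honors the empty convention", {
  g <- c(rep(1, 5), rep(0, 10))
  expect_equal(dice_score(g, g), 1)
  p <- c(rep(1, 10), rep(0, 5))     # covers g plus an equal-size extra
  expect_equal(dice_score(p, g), 2 / 3)
  expect_equal(dice_score(numeric(4), numeric(4)), 1)
  expect_equal(dice_score(numeric(4), numeric(4), empty_value = 0), 0)
})

test_that("region masks implement the nested label unions", {
  m <- brats_region_masks(c(0, 1, 2, 4))
  expect_equal(as.vector(m$WT), c(0, 1, 1, 1))
  expect_equal(as.vector(m$TC), c(0, 1, 0, 1))
  expect_equal(as.vector(m$ET), c(0, 0, 0, 1))
  empty <- brats_region_masks(array(0L, c(2, 2, 2)))
  expect_true(all(unlist(empty) == 0))
  expect_error(brats_region_masks(c(0, 3)), "3")
  set.seed(41)
  lab <- array(sample(c(0L, 1L, 2L, 4L), 4^3, TRUE), c(4, 4, 4))
  m <- brats_region_masks(lab)
  expect_lte(sum(m$ET), sum(m$TC))
  expect_lte(sum(m$TC), sum(m$WT))
  expect_true(all(m$ET <= m$TC) && all(m$TC <= m$WT))  # voxel-wise nesting
  # round trip through the label reconstruction
  expect_equal(region_masks_to_labels(m), lab)
})

test_that("cross-validation aggregation averages rows, columns and grand mean", {
  m <- matrix(0.7, 5, 3)
  agg <- aggregate_cv_results(m)
  expect_equal(unname(agg$class_means), rep(0.7, 3))
  expect_equal(unname(agg$fold_means), rep(0.7, 5))
  expect_equal(agg$grand, 0.7)
  # relabeling folds only permutes the per-fold means
  m2 <- matrix(runif(15), 5, 3)
  perm <- c(3, 1, 5, 2, 4)
  a1 <- aggregate_cv_results(m2)
  a2 <- aggregate_cv_results(m2[perm, ])
  expect_equal(sort(unname(a1$fold_means)), sort(unname(a2$fold_means)))
  expect_equal(a1$class_means, a2$class_means)
  expect_equal(a1$grand, a2$grand)
  m3 <- m2; m3[2, 3] <- NA
  expect_error(aggregate_cv_results(m3), "missing")
})
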