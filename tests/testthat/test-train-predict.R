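# Training loop, checkpoints, sliding-window inference, evaluation.

test_that("short training runs are bounded, finite, and seed-reproducible", {
  ph <- generate_brain_phantom(extent = c(32, 32, 32),
                               tumor_radius_frac = 0.3, seed = 5)
  net <- build_network(tiny_config(), seed = 2L)
  fit <- train_model(net, list(list(image = ph$image, label = ph$label)),
                     steps = 6L, lr = 1e-3, patch_size = 32L,
                     normalize = "nonzero_zscore", seed = 7L)
  expect_length(fit$losses, 6L)
  expect_true(all(fit$losses >= 0 & fit$losses <= 1))   # loss range
  fit2 <- train_model(net, list(list(image = ph$image, label = ph$label)),
                      steps = 6L, lr = 1e-3, patch_size = 32L,
                      normalize = "nonzero_zscore", seed = 7L)
  expect_identical(fit$losses, fit2$losses)             # deterministic mode
})

test_that("checkpoints round-trip weights and configuration", {
  td <- withr::local_tempdir()
  net <- build_network(tiny_config(), seed = 4L)
  cp <- file.path(td, "ck.rds")
  save_checkpoint(net, cp, extra = list(note = "test"))
  back <- load_checkpoint(cp)
  expect_identical(back$config$feature_size, net$config$feature_size)
  expect_identical(back$params, net$params)
  set.seed(1)
  x <- rand_map(4, 32, 32, 32)
  expect_identical(forward_pass(back, x), forward_pass(net, x))
})

test_that("single-tile sliding window equals the direct forward decision", {
  set.seed(60)
  net <- build_network(tiny_config(), seed = 8L)
  x <- rand_map(4, 32, 32, 32)
  pr <- predict_volume(net, x, roi = c(32, 32, 32))
  direct <- forward_pass(net, x)
  expect_equal(pr$logits, direct, tolerance = 1e-12)
  expect_identical(pr$labels, decide_labels(direct, "sigmoid"))
  expect_true(all(pr$labels %in% c(0L, 1L, 2L, 4L)))
})

test_that("tiled prediction covers larger volumes and respects the label set", {
  set.seed(61)
  cfg <- tiny_config(in_channels = 1L, out_channels = 5L, head = "softmax")
  net <- build_network(cfg, seed = 9L)
  x <- rand_map(1, 48, 32, 32)
  pr <- predict_volume(net, x, overlap = 0.5, roi = c(32, 32, 32))
  expect_identical(dim(pr$labels), c(48L, 32L, 32L))
  expect_true(all(pr$labels %in% 0:4))
  # volumes smaller than the window are padded and cropped back
  xs <- rand_map(1, 20, 20, 20)
  prs <- predict_volume(net, xs, roi = c(32, 32, 32))
  expect_identical(dim(prs$labels), c(20L, 20L, 20L))
})

test_that("perfect predictions evaluate to Dice 1; mismatches are caught", {
  set.seed(62)
  lab <- array(sample(c(0L, 1L, 2L, 4L), 4^3, TRUE), c(4, 4, 4))
  tab <- evaluate_predictions(list(a = lab), list(a = lab), task = "brain")
  expect_equal(unname(unlist(tab[1, c("TC", "WT", "ET")])), rep(1, 3))
  lab2 <- array(0L, c(4, 4, 4))
  tab2 <- evaluate_predictions(list(a = lab2), list(a = lab), task = "brain")
  expect_equal(tab2$WT[1], 0)                    # empty vs nonempty
  expect_error(evaluate_predictions(list(a = lab), list(b = lab), "brain"),
               "unmatched")
  # abdominal: one-vs-rest per organ, background excluded
  ab <- array(sample(0:3, 5^3, TRUE), c(5, 5, 5))
  tab3 <- evaluate_predictions(list(s = ab), list(s = ab), task = "abdomen",
                               n_classes = 3L)
  expect_equal(unname(unlist(tab3[1, paste0("organ", 1:3)])), rep(1, 3))
})

test_that("the parameter-count CLI passes its own checksum audit", {
  status <- cmd_count_params(c("--grid", "abdomen", "--sizes", "24,48",
                               "--check"))
  expect_identical(status, 0L)
})
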