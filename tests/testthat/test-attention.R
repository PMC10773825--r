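# The windowed self-attention baseline mixer.

test_that("zero query/key logits give uniform attention = window mean", {
  set.seed(3)
  dim_ <- 4L; heads <- 1L; window <- 2L
  prm <- init_window_attention(dim_, heads, window, init = "zero")
  # value projection = identity, output projection = identity
  prm$qkv_w[2L * dim_ + seq_len(dim_), ] <- diag(dim_)
  prm$proj_w <- diag(dim_)
  x <- rand_map(dim_, 2, 2, 2)
  res <- window_attention_mixer(x, prm, heads, window,
                                return_attention = TRUE)
  # one 2x2x2 window covering the whole grid: every token -> global mean
  expect_equal(dim(res$attention)[1:2], c(8L, 8L))
  expect_true(all(abs(res$attention - 1 / 8) < 1e-12))
  m <- rowMeans(matrix(x, dim_))
  for (i in 1:2) for (j in 1:2) for (l in 1:2)
    expect_equal(res$y[, i, j, l], m, tolerance = 1e-12)
})

test_that("attention weights of every query sum to one over its window", {
  set.seed(4)
  prm <- init_window_attention(6L, 2L, 3L)
  x <- rand_map(6, 5, 4, 7)
  for (shifted in c(FALSE, TRUE)) {
    res <- window_attention_mixer(x, prm, 2L, 3L, shifted = shifted,
                                  return_attention = TRUE)
    sums <- apply(res$attention, c(1, 3, 4), sum)
    expect_true(all(abs(sums - 1) < 1e-9))
    expect_identical(dim(res$y), dim(x))
    expect_true(all(is.finite(res$y)))
  }
})

test_that("parameter tally matches the closed-form attention count", {
  prm <- init_window_attention(24L, 3L, 7L)
  total <- sum(vapply(prm, length, numeric(1)))
  expect_identical(total, 3 * 24^2 + 3 * 24 + 24^2 + 24 + (2 * 7 - 1)^3 * 3)
})

test_that("head divisibility is enforced", {
  expect_error(init_window_attention(10L, 3L), "divisible")
})

test_that("windows larger than the extent are clipped, shift disabled", {
  set.seed(5)
  prm <- init_window_attention(4L, 2L, 7L)
  x <- rand_map(4, 2, 3, 2)  # all extents below the configured window
  for (shifted in c(FALSE, TRUE)) {
    y <- window_attention_mixer(x, prm, 2L, 7L, shifted = shifted)
    expect_identical(dim(y), dim(x))
    expect_true(all(is.finite(y)))
  }
})
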