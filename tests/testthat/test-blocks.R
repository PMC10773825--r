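# Transformer block composition, patch embedding and patch merging.

test_that("blocks preserve shape and produce finite values", {
  set.seed(8)
  x <- rand_map(8, 4, 4, 4)
  for (mixer in c("pooling", "attention")) {
    blk <- init_mixer_block(8L, mixer, heads = 2L, window = 3L)
    y <- mixer_block(x, blk)
    expect_identical(dim(y), dim(x))
    expect_true(all(is.finite(y)))
  }
  expect_error(mixer_block(rand_map(4, 4, 4, 4), blk), "channels")
})

test_that("pure pooling block = two norms plus the feed-forward; attention adds more", {
  for (d in c(8L, 16L)) {
    pool_blk <- init_mixer_block(d, "pooling", heads = 2L)
    n_pool <- sum(vapply(pool_blk$params, length, numeric(1)))
    expect_equal(n_pool, 2 * (2 * d) + (4 * d * d + 4 * d) +
                       (4 * d * d + d))
    attn_blk <- init_mixer_block(d, "attention", heads = 2L)
    n_attn <- sum(vapply(rapply(attn_blk$params, length, how = "unlist"),
                         sum, numeric(1)))
    expect_gt(n_attn, n_pool)
  }
})

test_that("a zero feed-forward pooling block with identity subtraction is a no-op on constants", {
  blk <- init_mixer_block(6L, "pooling", subtract_identity = TRUE,
                          init = "zero")
  x <- array(3, c(6, 4, 4, 4))
  # constant field: pool(x) - x = 0 in the mixer branch, zero mlp weights
  # leave the second branch at its bias (zero), so the block is an identity
  expect_equal(mixer_block(x, blk), x, tolerance = 1e-9)
})

test_that("patch embedding halves extents and maps to the embedding width", {
  set.seed(9)
  w <- init_patch_embed(4L, 12L)
  x <- rand_map(4, 8, 6, 10)
  y <- patch_embed(x, w)
  expect_identical(dim(y), c(12L, 4L, 3L, 5L))
  expect_error(patch_embed(rand_map(4, 7, 6, 10), w), "even")
  # weight-tensor arithmetic: 4 vs 1 input channels at C = 48
  n4 <- sum(vapply(init_patch_embed(4L, 48L), length, numeric(1)))
  n1 <- sum(vapply(init_patch_embed(1L, 48L), length, numeric(1)))
  expect_equal(n4 - n1, 3 * 48 * 8)
})

test_that("patch merging halves extents, doubles channels, composes to H/16", {
  set.seed(10)
  x <- rand_map(6, 16, 16, 16)
  w1 <- init_patch_merge(6L)
  y1 <- patch_merge(x, w1)
  expect_identical(dim(y1), c(12L, 8L, 8L, 8L))
  y2 <- patch_merge(y1, init_patch_merge(12L))
  y3 <- patch_merge(y2, init_patch_merge(24L))
  expect_identical(dim(y3), c(48L, 2L, 2L, 2L))  # 8C at (H/2)/8 = H/16
})

test_that("merging a spatially constant field stays spatially constant", {
  set.seed(11)
  w <- init_patch_merge(5L)
  x <- array(rep(rnorm(5), 4^3), c(5, 4, 4, 4))  # constant over space
  y <- patch_merge(x, w)
  for (c_ in seq_len(dim(y)[1]))
    expect_lt(stats::sd(y[c_, , , ]), 1e-10)
})
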