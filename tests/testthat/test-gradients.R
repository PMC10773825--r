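# Hand-derived backward passes against central finite differences.  Each
# layer's adjoint is checked on a tiny random instance with a random probe.

expect_grad <- function(analytic, numeric_, tol = 1e-5) {
  expect_lt(abs(analytic - numeric_), tol * max(1, abs(numeric_)))
}

test_that("convolution adjoints (3x3x3, pointwise, strided, transposed)", {
  set.seed(20)
  x <- rand_map(3, 4, 5, 4)
  g <- rand_map(4, 4, 5, 4)
  w <- array(rnorm(4 * 3 * 27, sd = 0.2), c(4, 3, 3, 3, 3))
  fwd <- pu$conv3d_fwd(x, w, return_patches = TRUE)
  bwd <- pu$conv3d_bwd(fwd$X, w, g)
  for (i in sample(length(x), 3))
    expect_grad(bwd$gx[i],
                num_deriv(function(z) sum(pu$conv3d_fwd(z, w) * g), x, i))
  for (i in sample(length(w), 3))
    expect_grad(bwd$gw[i],
                num_deriv(function(z) sum(pu$conv3d_fwd(x, z) * g), w, i))

  w1 <- matrix(rnorm(4 * 3), 4, 3)
  b1 <- pu$conv1_bwd(x, w1, g)
  for (i in sample(length(w1), 2))
    expect_grad(b1$gw[i],
                num_deriv(function(z) sum(pu$conv1_fwd(x, z) * g), w1, i))

  wd <- matrix(rnorm(5 * 24, sd = 0.2), 5, 24)   # down conv, 3 channels in
  bd <- numeric(5)
  gd <- rand_map(5, 2, 2, 2)
  dn <- pu$down_conv_fwd(x[, 1:4, 1:4, 1:4, drop = FALSE], wd, bd)
  db <- pu$down_conv_bwd(dn$s, wd, gd)
  xs <- x[, 1:4, 1:4, 1:4, drop = FALSE]
  for (i in sample(length(xs), 3))
    expect_grad(db$gx[i],
                num_deriv(function(z) sum(pu$down_conv_fwd(z, wd, bd)$y * gd),
                          xs, i))

  wu <- matrix(rnorm(8 * 2 * 3, sd = 0.2), 16, 3)  # transposed conv
  gu <- rand_map(2, 8, 10, 8)
  ub <- pu$up_conv_bwd(x, wu, gu)
  for (i in sample(length(wu), 3))
    expect_grad(ub$gw[i],
                num_deriv(function(z) sum(pu$up_conv_fwd(x, z) * gu), wu, i))
  for (i in sample(length(x), 2))
    expect_grad(ub$gx[i],
                num_deriv(function(z) sum(pu$up_conv_fwd(z, wu) * gu), x, i))
})

test_that("normalization adjoints (layer norm with/without affine, instance norm)", {
  set.seed(21)
  x <- rand_map(5, 3, 2, 4)
  g <- rand_map(5, 3, 2, 4)
  w <- rnorm(5); b <- rnorm(5)
  fa <- pu$layer_norm_fwd(x, w, b)
  ba <- pu$layer_norm_bwd(fa, w, g)
  for (i in sample(length(x), 3))
    expect_grad(ba$gx[i],
                num_deriv(function(z) sum(pu$layer_norm_fwd(z, w, b)$y * g),
                          x, i))
  for (i in sample(5, 2))
    expect_grad(ba$gw[i],
                num_deriv(function(z) sum(pu$layer_norm_fwd(x, z, b)$y * g),
                          w, i))
  fn <- pu$layer_norm_fwd(x)
  bn <- pu$layer_norm_bwd(fn, NULL, g)
  for (i in sample(length(x), 2))
    expect_grad(bn$gx[i],
                num_deriv(function(z) sum(pu$layer_norm_fwd(z)$y * g), x, i))
  fi <- pu$instance_norm_fwd(x)
  gi <- pu$instance_norm_bwd(fi, g)
  for (i in sample(length(x), 3))
    expect_grad(gi[i],
                num_deriv(function(z) sum(pu$instance_norm_fwd(z)$y * g),
                          x, i))
})

test_that("pooling backward is the exact adjoint of the forward", {
  set.seed(22)
  x <- rand_map(2, 4, 5, 3)
  g <- rand_map(2, 4, 5, 3)
  ga <- pu$avgpool3d_bwd(g, 3L)
  for (i in sample(length(x), 4))
    expect_grad(ga[i],
                num_deriv(function(z) sum(pu$avgpool3d_fwd(z, 3L) * g), x, i))
})

test_that("transformer block backward matches finite differences (both mixers)", {
  set.seed(23)
  for (mixer in c("pooling", "attention")) {
    blk <- init_mixer_block(6L, mixer, heads = 2L, window = 3L,
                            pool_proj = (mixer == "pooling"))
    x <- rand_map(6, 4, 3, 5, sd = 0.5)
    g <- rand_map(6, 4, 3, 5)
    fw <- pu$block_fwd(x, blk$params, blk$config)
    bw <- pu$block_bwd(blk$params, blk$config, fw$cache, g)
    for (i in sample(length(x), 3))
      expect_grad(bw$gx[i],
                  num_deriv(function(z)
                    sum(pu$block_fwd(z, blk$params, blk$config)$y * g), x, i))
    probe <- function(leaf_name) {
      p0 <- blk$params[[leaf_name]]
      i <- sample(length(p0), 1)
      fnum <- num_deriv(function(z) {
        p2 <- blk$params; p2[[leaf_name]] <- z
        sum(pu$block_fwd(x, p2, blk$config)$y * g)
      }, p0, i)
      expect_grad(bw$gparams[[leaf_name]][i], fnum)
    }
    probe("mlp_w1"); probe("norm2_w"); probe("norm1_b")
    if (mixer == "pooling") probe("proj_w")
  }
})

test_that("patch merge and SE backward match finite differences", {
  set.seed(24)
  w <- init_patch_merge(3L)
  x <- rand_map(3, 4, 4, 4)
  g <- rand_map(6, 2, 2, 2)
  fw <- pu$merge_fwd(x, w)
  bw <- pu$merge_bwd(w, fw$cache, g)
  for (i in sample(length(x), 3))
    expect_grad(bw$gx[i],
                num_deriv(function(z) sum(pu$merge_fwd(z, w)$y * g), x, i))
  for (i in sample(length(w$red_w), 2))
    expect_grad(bw$gparams$red_w[i],
                num_deriv(function(z) {
                  w2 <- w; w2$red_w <- z
                  sum(pu$merge_fwd(x, w2)$y * g)
                }, w$red_w, i))

  sw <- init_se(4L, 2L)
  xs <- rand_map(4, 3, 3, 3)
  gs <- rand_map(4, 3, 3, 3)
  sf <- pu$se_fwd(xs, sw)
  sb <- pu$se_bwd(xs, sw, sf, gs)
  for (i in sample(length(xs), 3))
    expect_grad(sb$gx[i],
                num_deriv(function(z) sum(pu$se_fwd(z, sw)$y * gs), xs, i))
  for (i in sample(length(sw$w1), 2))
    expect_grad(sb$gparams$w1[i],
                num_deriv(function(z) {
                  w2 <- sw; w2$w1 <- z
                  sum(pu$se_fwd(xs, w2)$y * gs)
                }, sw$w1, i))
})

test_that("segmentation loss gradients are exact for both heads", {
  set.seed(25)
  for (head in c("sigmoid", "softmax")) {
    k <- if (head == "sigmoid") 3L else 4L
    logits <- rand_map(k, 3, 3, 3)
    tgt <- array(rbinom(k * 27, 1, 0.4), c(k, 3, 3, 3))
    if (head == "softmax") {   # one-hot targets
      lab <- array(sample(0:(k - 1), 27, TRUE), c(3, 3, 3))
      tgt <- pu$labels_to_onehot(lab, 0:(k - 1))
    }
    sl <- pu$segmentation_loss(logits, tgt, head)
    for (i in sample(length(logits), 4))
      expect_grad(sl$glogits[i],
                  num_deriv(function(z)
                    pu$segmentation_loss(z, tgt, head,
                                         with_grad = FALSE)$loss,
                    logits, i))
  }
})
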