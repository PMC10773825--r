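# Network assembly, determinism, parameter accounting, forward contracts.

test_that("builds are deterministic and counts ignore roi and seed", {
  cfg <- tiny_config()
  n1 <- build_network(cfg, seed = 5L)
  n2 <- build_network(cfg, seed = 5L)
  expect_identical(n1$params, n2$params)
  n3 <- build_network(cfg, seed = 6L)
  expect_false(identical(n1$params$head$w, n3$params$head$w))
  expect_identical(count_parameters(n1)$total, count_parameters(n3)$total)
  cfg2 <- tiny_config(roi = c(64L, 32L, 32L))
  expect_identical(count_parameters(build_network(cfg2, seed = 1L))$total,
                   count_parameters(n1)$total)
})

test_that("shape-level and materialized builds tally identically", {
  cfg <- model_config(feature_size = 24L, in_channels = 1L,
                      out_channels = 14L, mixer = "pooling")
  a <- count_parameters(build_network(cfg, init = "shapes"))
  b <- count_parameters(build_network(cfg, seed = 1L))
  expect_identical(a$total, b$total)
  expect_identical(a$components, b$components)
  expect_identical(a$total, sum(a$components$parameters))
})

test_that("totals strictly increase with the embedding width for every variant", {
  for (mixer in c("attention", "pooling")) for (se in c(FALSE, TRUE)) {
    tots <- count_grid(c(24L, 36L, 48L, 60L, 72L, 84L), mixer, se)$total
    expect_true(all(diff(tots) > 0))
  }
})

test_that("forward pass maps input extents to per-class logits", {
  set.seed(30)
  net <- build_network(tiny_config(), seed = 1L)
  x <- rand_map(4, 32, 32, 32)
  y <- forward_pass(net, x)
  expect_identical(dim(y), c(3L, 32L, 32L, 32L))
  expect_true(all(is.finite(y)))
  expect_error(forward_pass(net, rand_map(2, 32, 32, 32)), "channels")
  expect_error(forward_pass(net, rand_map(4, 33, 32, 32)), "divisible")
  expect_error(model_config(roi = c(48L, 48L, 48L)), "divisible by 32")
  # shape-level networks cannot run
  sn <- build_network(tiny_config(), init = "shapes")
  expect_error(forward_pass(sn, x), "shape level")
})

test_that("softmax-head config produces 14-channel logits", {
  set.seed(31)
  cfg <- tiny_config(in_channels = 1L, out_channels = 14L, head = "softmax")
  net <- build_network(cfg, seed = 2L)
  y <- forward_pass(net, rand_map(1, 32, 32, 32))
  expect_identical(dim(y), c(14L, 32L, 32L, 32L))
})

test_that("gradients reach essentially every parameter tensor", {
  set.seed(32)
  # a (64, 32, 32) region keeps the bottleneck above one voxel so the
  # deepest stage stays on the gradient path
  roi <- c(64L, 32L, 32L)
  for (mixer in c("pooling", "attention")) {
    cfg <- tiny_config(mixer = mixer, roi = roi)
    net <- build_network(cfg, seed = 3L)
    x <- rand_map(4, 64, 32, 32)
    fw <- pu$net_fwd(net, x, keep = TRUE)
    g <- array(1 / length(fw$logits), dim(fw$logits))  # mean of the output
    grads <- pu$net_bwd(net, fw$cache, g)
    leaves <- pu$tree_leaves(grads)
    nonzero <- vapply(leaves, function(l) any(l != 0), logical(1))
    if (mixer == "pooling") {
      # the retained position-bias tables are vestigial by design
      vest <- grepl("\\.rpb$", names(leaves))
      expect_true(all(nonzero[!vest]))
      expect_gte(mean(nonzero | vest), 0.99)
    } else {
      expect_gte(mean(nonzero), 0.99)
      expect_true(all(nonzero[grepl("qkv_w", names(leaves))]))
    }
  }
})

test_that("mixer swap and SE toggle change only the intended components", {
  base <- count_parameters(build_network(tiny_config(), init = "shapes"))
  attn <- count_parameters(build_network(tiny_config(mixer = "attention"),
                                         init = "shapes"))
  se <- count_parameters(build_network(tiny_config(use_se = TRUE),
                                       init = "shapes"))
  b <- base$components; a <- attn$components; s <- se$components
  changed_attn <- b$component[b$parameters != a$parameters]
  expect_true(all(grepl("^stage", changed_attn)))
  changed_se <- b$component[b$parameters != s$parameters]
  expect_identical(changed_se, "se")
})
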