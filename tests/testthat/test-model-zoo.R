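test_that("the vanilla count matches the closed-form layer arithmetic", {
  net <- unet("vanilla", unet_config())
  expect_equal(count_parameters(net), vanilla_param_oracle())
  # and the small-backbone variant of the same arithmetic
  small <- unet("vanilla", unet_config(input_size = 32, depth = 2,
                                       base_filters = 8))
  expect_equal(count_parameters(small),
                   vanilla_param_oracle(base = 8, depth = 2))
})

test_that("a degenerate one-conv backbone has a hand-computable count", {
  cfg <- unet_config(input_size = 2, depth = 1, base_filters = 1,
                     convs_per_block = 1)
  net <- unet("vanilla", cfg)
  # encoder: 3x3 conv 3->1 (28) + bn (2); bottleneck: 3x3 1->2 (20) + bn (4)
  # up: 2x2 convt 2->1 (9) + bn (2); decoder: 3x3 conv 2->1 (19) + bn (2)
  # head: 1x1 conv 1->2 (4)
  expect_identical(count_parameters(net), 28L + 2L + 20L + 4L + 9L + 2L +
                     19L + 2L + 4L)
})

test_that("a single biased 1x1 convolution 3->2 holds 8 parameters", {
  gb <- histoseg:::new_graph(3L)
  histoseg:::g_conv(gb, 1L, 2L, k = 1L)
  expect_equal(sum(lengths(gb$params)), 8)
})

test_that("doubling base filters roughly quadruples the parameter count", {
  n8 <- count_parameters(unet("vanilla", unet_config(input_size = 32,
                                                     depth = 2,
                                                     base_filters = 8)))
  n16 <- count_parameters(unet("vanilla", unet_config(input_size = 32,
                                                      depth = 2,
                                                      base_filters = 16)))
  expect_gt(n16 / n8, 3.5)
  expect_lt(n16 / n8, 4.1)
})

test_that("unknown variants and truncating input sizes are rejected", {
  expect_error(unet("resnet"), "vanilla, attention, residual")
  expect_error(unet_config(input_size = 100, depth = 3), "divisible")
  expect_error(unet_config(input_size = 250), "divisible")
})

test_that("every variant's forward pass is a per-pixel distribution", {
  cfg <- unet_config(input_size = 16, depth = 2, base_filters = 4,
                     convs_per_block = 2)
  set.seed(30)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  for (v in unet_variants()) {
    net <- unet(v, cfg, seed = 2)
    pr <- predict_batch(net, x, type = "prob")
    expect_equal(dim(pr), c(16L, 16L, 2L))
    expect_equal(pr[, , 1] + pr[, , 2], matrix(1, 16, 16), tolerance = 1e-5)
    expect_true(all(pr >= 0))
    mask <- predict_batch(net, x, type = "mask")
    expect_identical(mask, (pr[, , 2] >= 0.5) * 1L)
  }
})

test_that("prediction rejects patches that do not fit the input shape", {
  net <- unet("vanilla", unet_config(input_size = 16, depth = 2,
                                     base_filters = 4))
  expect_error(predict_batch(net, array(0.5, c(32, 32, 3))),
               "does not match")
})

test_that("a flip-symmetrized network commutes with image flips", {
  cfg <- unet_config(input_size = 16, depth = 2, base_filters = 4,
                     convs_per_block = 2)
  net <- unet("vanilla", cfg, seed = 5)
  # symmetrize every spatial kernel under both axis flips; the remaining
  # operators (bn, relu, pool on aligned windows, softmax) are already
  # flip-equivariant, so prediction must commute with flips exactly
  for (nm in names(net$params)) {
    p <- net$params[[nm]]
    if (length(dim(p)) == 4L) {
      k <- dim(p)[1L]
      net$params[[nm]] <- (p + p[k:1, , , , drop = FALSE] +
                             p[, k:1, , , drop = FALSE] +
                             p[k:1, k:1, , , drop = FALSE]) / 4
    }
  }
  set.seed(31)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  flip_h <- function(a) a[, dim(a)[2]:1, , drop = FALSE]
  flip_v <- function(a) a[dim(a)[1]:1, , , drop = FALSE]
  p1 <- predict_batch(net, flip_h(x), type = "prob")
  p2 <- flip_h(predict_batch(net, x, type = "prob"))
  expect_equal(p1, p2, tolerance = 1e-10)
  p3 <- predict_batch(net, flip_v(x), type = "prob")
  p4 <- flip_v(predict_batch(net, x, type = "prob"))
  expect_equal(p3, p4, tolerance = 1e-10)
})

test_that("network builds are reproducible for a given seed", {
  cfg <- unet_config(input_size = 16, depth = 2, base_filters = 4)
  a <- unet("attention", cfg, seed = 9)
  b <- unet("attention", cfg, seed = 9)
  expect_identical(a$params, b$params)
  c <- unet("attention", cfg, seed = 10)
  expect_false(identical(a$params, c$params))
})
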