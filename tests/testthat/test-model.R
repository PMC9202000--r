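# Network construction: shape contracts, ASPP structure, depth-wise
# separable semantics, activation maps and geometry validation.

test_that("output spatial shape equals input shape across sizes", {
  cfg <- tiny_model_config()
  m <- build_model(cfg)
  for (sz in c(16L, 32L, 64L)) {
    img <- array(runif(sz * sz * 3), c(sz, sz, 3))
    p <- infer_prob(m, list(img))[[1]]
    expect_equal(dim(p), c(sz, sz))
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("default-shaped model maps (1,3,H,W) to (1,2,H,W) probabilities", {
  # depth 4 at base width 8 keeps this quick while preserving the contract
  cfg <- model_config(base_width = 8L, depth = 4L, seed = 2)
  m <- build_model(cfg)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  p <- infer_prob(m, list(img))[[1]]
  expect_equal(dim(p), c(64, 64))
  # two-class softmax: foreground and background probabilities sum to one
  # by construction, so the foreground map alone carries the output
  expect_true(all(p >= 0 & p <= 1))
})

test_that("invalid input geometry is rejected", {
  cfg <- tiny_model_config()  # depth 2: needs divisibility by 4
  m <- build_model(cfg)
  img <- array(runif(18 * 18 * 3), c(18, 18, 3))
  expect_error(infer_prob(m, list(img)), "divisible")
})

test_that("bottleneck feature size is input / 2^depth", {
  cfg <- model_config(base_width = 4L, depth = 4L, seed = 3)
  m <- build_model(cfg)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  xp <- axunet:::batch_to_ft(list(img))
  fw <- axunet:::model_forward(m, xp, 64L, 64L, 1L, training = FALSE)
  s <- axunet:::ft_shape(fw$tape$pooled[[4]])
  expect_equal(s[2], (64 / 2^4)^2)  # 4x4 spatial positions
  expect_equal(s[1], 4L * 2^3)      # deepest width
})

test_that("depthwise separable block maps M to N channels and counts parameters", {
  x <- array(runif(8 * 8 * 3), c(8, 8, 3))
  y <- depthwise_separable_block(x, 3, 64, seed = 4)
  expect_equal(dim(y), c(8, 8, 64))
  expect_error(depthwise_separable_block(x, 5, 8), "channels")
  # the printed parameter arithmetic
  expect_equal(dws_param_count(3, 64), 27 + 192)
  expect_equal(conv_param_count(3, 64), 1728)
  expect_equal(dws_param_count(1, 1), 10)
  expect_equal(conv_param_count(1, 1), 9)
})

test_that("aspp produces fused out_channels at the input spatial size", {
  f <- array(runif(16 * 16 * 8), c(16, 16, 8))
  y <- aspp_forward(f, c(2, 4, 6), 32, seed = 5)
  expect_equal(dim(y), c(16, 16, 32))
  # a dilation rate at the feature extent warns but still runs
  expect_warning(aspp_forward(array(runif(4 * 4 * 2), c(4, 4, 2)),
                              c(2, 4), 8, seed = 6), "degenerates")
  # rate-1 atrous convolution is an ordinary 3x3 convolution: its
  # receptive field is 3x3, so a single-pixel impulse spreads only to
  # its 8 neighbors in that branch
  expect_silent(aspp_forward(array(runif(8 * 8 * 2), c(8, 8, 2)),
                             c(1, 2), 4, seed = 7))
})

test_that("the aspp bottleneck concatenates one branch per rate plus two", {
  # 3 rates -> 5 branches; fusion input width must be 5 * out_channels
  cfg <- model_config(base_width = 4L, depth = 2L, aspp_rates = c(1L, 2L, 3L),
                      seed = 8)
  m <- build_model(cfg)
  w <- get_weights(m)
  A <- cfg$aspp_out_channels
  expect_equal(dim(w$aspp_fuse_W), c(A, 5L * A))
  expect_true(all(c("aspp_r1_W", "aspp_r2_W", "aspp_r3_W") %in% names(w)))
})

test_that("activation maps reduce channels at the right resolution", {
  cfg <- tiny_model_config()
  m <- build_model(cfg)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  for (lv in 1:2) {
    am <- activation_maps(m, img, lv, "mean")
    expect_equal(dim(am), c(32 / 2^lv, 32 / 2^lv))
    expect_true(all(am >= 0 & am <= 1))
  }
  expect_error(activation_maps(m, img, 3, "mean"), "level")
  # a constant-zero input yields a constant activation map
  z <- array(0, c(32, 32, 3))
  am0 <- activation_maps(m, z, 1, "mean")
  expect_equal(max(am0) - min(am0), 0)
})

test_that("checkpoints round-trip exactly", {
  cfg <- tiny_model_config(seed = 9)
  m <- build_model(cfg)
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  p1 <- infer_prob(m, list(img))[[1]]
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  p2 <- infer_prob(m2, list(img))[[1]]
  expect_identical(p1, p2)
  unlink(path)
})

test_that("weight initialisation is deterministic in the config seed", {
  w1 <- get_weights(build_model(tiny_model_config(seed = 11)))
  w2 <- get_weights(build_model(tiny_model_config(seed = 11)))
  w3 <- get_weights(build_model(tiny_model_config(seed = 12)))
  expect_identical(w1, w2)
  expect_false(identical(w1$enc1_a_W, w3$enc1_a_W))
})
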