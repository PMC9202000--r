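# Loss components against independent scalar-arithmetic oracles, exact
# zeros at perfect predictions, linearity in the mixing weights, and
# finite-difference gradient agreement.

test_that("generalized Dice loss matches the scalar oracle and its closed forms", {
  # 4x4 image, 2 foreground pixels, uniform 0.5 prediction
  target <- matrix(0, 4, 4); target[2, 2:3] <- 1
  pred <- matrix(0.5, 4, 4)
  expect_equal(generalized_dice_loss(pred, target),
               oracle_gdl(pred, target), tolerance = 1e-12)
  # perfect overlap -> 0 (within epsilon stabilisation)
  expect_lt(generalized_dice_loss(target, target), 1e-4)
  # total miss on a 50/50 image -> 1 (within epsilon)
  half <- matrix(0, 4, 4); half[1:2, ] <- 1
  expect_equal(generalized_dice_loss(1 - half, half), 1, tolerance = 1e-3)
  # random pairs equal the oracle
  set.seed(42)
  for (i in 1:20) {
    y <- random_mask(8, 8)
    p <- matrix(runif(64), 8, 8)
    expect_equal(generalized_dice_loss(p, y), oracle_gdl(p, y),
                 tolerance = 1e-10)
  }
  expect_error(generalized_dice_loss(matrix(0.1, 3, 3), matrix(0, 3, 3),
                                     strict = TRUE), "foreground")
})

test_that("focal loss matches hand evaluation and reduces to scaled cross-entropy", {
  # single pixel y=1, p=0.5, alpha=0.25, gamma=2
  expect_equal(focal_loss(matrix(0.5), matrix(1)),
               -0.25 * 0.25 * log(0.5), tolerance = 1e-12)
  # perfect confidence -> 0
  y <- random_mask(6, 6)
  expect_equal(focal_loss(y, y), 0, tolerance = 1e-6)
  # gamma=0, alpha=0.5 is half the binary cross-entropy
  set.seed(7)
  p <- matrix(runif(36, 0.05, 0.95), 6, 6)
  bce <- mean(-y * log(p) - (1 - y) * log(1 - p))
  expect_equal(focal_loss(p, y, alpha = 0.5, gamma = 0), 0.5 * bce,
               tolerance = 1e-10)
  # oracle equivalence on random pairs
  for (i in 1:20) {
    y <- random_mask(8, 8); p <- matrix(runif(64), 8, 8)
    expect_equal(focal_loss(p, y), oracle_focal(p, y), tolerance = 1e-10)
  }
  expect_error(focal_loss(p, y, gamma = -1), "gamma")
})

test_that("focal loss strictly decreases in p for a true-foreground pixel", {
  ps <- seq(0.05, 0.95, by = 0.05)
  ls <- vapply(ps, function(p) focal_loss(matrix(p), matrix(1)), numeric(1))
  expect_true(all(diff(ls) < 0))
})

test_that("Sobel edge map reproduces direct 3x3 convolution arithmetic", {
  k <- sobel_kernels()
  expect_equal(sum(k$Gx), 0)
  expect_equal(sum(k$Gy), 0)
  expect_equal(k$Gy, -t(k$Gx))
  # constant array -> zero edges
  expect_true(all(sobel_edge_map(matrix(0.7, 5, 5)) == 0))
  # vertical binary step: |gx| = 4 at the step, gy = 0 on interior rows
  x <- cbind(matrix(0, 6, 3), matrix(1, 6, 3))
  raw <- sqrt(axunet:::conv3x3_same(x, k$Gx)^2 + axunet:::conv3x3_same(x, k$Gy)^2)
  expect_equal(raw[3, 3], 4)  # before normalization
  expect_equal(axunet:::conv3x3_same(x, k$Gy)[3, 3], 0)
  # full map equals the scalar oracle
  set.seed(1)
  z <- matrix(runif(48), 6, 8)
  expect_equal(sobel_edge_map(z), oracle_sobel(z), tolerance = 1e-12)
  expect_error(sobel_edge_map(matrix(1, 2, 2)), "3x3")
})

test_that("contour-aware loss is zero at equality and grows under translation", {
  y <- matrix(0, 12, 12); y[4:8, 4:7] <- 1
  expect_lt(contour_aware_loss(y, y), 1e-6)
  # prediction translated by 2 px scores strictly worse
  yt <- matrix(0, 12, 12); yt[6:10, 6:9] <- 1
  expect_gt(contour_aware_loss(yt, y), contour_aware_loss(y, y))
  # constant-0.5 prediction vs binary target equals the composed oracle
  p <- matrix(0.5, 8, 8); tg <- matrix(0, 8, 8); tg[3:5, 3:6] <- 1
  expect_equal(contour_aware_loss(p, tg), oracle_cal(p, tg), tolerance = 1e-10)
  # random pairs
  set.seed(5)
  for (i in 1:10) {
    y2 <- random_mask(8, 8); p2 <- matrix(runif(64), 8, 8)
    expect_equal(contour_aware_loss(p2, y2), oracle_cal(p2, y2),
                 tolerance = 1e-10)
  }
})

test_that("ms-ssim criterion is available and bounded", {
  y <- matrix(0, 32, 32); y[10:20, 12:22] <- 1
  expect_lt(contour_aware_loss(y, y, criterion = "ms_ssim"), 1e-6)
  p <- matrix(runif(1024), 32, 32)
  v <- contour_aware_loss(p, y, criterion = "ms_ssim")
  expect_gte(v, 0)
  expect_error(contour_aware_loss(matrix(0.5, 4, 4), matrix(0, 4, 4),
                                  criterion = "ms_ssim"), "small")
})

test_that("hybrid loss is exactly linear in the weights", {
  set.seed(9)
  for (i in 1:20) {
    y <- random_mask(8, 8); p <- matrix(runif(64), 8, 8)
    cal <- contour_aware_loss(p, y)
    foc <- focal_loss(p, y)
    gdl <- generalized_dice_loss(p, y)
    w <- runif(3); w <- w / sum(w)
    lw <- loss_weights(w[1], w[2], w[3], normalize_check = FALSE)
    expect_equal(hybrid_loss(p, y, lw),
                 w[1] * cal + w[2] * foc + w[3] * gdl, tolerance = 1e-12)
  }
  # basis vector recovers GDL alone
  y <- random_mask(8, 8); p <- matrix(runif(64), 8, 8)
  expect_equal(hybrid_loss(p, y, loss_weights(0, 0, 1)),
               generalized_dice_loss(p, y), tolerance = 1e-12)
  # perfect binary prediction -> 0
  expect_lt(hybrid_loss(y, y), 1e-4)
})

test_that("analytic hybrid-loss gradient matches finite differences", {
  set.seed(21)
  y <- random_mask(8, 8)
  p <- matrix(runif(64, 0.1, 0.9), 8, 8)
  lg <- hybrid_loss_grad(p, y)
  h <- 1e-6
  # a handful of pixels, including foreground and background
  for (idx in c(1, 9, 23, 40, 64)) {
    pp <- p; pp[idx] <- p[idx] + h
    pm <- p; pm[idx] <- p[idx] - h
    fd <- (hybrid_loss(pp, y) - hybrid_loss(pm, y)) / (2 * h)
    expect_equal(lg$grad[idx], fd, tolerance = 1e-4)
  }
})

test_that("loss weights validate and default to the published mix", {
  lw <- loss_weights()
  expect_equal(c(lw$w_cal, lw$w_focal, lw$w_gdl), c(0.6, 0.2, 0.2))
  expect_error(loss_weights(0.5, 0.2, 0.2), "sum to 1")
  expect_error(loss_weights(-0.1, 0.6, 0.5), "\\[0, 1\\]")
  expect_silent(loss_weights(0.5, 0.2, 0.2, normalize_check = FALSE))
})
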