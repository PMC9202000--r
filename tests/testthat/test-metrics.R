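# Overlap and boundary metrics: hand-counted fixtures, brute-force
# oracle equivalence, algebraic identities and metric properties.

test_that("dice matches hand-counted fixtures", {
  fx <- fixture_masks()
  expect_equal(dice(fx$z, fx$y), 0.6)
  expect_equal(dice(fx$y, fx$y), 1)
  a <- matrix(0, 4, 4); a[1, 1] <- 1
  b <- matrix(0, 4, 4); b[4, 4] <- 1
  expect_equal(dice(a, b), 0)
  expect_equal(dice(matrix(0, 3, 3), matrix(0, 3, 3)), 1)  # both empty
  expect_error(dice(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("jaccard matches fixtures and the dice identity", {
  fx <- fixture_masks()
  expect_equal(jaccard(fx$z, fx$y), 3 / 7)
  j <- jaccard(fx$z, fx$y)
  expect_equal(2 * j / (1 + j), dice(fx$z, fx$y), tolerance = 1e-15)
  expect_error(jaccard(matrix(0, 3, 3), matrix(0, 3, 3)), "empty")
})

test_that("DSC = 2J/(1+J) on 200 random mask pairs to 1e-12", {
  set.seed(100)
  for (i in 1:200) {
    z <- random_mask(10, 10, 0.4)
    y <- random_mask(10, 10, 0.4)
    if (sum(pmax(z, y)) == 0) next
    j <- jaccard(z, y)
    expect_equal(dice(z, y), 2 * j / (1 + j), tolerance = 1e-12)
    expect_equal(dice(z, y), dice(y, z))  # symmetry
  }
})

test_that("precision and recall count pixels as stated", {
  y <- matrix(0, 5, 5); y[1:5, 1] <- 1            # |truth| = 5
  sup <- y; sup[1:5, 2] <- 1                      # prediction superset, |pred| = 10
  pr <- precision_recall(sup, y)
  expect_equal(unname(pr), c(0.5, 1.0))
  y2 <- matrix(0, 5, 5); y2[, 1:2] <- 1           # |truth| = 10
  sub <- matrix(0, 5, 5); sub[, 1] <- 1           # prediction subset, |pred| = 5
  pr2 <- precision_recall(sub, y2)
  expect_equal(unname(pr2), c(1.0, 0.5))
  expect_equal(unname(precision_recall(y, y)), c(1, 1))
  # empty prediction: precision undefined, not zero
  pr3 <- precision_recall(matrix(0, 5, 5), y)
  expect_true(is.na(pr3[["precision"]]))
  expect_equal(pr3[["recall"]], 0)
})

test_that("hausdorff equals the brute-force double loop", {
  expect_equal(hausdorff(rbind(c(0, 0)), rbind(c(3, 4))), 5)
  a <- rbind(c(1, 1), c(2, 2))
  expect_equal(hausdorff(a, a), 0)
  set.seed(17)
  for (i in 1:50) {
    a <- matrix(runif(100, 0, 20), ncol = 2)
    b <- matrix(runif(100, 0, 20), ncol = 2)
    expect_equal(hausdorff(a, b), oracle_hausdorff(a, b), tolerance = 1e-12)
    expect_equal(hausdorff(a, b), hausdorff(b, a))
  }
})

test_that("hausdorff satisfies the triangle inequality on random point sets", {
  set.seed(23)
  for (i in 1:30) {
    a <- matrix(runif(30, 0, 10), ncol = 2)
    b <- matrix(runif(30, 0, 10), ncol = 2)
    c_ <- matrix(runif(30, 0, 10), ncol = 2)
    expect_lte(hausdorff(a, c_), hausdorff(a, b) + hausdorff(b, c_) + 1e-12)
  }
})

test_that("boundary extraction keeps only 4-neighbor border pixels", {
  m <- matrix(0, 5, 5); m[2:4, 2:4] <- 1
  bp <- boundary_points(m)
  expect_equal(nrow(bp), 8)  # 3x3 block: all but the center pixel
  expect_false(any(bp[, 1] == 3 & bp[, 2] == 3))
  # a filled mask touching the image border is still bounded
  full <- matrix(1, 4, 4)
  expect_equal(nrow(boundary_points(full)), 12)
  expect_error(hausdorff(boundary_points(matrix(0, 3, 3)), bp), "non-empty")
})

test_that("evaluate_masks aggregates per-case metrics", {
  set.seed(3)
  zs <- lapply(1:4, function(i) random_mask(12, 12, 0.3))
  ys <- lapply(1:4, function(i) random_mask(12, 12, 0.3))
  ev <- evaluate_masks(zs, ys)
  expect_equal(nrow(ev), 4)
  expect_true(all(c("dice", "jaccard", "precision", "recall", "hausdorff")
                  %in% names(ev)))
  g <- glance(ev)
  expect_equal(g$n, 4)
  expect_equal(g$dice_mean, mean(ev$dice))
})
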