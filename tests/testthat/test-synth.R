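# Phantom generator: determinism, the small-target regime, the
# class-conditional texture contrast, cohort structure and pseudo-volumes.

test_that("identical seeds give bit-identical phantoms", {
  a <- make_phantom(phantom_spec(seed = 7))
  b <- make_phantom(phantom_spec(seed = 7))
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  c_ <- make_phantom(phantom_spec(seed = 8))
  expect_false(identical(a$mask, c_$mask))
})

test_that("foreground fraction honors the small-target regime across seeds", {
  fr <- vapply(1:100, function(s) {
    mean(make_phantom(phantom_spec(seed = s, size = c(128L, 128L),
                                   fg_fraction_target = 0.01))$mask)
  }, numeric(1))
  expect_true(all(fr >= 0.005 & fr <= 0.015))
})

test_that("phantom masks are a single connected component", {
  # flood fill from any foreground pixel reaches the whole mask
  flood_size <- function(mask) {
    idx <- which(mask == 1, arr.ind = TRUE)
    seen <- matrix(FALSE, nrow(mask), ncol(mask))
    queue <- list(idx[1, ])
    seen[idx[1, 1], idx[1, 2]] <- TRUE
    n <- 0
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]; n <- n + 1
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        q <- p + d
        if (q[1] >= 1 && q[1] <= nrow(mask) && q[2] >= 1 && q[2] <= ncol(mask) &&
            mask[q[1], q[2]] == 1 && !seen[q[1], q[2]]) {
          seen[q[1], q[2]] <- TRUE
          queue <- c(queue, list(q))
        }
      }
    }
    n
  }
  for (s in c(1, 2, 3)) {
    ph <- make_phantom(phantom_spec(seed = s))
    expect_equal(flood_size(ph$mask), sum(ph$mask))
  }
})

test_that("tumor-like texture shares the mask but raises intra-blob variance", {
  for (s in 1:10) {
    pn <- make_phantom(phantom_spec(seed = s, texture_class = "normal"))
    pt <- make_phantom(phantom_spec(seed = s, texture_class = "tumor_like"))
    expect_identical(pn$mask, pt$mask)
    vn <- var(pn$image[pn$mask == 1])
    vt <- var(pt$image[pt$mask == 1])
    expect_gt(vt, vn)
  }
})

test_that("tumor phantoms have larger intra-ROI gray-level entropy", {
  ent <- function(ph) {
    g <- compute_glcm(ph$image, ph$mask, levels = 16)
    texture_features(g)$entropy
  }
  wins <- 0
  for (s in 1:40) {
    en <- ent(make_phantom(phantom_spec(seed = s, texture_class = "normal")))
    et <- ent(make_phantom(phantom_spec(seed = s, texture_class = "tumor_like")))
    if (et > en) wins <- wins + 1
  }
  expect_gte(wins / 40, 0.95)
})

test_that("cohorts have the requested sizes, labels and reproducibility", {
  ch <- make_cohort(13, 31, phantom_spec(size = c(64L, 64L)), seed = 3)
  expect_length(ch, 44)
  expect_equal(sum(vapply(ch, function(p) p$label, "") == "T"), 31)
  ch2 <- make_cohort(1, 1, phantom_spec(size = c(64L, 64L)), seed = 3)
  ch3 <- make_cohort(1, 1, phantom_spec(size = c(64L, 64L)), seed = 3)
  expect_identical(ch2[[1]]$image, ch3[[1]]$image)
  expect_identical(ch2[[2]]$image, ch3[[2]]$image)
})

test_that("pseudo-volumes drift smoothly across slices", {
  v <- make_volume(phantom_spec(seed = 4, n_slices = 5L))
  expect_equal(dim(v$image)[3], 5)
  for (s in 1:4) {
    d <- dice(v$mask[, , s], v$mask[, , s + 1])
    expect_gt(d, 0.7)
  }
  expect_error(make_volume(phantom_spec(seed = 4, n_slices = 2L)), ">= 3")
  # determinism
  v2 <- make_volume(phantom_spec(seed = 4, n_slices = 5L))
  expect_identical(v$image, v2$image)
})

test_that("generated images are valid preprocessing inputs", {
  for (s in 1:5) {
    ph <- make_phantom(phantom_spec(seed = s))
    expect_true(all(ph$image >= 0 & ph$image <= 1))
    x <- axunet:::preprocess_slice(ph$image)
    expect_true(all(x >= 0 & x <= 1))
    expect_equal(dim(x), c(128, 128, 3))
  }
})
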