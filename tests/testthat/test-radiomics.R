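# GLCM construction and texture features against brute-force counters,
# exact nonparametric statistics, correlation screening, and the cohort
# report surface.

test_that("GLCM matches the brute-force double-loop counter", {
  set.seed(31)
  for (i in 1:10) {
    img <- matrix(runif(64), 8, 8)
    mask <- matrix(1, 8, 8)
    g <- compute_glcm(img, mask, levels = 8)
    expect_equal(g$P, unname(oracle_glcm(img, mask, 8)), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(sum(g$P), 1, tolerance = 1e-9)
    expect_equal(g$P, t(g$P), tolerance = 1e-12)  # symmetric mode
  }
  # masked ROI: pairs crossing the mask edge are excluded
  mask <- matrix(0, 8, 8); mask[3:6, 3:6] <- 1
  img <- matrix(runif(64), 8, 8)
  g <- compute_glcm(img, mask, levels = 4)
  expect_equal(g$P, unname(oracle_glcm(img, mask, 4)), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("constant and checkerboard ROIs give the expected GLCM structure", {
  # constant ROI -> single nonzero entry P[1,1] = 1
  g <- compute_glcm(matrix(0.5, 6, 6), matrix(1, 6, 6), levels = 8)
  expect_equal(g$P[1, 1], 1)
  expect_equal(sum(g$P), 1)
  # checkerboard of two levels at angle 0 -> all mass off-diagonal
  cb <- (outer(1:4, 1:4, "+") %% 2) * 1
  g2 <- compute_glcm(cb, matrix(1, 4, 4), levels = 2, angles = 0)
  expect_equal(sum(diag(g2$P)), 0)
  expect_equal(sum(g2$P), 1)
  expect_error(compute_glcm(matrix(1, 2, 2), matrix(c(1, 0, 0, 0), 2, 2)),
               "2 masked pixels")
})

test_that("texture features equal the scalar loop oracle on random GLCMs", {
  set.seed(41)
  for (i in 1:50) {
    P <- matrix(runif(64), 8, 8)
    P <- (P + t(P)) / 2
    P <- P / sum(P)
    g <- structure(list(P = P, levels = 8L, distance = 1L,
                        angles = c(0, 45, 90, 135), symmetric = TRUE),
                   class = "axunet_glcm")
    f <- texture_features(g)
    o <- oracle_features(P)
    expect_equal(f$entropy, o$S, tolerance = 1e-12)
    expect_equal(f$energy, o$E, tolerance = 1e-12)
    expect_equal(f$glcm_homogeneity, o$GH, tolerance = 1e-12)
    expect_equal(f$glcm_dissimilarity, o$GD, tolerance = 1e-12)
    expect_equal(f$contrast, o$C, tolerance = 1e-12)
    expect_equal(f$acu, o$Acu, tolerance = 1e-12)
  }
})

test_that("closed forms hold: constant ROI and uniform GLCM", {
  g <- compute_glcm(matrix(0.4, 6, 6), matrix(1, 6, 6), levels = 8)
  f <- texture_features(g, matrix(0.4, 6, 6), matrix(1, 6, 6))
  expect_equal(f$entropy, 0)
  expect_equal(f$energy, 1)
  expect_equal(f$glcm_homogeneity, 1)
  expect_equal(f$glcm_dissimilarity, 0)
  expect_equal(f$contrast, 0)
  expect_equal(f$gray_mean, 0.4)
  # uniform GLCM over N^2 = 4 cells: entropy ln 4, energy 1/4; entropy is
  # maximal among all GLCMs with the same level count
  gu <- structure(list(P = matrix(0.25, 2, 2), levels = 2L, distance = 1L,
                       angles = 0, symmetric = TRUE), class = "axunet_glcm")
  fu <- texture_features(gu)
  expect_equal(fu$entropy, log(4), tolerance = 1e-12)
  expect_equal(fu$energy, 0.25, tolerance = 1e-12)
  set.seed(2)
  for (i in 1:20) {
    P <- matrix(runif(4), 2, 2); P <- P / sum(P)
    g2 <- structure(list(P = P, levels = 2L, distance = 1L, angles = 0,
                         symmetric = TRUE), class = "axunet_glcm")
    expect_lte(texture_features(g2)$entropy, log(4) + 1e-12)
  }
})

test_that("pearson screening drops duplicated and near-duplicated columns", {
  set.seed(51)
  n <- 200
  x <- rnorm(n)
  tbl <- tibble::tibble(a = x, b = x, c = rnorm(n), d = rnorm(n))
  sc <- pearson_screen(tbl, 0.9)
  expect_equal(length(sc$dropped), 1L)
  expect_true(sc$dropped %in% c("a", "b"))
  # duplicated-with-noise column (r ~ 0.98) is dropped at 0.9
  tbl2 <- tibble::tibble(a = x, b = x + rnorm(n, sd = 0.2), c = rnorm(n))
  sc2 <- pearson_screen(tbl2, 0.9)
  expect_equal(length(sc2$dropped), 1L)
  # independent columns survive
  tbl3 <- tibble::tibble(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  sc3 <- pearson_screen(tbl3, 0.9)
  expect_equal(sc3$dropped, character(0))
  # constant column flagged, not dropped by correlation
  tbl4 <- tibble::tibble(a = rnorm(n), b = rnorm(n), k = rep(1, n))
  sc4 <- pearson_screen(tbl4, 0.9)
  expect_equal(sc4$constant, "k")
})

test_that("normality test calibrates and detects", {
  # strongly exponential sample rejected in most seeds
  rej <- 0
  for (s in 1:40) {
    set.seed(s)
    nt <- normality_test(rexp(50), rep("g", 50))
    if (nt$p < 0.05) rej <- rej + 1
  }
  expect_gte(rej / 40, 0.95)
  # normal samples not systematically rejected
  rej <- 0
  for (s in 1:40) {
    set.seed(1000 + s)
    nt <- normality_test(rnorm(100), rep("g", 100))
    if (nt$p < 0.05) rej <- rej + 1
  }
  expect_lte(rej / 40, 0.2)
  expect_error(normality_test(c(1, 2), rep("g", 2)), "n >= 3")
  expect_true(normality_test(rep(1, 10), rep("g", 10))$degenerate)
})

test_that("Mann-Whitney exact p equals exhaustive enumeration for all n,m <= 7", {
  # the printed example: {1,2,3} vs {4,5,6}
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)
  expect_equal(mw$method, "exact")
  set.seed(61)
  for (n in 2:7) for (m in n:7) {
    a <- rnorm(n); b <- rnorm(m)
    mw <- mann_whitney(a, b)
    expect_equal(mw$p, oracle_mw_exact(a, b), tolerance = 1e-12,
                 info = sprintf("n=%d m=%d", n, m))
  }
})

test_that("Mann-Whitney agrees with wilcox.test as an independent cross-check", {
  set.seed(71)
  for (i in 1:10) {
    a <- rnorm(6); b <- rnorm(6, 0.5)
    mw <- mann_whitney(a, b)
    wt <- stats::wilcox.test(a, b, exact = TRUE)
    expect_equal(mw$U, unname(wt$statistic))
    expect_equal(mw$p, wt$p.value, tolerance = 1e-10)
  }
  # identical groups: U = nm/2, p near 1
  a <- 1:8
  mw <- mann_whitney(a, a)
  expect_equal(mw$U, 32)
  expect_gte(mw$p, 0.9)
  # large-sample approximation tracks wilcox.test with correction
  set.seed(72)
  a <- rnorm(30); b <- rnorm(25, 0.3)
  mw <- mann_whitney(a, b)
  wt <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(mw$p, wt$p.value, tolerance = 1e-8)
})

test_that("cohort report flags the generator's entropy difference", {
  ch <- make_cohort(6, 8, phantom_spec(size = c(96L, 96L)), seed = 5)
  rep_ <- cohort_report(ch)
  expect_s3_class(rep_, "axunet_stat_report")
  expect_true("entropy" %in% rep_$tests$feature)
  # the duplicated contrast column is screened out
  expect_true(any(c("contrast", "glcm_contrast") %in% rep_$dropped))
  td <- tidy(rep_)
  expect_true(all(td$p >= 0 & td$p <= 1))
  g <- glance(rep_)
  expect_equal(g$n_subjects, 14)
  expect_error(cohort_report(ch[c(1, 7)]), "3 subjects|two groups")
})

test_that("pixel-domain feature variant and report writer work", {
  ph <- make_phantom(phantom_spec(seed = 3, size = c(64L, 64L)))
  g <- compute_glcm(ph$image, ph$mask)
  f_glcm <- texture_features(g, ph$image, ph$mask)
  f_pix <- texture_features(g, ph$image, ph$mask, domain = "pixel")
  # pairwise features are unchanged; distributional ones differ
  expect_equal(f_glcm$contrast, f_pix$contrast)
  expect_equal(f_glcm$glcm_homogeneity, f_pix$glcm_homogeneity)
  expect_false(isTRUE(all.equal(f_glcm$entropy, f_pix$entropy)))
  expect_error(texture_features(g, domain = "pixel"), "pixel-domain")
  rep_ <- cohort_report(make_cohort(4, 5, phantom_spec(size = c(64L, 64L)),
                                    seed = 11))
  d <- tempfile()
  write_stat_report(rep_, d)
  expect_true(file.exists(file.path(d, "features.csv")))
  expect_true(file.exists(file.path(d, "report.json")))
  js <- jsonlite::read_json(file.path(d, "report.json"))
  expect_true(length(js$tests) >= 1)
  unlink(d, recursive = TRUE)
})
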