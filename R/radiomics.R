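## GLCM texture radiomics and the two-group nonparametric comparison:
## per-subject features from the gray-level co-occurrence matrix of the
## segmented ROI, Pearson correlation screening of redundant features,
## Shapiro-Wilk normality checks per group, and a Mann-Whitney U test
## (exact by enumeration for small groups, tie-corrected normal
## approximation otherwise) with significance flagged at p <= 0.05.

#' Gray-level co-occurrence matrix of a masked ROI
#'
#' Quantizes the ROI intensities to `levels` gray bins over the ROI's
#' own intensity range, counts co-occurring bin pairs at the given pixel
#' `distance` along each angle (both pixels must lie inside the mask),
#' symmetrizes, averages over angles and normalizes to sum 1.
#'
#' @param roi_pixels Intensity matrix.
#' @param mask Binary matrix of the same shape selecting the ROI.
#' @param levels Number of gray levels (radiomics-standard default 32).
#' @param distance Pixel offset distance.
#' @param angles Offset angles in degrees, subset of 0/45/90/135.
#' @param symmetric Count both pixel orders (default `TRUE`).
#' @return An object of class `axunet_glcm`: list with the `levels x levels`
#'   probability matrix `P` and the construction parameters.
#' @export
compute_glcm <- function(roi_pixels, mask, levels = 32L, distance = 1L,
                         angles = c(0, 45, 90, 135), symmetric = TRUE) {
  stopifnot(all(dim(roi_pixels) == dim(mask)), all(mask %in% c(0, 1)),
            levels >= 2L, distance >= 1L,
            all(angles %in% c(0, 45, 90, 135)))
  inside <- mask == 1
  if (sum(inside) < 2L) stop("need at least 2 masked pixels", call. = FALSE)
  vals <- roi_pixels[inside]
  rng <- range(vals)
  q <- matrix(1L, nrow(mask), ncol(mask))
  if (rng[2] > rng[1]) {
    q[inside] <- pmin(floor((roi_pixels[inside] - rng[1]) /
                              (rng[2] - rng[1]) * levels) + 1L, levels)
  }
  offsets <- list(`0` = c(0L, 1L), `45` = c(-1L, 1L),
                  `90` = c(-1L, 0L), `135` = c(-1L, -1L))
  H <- nrow(mask); W <- ncol(mask)
  P <- matrix(0, levels, levels)
  npairs <- 0L
  for (ang in angles) {
    o <- offsets[[as.character(ang)]] * distance
    r1 <- seq_len(H)[seq_len(H) + o[1] >= 1L & seq_len(H) + o[1] <= H]
    c1 <- seq_len(W)[seq_len(W) + o[2] >= 1L & seq_len(W) + o[2] <= W]
    if (!length(r1) || !length(c1)) next
    m1 <- inside[r1, c1, drop = FALSE]
    m2 <- inside[r1 + o[1], c1 + o[2], drop = FALSE]
    ok <- m1 & m2
    if (!any(ok)) next
    a <- q[r1, c1, drop = FALSE][ok]
    b <- q[r1 + o[1], c1 + o[2], drop = FALSE][ok]
    tab <- table(factor(a, levels = seq_len(levels)),
                 factor(b, levels = seq_len(levels)))
    Pang <- unclass(tab)
    if (symmetric) Pang <- Pang + t(Pang)
    P <- P + Pang
    npairs <- npairs + sum(ok)
  }
  if (npairs == 0L)
    stop("ROI smaller than the offset reach: no valid pixel pairs", call. = FALSE)
  P <- P / sum(P)
  structure(list(P = P, levels = as.integer(levels),
                 distance = as.integer(distance), angles = angles,
                 symmetric = symmetric),
            class = "axunet_glcm")
}

#' Texture features from a GLCM
#'
#' The ten per-subject texture features: six computed over the GLCM
#' probabilities `P_ij` with 0-based level indices `i, j` —
#' entropy `S = sum P (-ln P)` (nats, `0 ln 0 := 0`),
#' energy `E = sum P^2`,
#' homogeneity `GH = sum P / (1 + (i-j)^2)`,
#' dissimilarity `GD = sum P |i-j|`,
#' edge sharpness `Acu = sum (P - mean(P))^2`,
#' contrast `C = sum P (i-j)^2` — plus the GLCM contrast `GC` (identical
#' formula to `C`, retained as its own named column), the GLCM marginal
#' mean and standard deviation, and the plain ROI gray mean. With
#' `domain = "pixel"` the distributional features (`S`, `E`, `Acu`) are
#' computed over the quantized pixel histogram instead of the GLCM.
#'
#' @param glcm An [compute_glcm()] result.
#' @param roi_pixels,mask Optional ROI intensities and mask for
#'   `gray_mean` (otherwise `NA`) and for the pixel-domain variant.
#' @param domain `"glcm"` (default) or `"pixel"`.
#' @return A one-row tibble with the ten feature columns.
#' @export
texture_features <- function(glcm, roi_pixels = NULL, mask = NULL,
                             domain = c("glcm", "pixel")) {
  domain <- match.arg(domain)
  stopifnot(inherits(glcm, "axunet_glcm"))
  P <- glcm$P
  N <- glcm$levels
  i <- matrix(0:(N - 1), N, N)
  j <- t(i)
  plogp <- ifelse(P > 0, P * log(P), 0)
  if (domain == "pixel") {
    if (is.null(roi_pixels) || is.null(mask))
      stop("pixel-domain features need roi_pixels and mask", call. = FALSE)
    vals <- roi_pixels[mask == 1]
    rng <- range(vals)
    qv <- if (rng[2] > rng[1])
      pmin(floor((vals - rng[1]) / (rng[2] - rng[1]) * N) + 1L, N) else rep(1L, length(vals))
    h <- tabulate(qv, nbins = N) / length(qv)
    S <- -sum(ifelse(h > 0, h * log(h), 0))
    E <- sum(h^2)
    Acu <- sum((h - mean(h))^2)
  } else {
    S <- -sum(plogp)
    E <- sum(P^2)
    Acu <- sum((P - mean(P))^2)
  }
  C <- sum(P * (i - j)^2)
  pi_ <- rowSums(P)
  gm <- sum((0:(N - 1)) * pi_)
  gs <- sqrt(sum(((0:(N - 1)) - gm)^2 * pi_))
  tibble::tibble(
    entropy = S,
    energy = E,
    glcm_homogeneity = sum(P / (1 + (i - j)^2)),
    glcm_dissimilarity = sum(P * abs(i - j)),
    acu = Acu,
    contrast = C,
    gray_mean = if (is.null(roi_pixels) || is.null(mask)) NA_real_
                else mean(roi_pixels[mask == 1]),
    glcm_contrast = C,
    glcm_mean = gm,
    glcm_std = gs)
}

#' Pearson correlation screening
#'
#' Computes the full Pearson correlation matrix of the feature columns
#' and iteratively removes redundancy: while any pair exceeds
#' `|r| >= threshold`, the strongest-correlated pair is located and its
#' later-ordered member is dropped, so earlier columns act as the
#' canonical representatives of a correlated cluster (the feature order
#' of [texture_features()] lists the domain's primary features first).
#' Constant columns have undefined correlations; they are flagged and
#' excluded from screening.
#'
#' @param features A data frame of numeric feature columns.
#' @param threshold Absolute-correlation cutoff (default 0.9).
#' @return A list with `table` (screened tibble), `dropped`, `constant`
#'   and the initial correlation matrix `cor`.
#' @export
pearson_screen <- function(features, threshold = 0.9) {
  stopifnot(is.data.frame(features), ncol(features) >= 2L, nrow(features) >= 3L)
  X <- as.data.frame(features)
  num <- vapply(X, is.numeric, logical(1))
  stopifnot(all(num))
  const <- names(X)[vapply(X, function(v) sd(v) == 0 || !is.finite(sd(v)), logical(1))]
  act <- setdiff(names(X), const)
  cm <- suppressWarnings(stats::cor(X[act]))
  cm0 <- cm
  dropped <- character(0)
  repeat {
    a <- abs(cm)
    diag(a) <- 0
    if (all(a < threshold, na.rm = TRUE) || nrow(a) <= 1L) break
    ij <- which(a == max(a, na.rm = TRUE), arr.ind = TRUE)[1, ]
    # drop the later-ordered member of the strongest pair
    ord <- match(rownames(a), names(X))
    nm <- rownames(a)[ij[which.max(ord[ij])]]
    dropped <- c(dropped, nm)
    keep <- setdiff(rownames(a), nm)
    cm <- cm[keep, keep, drop = FALSE]
  }
  keep <- setdiff(names(X), c(const, dropped))
  list(table = tibble::as_tibble(X[keep]), dropped = dropped,
       constant = const, cor = cm0)
}

#' Shapiro-Wilk normality test per group
#'
#' @param values Numeric vector.
#' @param group Factor-like group labels aligned with `values`.
#' @return A tibble with one row per group (`group`, `w`, `p`); a
#'   degenerate (constant) sample yields `NA` with a flag.
#' @export
normality_test <- function(values, group) {
  stopifnot(length(values) == length(group))
  purrr::map_dfr(split(values, group), function(v) {
    if (length(v) < 3L) stop("Shapiro-Wilk needs n >= 3 per group", call. = FALSE)
    if (length(v) > 5000L) stop("Shapiro-Wilk needs n <= 5000", call. = FALSE)
    if (sd(v) == 0)
      return(tibble::tibble(w = NA_real_, p = NA_real_, degenerate = TRUE))
    sw <- shapiro.test(v)
    tibble::tibble(w = unname(sw$statistic), p = sw$p.value, degenerate = FALSE)
  }, .id = "group")
}

# exact null distribution of U by enumeration over rank assignments
mw_exact_p <- function(u, n, m) {
  N <- n + m
  combs <- utils::combn(N, n)
  tot <- ncol(combs)
  us <- colSums(combs) - n * (n + 1) / 2
  ple <- sum(us <= u) / tot
  pge <- sum(us >= u) / tot
  min(1, 2 * min(ple, pge))
}

#' Mann-Whitney U rank test
#'
#' U statistic with midrank ties. The two-sided p-value is exact (full
#' enumeration of all rank labelings) when `min(n, m) <= 8` and the data
#' contain no ties, and otherwise uses the normal approximation with tie
#' correction and continuity correction.
#'
#' @param group_a,group_b Numeric vectors (non-empty).
#' @return A list with `U` (statistic of the first group), `p`
#'   (two-sided) and `method`.
#' @export
mann_whitney <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 1L, length(group_b) >= 1L)
  n <- length(group_a); m <- length(group_b)
  all_ <- c(group_a, group_b)
  r <- rank(all_)
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- anyDuplicated(all_) > 0L
  if (!ties && min(n, m) <= 8L) {
    p <- mw_exact_p(u, n, m)
    method <- "exact"
  } else {
    N <- n + m
    tt <- table(all_)
    tie_term <- sum(tt^3 - tt) / (N * (N - 1))
    sigma2 <- n * m / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(u - n * m / 2) - 0.5) / sqrt(sigma2)
      z <- max(z, 0)
      p <- min(1, 2 * stats::pnorm(-z))
    }
    method <- "normal_approx"
  }
  list(U = u, p = p, method = method)
}

#' Cohort radiomics report
#'
#' The full downstream pipeline on a segmented two-group cohort: extract
#' the ten texture features from each subject's ROI, screen highly
#' correlated features by Pearson correlation, test each retained
#' feature for normality per group (Shapiro-Wilk) and for a group
#' difference (Mann-Whitney U, two-sided), flag significance at
#' `p <= alpha` (uncorrected, with a Benjamini-Hochberg column supplied
#' alongside), and attach quartile summaries per feature and group for
#' boxplot display.
#'
#' @param images List of intensity matrices, or a list of
#'   `axunet_phantom` objects (in which case `masks` and `labels` are
#'   taken from the phantoms unless supplied).
#' @param masks List of binary ROI masks.
#' @param labels Group labels, coerced to `"N"`/`"T"` factor order.
#' @param levels,distance GLCM parameters.
#' @param screen_threshold Pearson screening cutoff.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `axunet_stat_report`.
#' @export
cohort_report <- function(images, masks = NULL, labels = NULL,
                          levels = 32L, distance = 1L,
                          screen_threshold = 0.9, alpha = 0.05) {
  if (length(images) && inherits(images[[1]], "axunet_phantom")) {
    phantoms <- images
    images <- purrr::map(phantoms, "image")
    if (is.null(masks)) masks <- purrr::map(phantoms, "mask")
    if (is.null(labels)) labels <- purrr::map_chr(phantoms, "label")
  }
  stopifnot(length(images) == length(masks), length(images) == length(labels))
  labels <- as.character(labels)
  if (min(table(labels)) < 3L)
    stop("each group needs at least 3 subjects", call. = FALSE)
  if (length(unique(labels)) != 2L)
    stop("exactly two groups required", call. = FALSE)
  feats <- purrr::map2_dfr(images, masks, function(img, msk) {
    g <- compute_glcm(img, msk, levels = levels, distance = distance)
    texture_features(g, img, msk)
  })
  screened <- pearson_screen(feats, screen_threshold)
  groups <- sort(unique(labels))
  tests <- purrr::map_dfr(names(screened$table), function(f) {
    v <- screened$table[[f]]
    sw <- tryCatch(normality_test(v, labels),
                   error = function(e) NULL)
    mw <- mann_whitney(v[labels == groups[1]], v[labels == groups[2]])
    tibble::tibble(
      feature = f,
      sw_p_a = if (is.null(sw)) NA_real_ else sw$p[sw$group == groups[1]],
      sw_p_b = if (is.null(sw)) NA_real_ else sw$p[sw$group == groups[2]],
      U = mw$U, p = mw$p, method = mw$method)
  })
  tests$p_bh <- stats::p.adjust(tests$p, method = "BH")
  tests$significant <- tests$p <= alpha
  names(tests)[names(tests) == "sw_p_a"] <- paste0("sw_p_", groups[1])
  names(tests)[names(tests) == "sw_p_b"] <- paste0("sw_p_", groups[2])
  summaries <- dplyr::bind_cols(tibble::tibble(group = labels), feats) |>
    tidyr::pivot_longer(-"group", names_to = "feature") |>
    dplyr::group_by(.data$feature, .data$group) |>
    dplyr::summarise(
      q1 = quantile(.data$value, 0.25), median = median(.data$value),
      q3 = quantile(.data$value, 0.75), min = min(.data$value),
      max = max(.data$value), .groups = "drop")
  structure(list(features = dplyr::bind_cols(tibble::tibble(group = labels), feats),
                 screened = screened$table, dropped = screened$dropped,
                 constant = screened$constant, cor = screened$cor,
                 tests = tests, summaries = summaries, alpha = alpha),
            class = "axunet_stat_report")
}

#' @export
print.axunet_stat_report <- function(x, ...) {
  sig <- x$tests$feature[x$tests$significant]
  cat(sprintf("<axunet_stat_report> %d subjects, %d features tested (%d dropped)\n",
              nrow(x$features), nrow(x$tests), length(x$dropped)))
  cat("significant at p <=", x$alpha, ":",
      if (length(sig)) paste(sig, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' @method tidy axunet_stat_report
#' @export
tidy.axunet_stat_report <- function(x, ...) x$tests

#' @method glance axunet_stat_report
#' @export
glance.axunet_stat_report <- function(x, ...) {
  tibble::tibble(n_subjects = nrow(x$features),
                 n_features = ncol(x$features) - 1L,
                 n_tested = nrow(x$tests),
                 n_dropped = length(x$dropped),
                 n_significant = sum(x$tests$significant))
}

#' Write a stat report to disk
#'
#' Emits the per-subject feature CSV, the correlation matrix CSV and a
#' JSON file with the test table and summaries.
#'
#' @param report An `axunet_stat_report`.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_stat_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$features, file.path(dir, "features.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(report$cor), file.path(dir, "correlation.csv"))
  jsonlite::write_json(
    list(tests = report$tests, dropped = report$dropped,
         summaries = report$summaries, alpha = report$alpha),
    file.path(dir, "report.json"), dataframe = "rows", auto_unbox = TRUE,
    digits = NA)
  invisible(dir)
}
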