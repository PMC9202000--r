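## Seeded synthetic CT-like phantoms: a large dark noisy background with
## one small, smooth-edged, elongated bright-ish blob of near-background
## contrast, emulating the small-target / blurry-boundary regime of
## pancreas CT (the organ typically occupies well under 1.5% of a 2D
## slice). The "tumor_like" texture class adds extra intra-blob speckle
## so that intra-ROI gray-level entropy is stochastically larger, which
## is the effect the cohort statistics pipeline is meant to detect.

#' Phantom specification
#'
#' @param seed Integer seed; identical specs produce bit-identical phantoms.
#' @param size `(H, W)` in pixels.
#' @param n_slices Number of slices for pseudo-volumes (see [make_volume()]).
#' @param fg_fraction_target Target foreground fraction of a 2D slice;
#'   the default 0.01 keeps the blob inside the small-target regime
#'   (< 1.5% of the image).
#' @param blob_elongation Ratio of the blob's major to minor semi-axis.
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param intensity_fg,intensity_bg Mean intensities of blob and
#'   background; their small gap (default 0.18) emulates the
#'   near-background soft-tissue contrast of the pancreas.
#' @param texture_class `"normal"` or `"tumor_like"`.
#' @param texture_heterogeneity Speckle multiplier applied inside the
#'   blob for `tumor_like` phantoms (1 = indistinguishable from normal).
#' @return An object of class `axunet_phantom_spec`.
#' @export
phantom_spec <- function(seed = 1L,
                         size = c(128L, 128L),
                         n_slices = 1L,
                         fg_fraction_target = 0.01,
                         blob_elongation = 2.0,
                         noise_sd = 0.04,
                         intensity_fg = 0.48,
                         intensity_bg = 0.30,
                         texture_class = c("normal", "tumor_like"),
                         texture_heterogeneity = 2.5) {
  texture_class <- match.arg(texture_class)
  stopifnot(fg_fraction_target > 0, fg_fraction_target < 0.015,
            blob_elongation >= 1, noise_sd >= 0,
            intensity_fg > 0, intensity_fg < 1,
            intensity_bg > 0, intensity_bg < 1,
            texture_heterogeneity >= 1, n_slices >= 1)
  structure(list(seed = as.integer(seed), size = as.integer(size),
                 n_slices = as.integer(n_slices),
                 fg_fraction_target = fg_fraction_target,
                 blob_elongation = blob_elongation, noise_sd = noise_sd,
                 intensity_fg = intensity_fg, intensity_bg = intensity_bg,
                 texture_class = texture_class,
                 texture_heterogeneity = texture_heterogeneity),
            class = "axunet_phantom_spec")
}

# separable Gaussian blur with replicate padding
gauss_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  H <- nrow(x); W <- ncol(x)
  y <- matrix(0, H, W)
  for (o in (-r):r) {
    rows <- pmin(pmax(seq_len(H) + o, 1L), H)
    y <- y + k[o + r + 1L] * x[rows, , drop = FALSE]
  }
  z <- matrix(0, H, W)
  for (o in (-r):r) {
    cols <- pmin(pmax(seq_len(W) + o, 1L), W)
    z <- z + k[o + r + 1L] * y[, cols, drop = FALSE]
  }
  z
}

# super-ellipse membership on rotated coordinates
superellipse_mask <- function(H, W, cy, cx, a, b, theta, p = 2.5) {
  yy <- matrix(seq_len(H), H, W) - cy
  xx <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  u <- cos(theta) * xx + sin(theta) * yy
  v <- -sin(theta) * xx + cos(theta) * yy
  (abs(u) / a)^p + (abs(v) / b)^p <= 1
}

#' Generate one phantom
#'
#' Draws a randomly placed, randomly oriented super-ellipse blob whose
#' area matches `fg_fraction_target`, composes it over a noisy dark
#' background with a Gaussian-blurred boundary, and (for the
#' `tumor_like` class) adds intra-blob speckle. The blob geometry — and
#' hence the ground-truth mask — depends only on the seed, so the two
#' texture classes share masks at equal seeds.
#'
#' @param spec An [phantom_spec()] object.
#' @return An object of class `axunet_phantom`: a list with `image`
#'   (matrix in `[0, 1]`), `mask` (binary matrix), `label`
#'   (`"N"` or `"T"`) and `spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "axunet_phantom_spec"))
  H <- spec$size[1]; W <- spec$size[2]
  area <- spec$fg_fraction_target * H * W
  if (area < 6) stop("fg_fraction_target infeasible for this size", call. = FALSE)
  with_local_seed(spec$seed, {
    # super-ellipse with exponent 2.5: area = 3.381 * a * b
    ab <- area / 3.381
    a <- sqrt(ab * spec$blob_elongation)
    b <- sqrt(ab / spec$blob_elongation)
    if (2 * a > 0.45 * min(H, W))
      stop("fg_fraction_target infeasible for this size", call. = FALSE)
    cy <- runif(1, 0.30 * H, 0.70 * H)
    cx <- runif(1, 0.30 * W, 0.70 * W)
    theta <- runif(1, 0, pi)
    mask <- superellipse_mask(H, W, cy, cx, a, b, theta)
    soft <- gauss_blur(mask * 1, 1.2)
    noise <- matrix(rnorm(H * W), H, W)
    # unsmoothed unit-variance speckle: inside the blob it decorrelates
    # neighboring pixels, spreading the co-occurrence mass away from the
    # diagonal, which is what raises the tumor group's intra-ROI
    # gray-level entropy
    speckle <- matrix(rnorm(H * W), H, W)
    img <- spec$intensity_bg + (spec$intensity_fg - spec$intensity_bg) * soft +
      spec$noise_sd * gauss_blur(noise, 1.2)
    mult <- if (spec$texture_class == "tumor_like") spec$texture_heterogeneity else 1
    if (mult > 1) img <- img + spec$noise_sd * (mult - 1) * speckle * soft
    img <- pmin(pmax(img, 0), 1)
    structure(list(image = img, mask = mask * 1,
                   label = if (spec$texture_class == "tumor_like") "T" else "N",
                   spec = spec),
              class = "axunet_phantom")
  })
}

#' @export
print.axunet_phantom <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<axunet_phantom> %s, %s, fg fraction %.4f\n",
              paste(d, collapse = "x"), x$label, mean(x$mask)))
  invisible(x)
}

#' Generate a pseudo-volume phantom
#'
#' Stacks `n_slices` phantom slices whose blob drifts smoothly (at most
#' about 2 px per slice) and whose axes vary gently, so adjacent-slice
#' masks overlap strongly and [slice_overlay()] extraction is meaningful.
#'
#' @param spec An [phantom_spec()] with `n_slices >= 3`.
#' @return An `axunet_phantom` whose `image` and `mask` are
#'   `(H, W, n_slices)` arrays.
#' @export
make_volume <- function(spec) {
  stopifnot(inherits(spec, "axunet_phantom_spec"))
  if (spec$n_slices < 3L) stop("n_slices must be >= 3", call. = FALSE)
  H <- spec$size[1]; W <- spec$size[2]; S <- spec$n_slices
  area <- spec$fg_fraction_target * H * W
  with_local_seed(spec$seed, {
    ab <- area / 3.381
    a0 <- sqrt(ab * spec$blob_elongation)
    b0 <- sqrt(ab / spec$blob_elongation)
    cy <- runif(1, 0.35 * H, 0.65 * H)
    cx <- runif(1, 0.35 * W, 0.65 * W)
    theta <- runif(1, 0, pi)
    dcy <- runif(1, -1.5, 1.5); dcx <- runif(1, -1.5, 1.5)
    img <- array(0, c(H, W, S)); msk <- array(0, c(H, W, S))
    mid <- (S + 1) / 2
    for (s in seq_len(S)) {
      # gentle through-plane size profile, widest at the middle slice
      scale <- sqrt(pmax(1 - 0.6 * ((s - mid) / mid)^2, 0.3))
      m <- superellipse_mask(H, W, cy + (s - mid) * dcy, cx + (s - mid) * dcx,
                             a0 * scale, b0 * scale, theta)
      soft <- gauss_blur(m * 1, 1.2)
      noise <- gauss_blur(matrix(rnorm(H * W), H, W), 1.2)
      speckle <- matrix(rnorm(H * W), H, W)
      x <- spec$intensity_bg + (spec$intensity_fg - spec$intensity_bg) * soft +
        spec$noise_sd * noise
      mult <- if (spec$texture_class == "tumor_like") spec$texture_heterogeneity else 1
      if (mult > 1) x <- x + spec$noise_sd * (mult - 1) * speckle * soft
      img[, , s] <- pmin(pmax(x, 0), 1)
      msk[, , s] <- m * 1
    }
    structure(list(image = img, mask = msk,
                   label = if (spec$texture_class == "tumor_like") "T" else "N",
                   spec = spec),
              class = "axunet_phantom")
  })
}

#' Generate a two-group phantom cohort
#'
#' `n_normal` phantoms of the `normal` texture class and `n_tumor` of
#' the `tumor_like` class (the published cohort sizes, 13 and 31, are
#' the defaults). Each phantom gets its own RNG stream derived from
#' `(seed, index)` so cohorts are reproducible under any generation
#' order.
#'
#' @param n_normal,n_tumor Group sizes (each >= 1).
#' @param base_spec Template [phantom_spec()]; per-phantom seed and
#'   texture class are overridden.
#' @param seed Master seed.
#' @return A list of `axunet_phantom` objects, normals first.
#' @export
make_cohort <- function(n_normal = 13L, n_tumor = 31L,
                        base_spec = phantom_spec(), seed = 1L) {
  stopifnot(n_normal >= 1L, n_tumor >= 1L)
  classes <- c(rep("normal", n_normal), rep("tumor_like", n_tumor))
  purrr::imap(classes, function(cl, i) {
    sp <- base_spec
    sp$seed <- (as.integer(seed) * 1009L + i * 7919L) %% 2147483629L
    sp$texture_class <- cl
    make_phantom(sp)
  })
}
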