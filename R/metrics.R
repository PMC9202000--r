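## Overlap and boundary metrics for binary segmentation masks. All
## semantics are brute-force verifiable: Dice/Jaccard/precision/recall
## are pixel counts, the Hausdorff distance is the symmetric max-min
## Euclidean distance between boundary point sets.

check_masks <- function(predicted, truth) {
  if (!all(dim(predicted) == dim(truth)))
    stop("mask shapes differ", call. = FALSE)
  if (!all(predicted %in% c(0, 1)) || !all(truth %in% c(0, 1)))
    stop("masks must be binary", call. = FALSE)
  invisible(TRUE)
}

#' Dice similarity coefficient
#'
#' `DSC(Z, Y) = 2 |Z intersect Y| / (|Z| + |Y|)`. Two empty masks count
#' as perfect agreement (1); one empty mask scores 0.
#'
#' @param predicted,truth Binary matrices of identical shape.
#' @return A scalar in `[0, 1]`.
#' @export
dice <- function(predicted, truth) {
  check_masks(predicted, truth)
  sz <- sum(predicted); sy <- sum(truth)
  if (sz + sy == 0) return(1)
  2 * sum(predicted * truth) / (sz + sy)
}

#' Jaccard index
#'
#' `|U intersect V| / |U union V|`; related to Dice by `DSC = 2J/(1+J)`.
#'
#' @inheritParams dice
#' @param strict Error when both masks are empty (otherwise returns 1).
#' @return A scalar in `[0, 1]`.
#' @export
jaccard <- function(predicted, truth, strict = TRUE) {
  check_masks(predicted, truth)
  inter <- sum(predicted * truth)
  uni <- sum(pmax(predicted, truth))
  if (uni == 0) {
    if (strict) stop("both masks empty: Jaccard undefined", call. = FALSE)
    return(1)
  }
  inter / uni
}

#' Pixel-wise precision and recall
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)` counted on foreground
#' pixels. An empty prediction yields `NA` precision (undefined, not a
#' silent zero); an empty truth yields `NA` recall.
#'
#' @inheritParams dice
#' @return Named numeric vector `c(precision =, recall =)`.
#' @export
precision_recall <- function(predicted, truth) {
  check_masks(predicted, truth)
  tp <- sum(predicted * truth)
  fp <- sum(predicted * (1 - truth))
  fn <- sum((1 - predicted) * truth)
  c(precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
    recall = if (tp + fn == 0) NA_real_ else tp / (tp + fn))
}

#' Boundary point set of a binary mask
#'
#' Foreground pixels with at least one background 4-neighbor (pixels on
#' the image border count their out-of-image neighbors as background).
#' This is the documented convention for Hausdorff computation.
#'
#' @param mask Binary matrix.
#' @param spacing Pixel spacing `c(row, col)` used to scale coordinates.
#' @return A two-column matrix of (row, col) coordinates (possibly 0 rows).
#' @export
boundary_points <- function(mask, spacing = c(1, 1)) {
  stopifnot(all(mask %in% c(0, 1)))
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(0, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- mask
  core <- pad[2:(H + 1L), 2:(W + 1L)]
  nb_min <- pmin(pad[1:H, 2:(W + 1L)], pad[3:(H + 2L), 2:(W + 1L)],
                 pad[2:(H + 1L), 1:W], pad[2:(H + 1L), 3:(W + 2L)])
  idx <- which(core == 1 & nb_min == 0, arr.ind = TRUE)
  cbind(idx[, 1] * spacing[1], idx[, 2] * spacing[2])
}

#' Hausdorff distance between two point sets
#'
#' `H(A, B) = max(h(A, B), h(B, A))` with the directed distance
#' `h(A, B) = max_{a in A} min_{b in B} ||a - b||` using Euclidean
#' distances. Both sets must be non-empty.
#'
#' @param a,b Two-column coordinate matrices.
#' @return A non-negative scalar.
#' @export
hausdorff <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) == 0 || nrow(b) == 0)
    stop("Hausdorff distance requires non-empty point sets", call. = FALSE)
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  h_ab <- max(apply(d2, 1, min))  # farthest A point from its nearest B point
  h_ba <- max(apply(d2, 2, min))
  sqrt(max(h_ab, h_ba))
}

#' Hausdorff distance between mask boundaries
#'
#' Convenience wrapper: extracts 4-connectivity boundary point sets from
#' two masks and returns their Hausdorff distance, `NA` when either mask
#' is empty.
#'
#' @inheritParams dice
#' @param spacing Pixel spacing passed to [boundary_points()].
#' @return A non-negative scalar or `NA`.
#' @export
hausdorff_masks <- function(predicted, truth, spacing = c(1, 1)) {
  check_masks(predicted, truth)
  a <- boundary_points(predicted, spacing)
  b <- boundary_points(truth, spacing)
  if (nrow(a) == 0 || nrow(b) == 0) return(NA_real_)
  hausdorff(a, b)
}

#' Evaluate a set of predicted masks
#'
#' Computes Dice, Jaccard, precision, recall and boundary Hausdorff
#' distance per case and returns one row per case plus attributes with
#' mean/sd summaries.
#'
#' @param predicted,truth Lists of binary matrices (same length).
#' @param ids Optional case identifiers.
#' @return A tibble with one row per case.
#' @export
evaluate_masks <- function(predicted, truth, ids = NULL) {
  stopifnot(length(predicted) == length(truth))
  if (is.null(ids)) ids <- seq_along(predicted)
  rows <- purrr::map2(predicted, truth, function(z, y) {
    pr <- precision_recall(z, y)
    tibble::tibble(dice = dice(z, y),
                   jaccard = if (sum(pmax(z, y)) == 0) 1 else jaccard(z, y),
                   precision = pr[["precision"]], recall = pr[["recall"]],
                   hausdorff = hausdorff_masks(z, y))
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::bind_cols(tibble::tibble(id = ids), out)
  class(out) <- c("axunet_eval", class(out))
  out
}

#' @method glance axunet_eval
#' @export
glance.axunet_eval <- function(x, ...) {
  dplyr::summarise(
    tibble::as_tibble(x),
    dplyr::across(c("dice", "jaccard", "precision", "recall", "hausdorff"),
                  list(mean = ~mean(.x, na.rm = TRUE),
                       sd = ~sd(.x, na.rm = TRUE))),
    n = dplyr::n())
}
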