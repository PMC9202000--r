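## Preprocessing, cross-validation, the training/inference harness and
## file I/O. Preprocessing order is fixed — min-max normalize, then
## contrast enhance, then adjacent-slice overlay — and the same code
## path is used at training and prediction time.

#' Min-max normalization
#'
#' Rescales an image to `[0, 1]` by its own minimum and maximum
#' (computed per image, never pooled across a dataset split). A constant
#' image maps to all zeros with a warning.
#'
#' @param image Numeric matrix or array.
#' @return Same shape, values in `[0, 1]`.
#' @export
minmax_normalize <- function(image) {
  rng <- range(image)
  if (rng[2] <= rng[1]) {
    warning("constant image: min-max normalization returns zeros")
    image[] <- 0
    return(image)
  }
  (image - rng[1]) / (rng[2] - rng[1])
}

#' Linear contrast enhancement
#'
#' Stretches intensities about the image mean:
#' `x' = clip(mu + factor * (x - mu), 0, 1)`. `factor = 1` is the
#' identity; the published preprocessing uses `factor = 2.2`.
#'
#' @param image Numeric matrix or array with values in `[0, 1]`.
#' @param factor Positive stretch factor.
#' @return Same shape, values in `[0, 1]`.
#' @export
contrast_enhance <- function(image, factor = 2.2) {
  if (factor <= 0) stop("factor must be positive", call. = FALSE)
  mu <- mean(image)
  pmin(pmax(mu + factor * (image - mu), 0), 1)
}

#' Adjacent-slice overlay
#'
#' Extracts `k` adjacent slices of a volume centered at `index` and
#' stacks them as channels (edge slices are replicated at the volume
#' boundaries), producing the multi-channel input the network consumes.
#'
#' @param volume `(H, W, S)` array.
#' @param index Center slice (1-based).
#' @param k Odd number of channels (default 3).
#' @return `(H, W, k)` array.
#' @export
slice_overlay <- function(volume, index, k = 3L) {
  stopifnot(length(dim(volume)) == 3L)
  if (k %% 2L == 0L) stop("k must be odd", call. = FALSE)
  S <- dim(volume)[3]
  stopifnot(index >= 1L, index <= S)
  r <- (k - 1L) %/% 2L
  sel <- pmin(pmax(index + (-r):r, 1L), S)
  volume[, , sel, drop = FALSE]
}

#' Preprocess a single 2D slice for the network
#'
#' The shared train/predict path: min-max normalize, contrast-enhance,
#' then replicate the slice to the network's channel count (the 2D
#' stand-in for the adjacent-slice overlay).
#'
#' @param image Numeric matrix of raw intensities.
#' @param in_channels Channel count of the network input.
#' @param contrast_factor Passed to [contrast_enhance()].
#' @return An `(H, W, in_channels)` array in `[0, 1]`.
#' @export
preprocess_slice <- function(image, in_channels = 3L, contrast_factor = 2.2) {
  x <- contrast_enhance(minmax_normalize(image), contrast_factor)
  array(rep(x, in_channels), dim = c(dim(x), in_channels))
}

#' Subject-disjoint k-fold split
#'
#' Shuffles subjects with the given seed and deals them into `k` folds
#' whose sizes differ by at most one; every subject lands in exactly one
#' fold.
#'
#' @param subject_ids Vector of unique subject identifiers.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return A tibble with columns `subject` and `fold`.
#' @export
kfold_split <- function(subject_ids, k = 4L, seed = 1L) {
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (anyDuplicated(subject_ids)) stop("subject ids must be unique", call. = FALSE)
  if (length(subject_ids) < k) stop("need at least k subjects", call. = FALSE)
  ord <- with_local_seed(seed, sample(length(subject_ids)))
  tibble::tibble(subject = subject_ids[ord],
                 fold = rep_len(seq_len(k), length(subject_ids))) |>
    dplyr::arrange(.data$subject)
}

# ---- training --------------------------------------------------------------

# shuffled index batches; the caller controls the RNG state
make_batches <- function(n, batch_size) {
  ord <- sample(n)
  split(ord, ceiling(seq_along(ord) / batch_size))
}

#' Train the segmentation network
#'
#' Seeded RMSProp optimization of the hybrid boundary-aware loss with
#' fixed-step learning-rate decay. Per epoch the mean loss (and its
#' contour/focal/Dice components) is recorded; when a validation set is
#' supplied, validation Dice is tracked and the best-scoring weights are
#' restored at the end (and written to `checkpoint_path` when given).
#' A non-finite loss aborts with a diagnostic naming the offending
#' component.
#'
#' @param model An [build_model()] result (modified in place and returned).
#' @param images List of `(H, W, C)` preprocessed input arrays.
#' @param masks List of binary `H x W` ground-truth masks.
#' @param config An [train_config()] object.
#' @param validation Optional `list(images =, masks =)` for per-epoch
#'   validation Dice.
#' @param checkpoint_path Optional path for the final (best) checkpoint.
#' @param verbose Print one line per epoch.
#' @return A list with `model` and `history` (a tibble, class
#'   `axunet_history`).
#' @export
train_model <- function(model, images, masks, config = train_config(),
                        validation = NULL, checkpoint_path = NULL,
                        verbose = FALSE) {
  stopifnot(inherits(model, "axunet_model"),
            inherits(config, "axunet_train_config"),
            length(images) == length(masks), length(images) >= 1L)
  d <- dim(images[[1]])
  H <- d[1]; W <- d[2]
  rms <- lapply(model$params, function(p) {
    s <- ft_shape(p); ft_zeros(s[1], s[2])
  })
  hist <- vector("list", config$epochs)
  best_dice <- -Inf
  best_weights <- NULL
  with_local_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      lr <- config$learning_rate *
        config$lr_decay_factor^((epoch - 1L) %/% config$lr_decay_every)
      batches <- make_batches(length(images), config$batch_size)
      ep <- c(loss = 0, cal = 0, focal = 0, gdl = 0)
      nb <- 0L
      for (ids in batches) {
        B <- length(ids)
        xp <- batch_to_ft(images[ids])
        fw <- model_forward(model, xp, H, W, B, training = TRUE)
        dprob <- matrix(0, 1, B * H * W)
        comp <- c(loss = 0, cal = 0, focal = 0, gdl = 0)
        for (j in seq_len(B)) {
          sel <- ((j - 1) * H * W + 1):(j * H * W)
          pred <- matrix(fw$prob[1, sel], H, W)
          lg <- hybrid_loss_grad(pred, masks[[ids[j]]], config$loss,
                                 config$focal_alpha, config$focal_gamma)
          comp["loss"] <- comp["loss"] + lg$value / B
          comp["cal"] <- comp["cal"] + lg$components["cal"] / B
          comp["focal"] <- comp["focal"] + lg$components["focal"] / B
          comp["gdl"] <- comp["gdl"] + lg$components["gdl"] / B
          dprob[1, sel] <- lg$grad / B
        }
        if (!is.finite(comp[["loss"]])) {
          bad <- names(comp)[!is.finite(comp) & !is.na(comp)]
          stop(sprintf("non-finite training loss at epoch %d (component: %s)",
                       epoch, paste(setdiff(bad, "loss"), collapse = ", ")),
               call. = FALSE)
        }
        grads <- model_backward(model, fw$tape, dprob)
        for (nm in names(grads))
          rmsprop_step(model$params[[nm]], grads[[nm]], rms[[nm]],
                       lr, 0.9, 1e-8)
        ep <- ep + comp
        nb <- nb + 1L
        rm(fw, grads, xp)
        if (nb %% 4L == 0L) gc(verbose = FALSE)
      }
      ep <- ep / nb
      val_dice <- NA_real_
      if (!is.null(validation)) {
        probs <- infer_prob(model, validation$images)
        ds <- purrr::map2_dbl(probs, validation$masks,
                              function(p, m) dice((p >= 0.5) * 1, m))
        val_dice <- mean(ds)
        if (val_dice >= best_dice) {
          best_dice <- val_dice
          best_weights <- get_weights(model)
        }
      }
      hist[[epoch]] <- tibble::tibble(
        epoch = epoch, lr = lr, loss = ep[["loss"]], cal = ep[["cal"]],
        focal = ep[["focal"]], gdl = ep[["gdl"]], val_dice = val_dice)
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  val dice %s", epoch, ep[["loss"]],
                        ifelse(is.na(val_dice), "-", sprintf("%.3f", val_dice))))
      gc(verbose = FALSE)
    }
  })
  if (!is.null(best_weights)) set_weights(model, best_weights)
  if (!is.null(checkpoint_path)) save_checkpoint(model, checkpoint_path)
  history <- dplyr::bind_rows(hist)
  class(history) <- c("axunet_history", class(history))
  list(model = model, history = history)
}

#' Predict a binary mask
#'
#' Applies the shared preprocessing (min-max normalization, contrast
#' enhancement, channel overlay), pads the image to the nearest multiple
#' of `2^depth` when necessary (cropping back afterwards), and thresholds
#' the softmax foreground probability. Volumes are processed per slice
#' with adjacent-slice overlays.
#'
#' @param object An `axunet_model`.
#' @param image A 2D matrix or `(H, W, S)` volume of raw intensities.
#' @param threshold Probability threshold (default 0.5).
#' @param contrast_factor Preprocessing contrast factor.
#' @param ... Unused.
#' @return A binary mask of the input's spatial shape.
#' @export
predict.axunet_model <- function(object, image, threshold = 0.5,
                                 contrast_factor = 2.2, ...) {
  cfg <- object$config
  if (length(dim(image)) == 3L) {
    S <- dim(image)[3]
    out <- array(0, dim(image))
    vol <- contrast_enhance(minmax_normalize(image), contrast_factor)
    for (s in seq_len(S)) {
      ov <- slice_overlay(vol, s, cfg$in_channels)
      out[, , s] <- predict_prepared(object, ov, threshold)
    }
    return(out)
  }
  x <- preprocess_slice(image, cfg$in_channels, contrast_factor)
  predict_prepared(object, x, threshold)
}

predict_prepared <- function(model, x, threshold) {
  cfg <- model$config
  d <- dim(x)
  div <- 2L^cfg$depth
  Hp <- div * ((d[1] + div - 1L) %/% div)
  Wp <- div * ((d[2] + div - 1L) %/% div)
  padded <- !(Hp == d[1] && Wp == d[2])
  if (padded) {
    message(sprintf("padding input %dx%d to %dx%d for depth %d",
                    d[1], d[2], Hp, Wp, cfg$depth))
    xp <- array(0, c(Hp, Wp, d[3]))
    xp[seq_len(d[1]), seq_len(d[2]), ] <- x
    x <- xp
  }
  p <- infer_prob(model, list(x))[[1]]
  if (padded) p <- p[seq_len(d[1]), seq_len(d[2]), drop = FALSE]
  (p >= threshold) * 1
}

#' @method glance axunet_history
#' @export
glance.axunet_history <- function(x, ...) {
  tibble::tibble(epochs = max(x$epoch), final_loss = x$loss[which.max(x$epoch)],
                 best_val_dice = suppressWarnings(max(x$val_dice, na.rm = TRUE)))
}

# ---- file I/O --------------------------------------------------------------

#' Read and write images and masks
#'
#' PNG I/O is 8-bit grayscale; NIfTI I/O keeps floating-point
#' intensities. Masks are written as 0/1.
#'
#' @param path File path (`.png`, `.nii` or `.nii.gz`).
#' @param image Matrix (PNG) or array (NIfTI) of values in `[0, 1]`.
#' @return `read_image()` returns a matrix or array.
#' @export
write_image <- function(image, path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(t(image)[, , drop = FALSE], path)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    RNifti::writeNifti(RNifti::asNifti(image), path)
  } else stop("unsupported image format: ", path, call. = FALSE)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    x <- png::readPNG(path)
    if (length(dim(x)) == 3L) x <- x[, , 1]
    t(x)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    x <- RNifti::readNifti(path)
    array(as.numeric(x), dim = dim(x))
  } else stop("unsupported image format: ", path, call. = FALSE)
}

#' Write a phantom dataset with manifest
#'
#' Writes paired image/mask PNGs (or NIfTI for volumes) plus a manifest
#' CSV with columns `image`, `mask`, `label`, `seed`.
#'
#' @param phantoms List of `axunet_phantom` objects.
#' @param dir Output directory (created if needed).
#' @param format `"png"` or `"nifti"`.
#' @return The manifest tibble, invisibly.
#' @export
write_phantom_set <- function(phantoms, dir, format = c("png", "nifti")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "png") "png" else "nii.gz"
  rows <- purrr::imap(phantoms, function(ph, i) {
    ip <- file.path(dir, sprintf("phantom_%03d_image.%s", i, ext))
    mp <- file.path(dir, sprintf("phantom_%03d_mask.%s", i, ext))
    write_image(ph$image, ip)
    write_image(ph$mask, mp)
    tibble::tibble(image = ip, mask = mp, label = ph$label, seed = ph$spec$seed)
  })
  manifest <- dplyr::bind_rows(rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
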