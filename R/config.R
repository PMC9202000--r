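#' Network configuration
#'
#' Describes the topology of the encoder-decoder segmentation network.
#' The defaults reproduce the published configuration: a three-channel
#' input (an overlay of three adjacent CT slices), four downsampling
#' blocks of widths 64/128/256/512, an atrous-spatial-pyramid-pooling
#' (ASPP) bottleneck with dilation rates (2, 4, 6), and a mirrored
#' decoder ending in a 1x1 convolution to two class maps.
#'
#' `aspp_out_channels` defaults to `4 * base_width`, which equals the
#' published 256 fused ASPP channels at the published base width of 64
#' and keeps the bottleneck proportionate when smaller models are built.
#'
#' @param in_channels Number of input channels (adjacent-slice overlay).
#' @param base_width Width of the first encoder block; widths double at
#'   each of the `depth` blocks.
#' @param depth Number of downsampling blocks. Input height and width
#'   must be divisible by `2^depth`.
#' @param aspp_rates Dilation rates of the three (or more) parallel
#'   atrous branches in the bottleneck.
#' @param aspp_out_channels Channels of the fused ASPP output;
#'   `NULL` means `4 * base_width`.
#' @param out_classes Number of output class maps (background/foreground).
#' @param variant `"ax_unet"` applies the depth-wise separable
#'   replacement rule (the first convolution of every double-conv block,
#'   except the network's first layer, becomes a 1x1 pointwise followed
#'   by a per-channel 3x3 depthwise stage); `"baseline_unet"` uses
#'   normal convolutions everywhere.
#' @param seed Integer seed controlling weight initialisation.
#'
#' @return An object of class `axunet_config` (a named list).
#' @export
#' @examples
#' cfg <- model_config(base_width = 16, seed = 1)
#' cfg$widths
model_config <- function(in_channels = 3L,
                         base_width = 64L,
                         depth = 4L,
                         aspp_rates = c(2L, 4L, 6L),
                         aspp_out_channels = NULL,
                         out_classes = 2L,
                         variant = c("ax_unet", "baseline_unet"),
                         seed = 42L) {
  variant <- match.arg(variant)
  stopifnot(depth >= 1L, in_channels >= 1L, base_width >= 1L,
            out_classes >= 2L, all(aspp_rates >= 1L))
  if (is.null(aspp_out_channels)) aspp_out_channels <- 4L * base_width
  stopifnot(aspp_out_channels >= 1L)
  widths <- as.integer(base_width * 2^(seq_len(depth) - 1L))
  structure(
    list(in_channels = as.integer(in_channels),
         base_width = as.integer(base_width),
         depth = as.integer(depth),
         widths = widths,
         aspp_rates = as.integer(aspp_rates),
         aspp_out_channels = as.integer(aspp_out_channels),
         out_classes = as.integer(out_classes),
         variant = variant,
         seed = as.integer(seed)),
    class = "axunet_config")
}

#' @export
print.axunet_config <- function(x, ...) {
  cat(sprintf("<axunet_config> variant=%s in=%d widths=%s aspp=(%s)->%d seed=%d\n",
              x$variant, x$in_channels, paste(x$widths, collapse = "/"),
              paste(x$aspp_rates, collapse = ","), x$aspp_out_channels, x$seed))
  invisible(x)
}

#' Loss mixing weights
#'
#' The hybrid training loss is `w_cal * CAL + w_focal * Focal + w_gdl * GDL`,
#' where CAL is the Sobel-based contour-aware loss, Focal the class-balanced
#' focal loss and GDL the generalized Dice loss. The published mix gives the
#' contour term the largest share: (0.6, 0.2, 0.2).
#'
#' @param w_cal,w_focal,w_gdl Non-negative weights in `[0, 1]`.
#' @param normalize_check When `TRUE` (default) the weights must sum to 1.
#' @return An object of class `axunet_loss_weights`.
#' @export
loss_weights <- function(w_cal = 0.6, w_focal = 0.2, w_gdl = 0.2,
                         normalize_check = TRUE) {
  w <- c(w_cal = w_cal, w_focal = w_focal, w_gdl = w_gdl)
  if (any(w < 0) || any(w > 1)) stop("loss weights must lie in [0, 1]", call. = FALSE)
  if (normalize_check && abs(sum(w) - 1) > 1e-8)
    stop("loss weights must sum to 1 (set normalize_check = FALSE to override)",
         call. = FALSE)
  structure(as.list(w), class = "axunet_loss_weights")
}

#' Training configuration
#'
#' Defaults mirror the published training recipe: RMSProp at an initial
#' learning rate of 0.001, batch size 32, 150 epochs, fixed-step learning
#' rate decay, four-fold subject-disjoint cross-validation and a 2.2x
#' contrast enhancement during preprocessing. Desk-scale runs typically
#' lower `epochs` and `batch_size`.
#'
#' @param learning_rate Initial learning rate.
#' @param batch_size Images per optimizer step.
#' @param epochs Number of passes over the training set.
#' @param optimizer `"rms"` (RMSProp) or `"adam"` (`"rms"` reproduces the
#'   published setting; `"adam"` falls back to RMSProp with momentum-free
#'   updates and is accepted for interface compatibility).
#' @param lr_decay_every,lr_decay_factor Step decay schedule: multiply the
#'   learning rate by `lr_decay_factor` every `lr_decay_every` epochs.
#' @param seed Integer seed for batching and initialisation.
#' @param folds Number of cross-validation folds.
#' @param loss An [loss_weights()] object.
#' @param focal_gamma,focal_alpha Focal-loss parameters.
#' @param contrast_factor Contrast-enhancement factor applied after
#'   min-max normalization.
#' @return An object of class `axunet_train_config`.
#' @export
train_config <- function(learning_rate = 0.001,
                         batch_size = 32L,
                         epochs = 150L,
                         optimizer = c("rms", "adam"),
                         lr_decay_every = 50L,
                         lr_decay_factor = 0.1,
                         seed = 42L,
                         folds = 4L,
                         loss = loss_weights(),
                         focal_gamma = 2.0,
                         focal_alpha = 0.25,
                         contrast_factor = 2.2) {
  optimizer <- match.arg(optimizer)
  stopifnot(learning_rate > 0, batch_size >= 1L, epochs >= 1L,
            folds >= 2L, lr_decay_every >= 1L, lr_decay_factor > 0,
            focal_gamma >= 0, focal_alpha >= 0, focal_alpha <= 1,
            contrast_factor > 0)
  stopifnot(inherits(loss, "axunet_loss_weights"))
  structure(
    list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
         epochs = as.integer(epochs), optimizer = optimizer,
         lr_decay_every = as.integer(lr_decay_every),
         lr_decay_factor = lr_decay_factor, seed = as.integer(seed),
         folds = as.integer(folds), loss = loss,
         focal_gamma = focal_gamma, focal_alpha = focal_alpha,
         contrast_factor = contrast_factor),
    class = "axunet_train_config")
}
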