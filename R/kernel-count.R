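## 3x3-kernel accounting for the encoder-decoder double-convolution path.
## A normal 3x3 convolution M -> N holds M*N kernel planes of size 3x3;
## a depth-wise separable replacement holds one 3x3 kernel per channel
## entering its depthwise stage (the pointwise 1x1 stage contributes no
## 3x3 kernels). The ledger covers the double-conv blocks of encoder and
## decoder; 1x1 fusions, projections, upsampling kernels and the ASPP
## bottleneck are outside the published accounting and are not counted.

# One row per 3x3-capable convolution in the double-conv path, in
# execution order. Shared by the ledger and by the model builder so the
# two can never drift apart.
conv_plan <- function(config) {
  stopifnot(inherits(config, "axunet_config"))
  w <- config$widths
  cin <- c(config$in_channels, w)
  enc <- purrr::map_dfr(seq_len(config$depth), function(i) {
    tibble::tibble(stage = "encoder", block = i, conv = c("a", "b"),
                   M = c(cin[i], w[i]), N = c(w[i], w[i]))
  })
  dec <- purrr::map_dfr(rev(seq_len(config$depth)), function(i) {
    tibble::tibble(stage = "decoder", block = i, conv = c("a", "b"),
                   M = c(w[i], w[i]), N = c(w[i], cin[i]))
  })
  plan <- dplyr::bind_rows(enc, dec)
  first_layer <- plan$stage == "encoder" & plan$block == 1L & plan$conv == "a"
  plan$kind <- ifelse(
    config$variant == "ax_unet" & plan$conv == "a" & !first_layer,
    "depthwise", "normal")
  plan
}

#' Count the 3x3 convolution kernels of a configuration
#'
#' Enumerates every convolution of the encoder and decoder double-conv
#' blocks and counts its 3x3 kernel planes: a normal convolution from
#' `M` to `N` channels contributes `M * N`, a depth-wise separable stage
#' contributes one kernel per channel it convolves, and 1x1 convolutions
#' contribute zero. For the default topology (3-channel input, widths
#' 64/128/256/512, mirrored decoder) the baseline variant totals exactly
#' 1,040,768 kernels.
#'
#' @param config An [model_config()] object.
#' @return An object of class `axunet_kernel_report`: a list with the
#'   per-convolution `ledger` tibble and the `total_3x3_kernels`.
#' @export
#' @examples
#' count_3x3_kernels(model_config(variant = "baseline_unet"))$total_3x3_kernels
count_3x3_kernels <- function(config) {
  plan <- conv_plan(config)
  plan$kernels <- ifelse(plan$kind == "normal", plan$M * plan$N, plan$N)
  structure(list(variant = config$variant, ledger = plan,
                 total_3x3_kernels = sum(plan$kernels)),
            class = "axunet_kernel_report")
}

#' @export
print.axunet_kernel_report <- function(x, ...) {
  cat(sprintf("<axunet_kernel_report> variant=%s convolutions=%d total 3x3 kernels=%s\n",
              x$variant, nrow(x$ledger),
              format(x$total_3x3_kernels, big.mark = ",")))
  invisible(x)
}

#' @method tidy axunet_kernel_report
#' @export
tidy.axunet_kernel_report <- function(x, ...) x$ledger
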