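## ggplot2 display methods for the package's result types.

raster_df <- function(m) {
  tibble::tibble(row = rep(seq_len(nrow(m)), ncol(m)),
                 col = rep(seq_len(ncol(m)), each = nrow(m)),
                 value = as.vector(m))
}

#' Plot a grayscale image matrix
#'
#' @param m Numeric matrix.
#' @param title Optional title.
#' @return A ggplot object.
#' @export
plot_image <- function(m, title = NULL) {
  ggplot2::ggplot(raster_df(m), ggplot2::aes(.data$col, .data$row,
                                             fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method autoplot axunet_phantom
#' @export
autoplot.axunet_phantom <- function(object, ...) {
  df <- raster_df(if (length(dim(object$image)) == 3L)
    object$image[, , (dim(object$image)[3] + 1) %/% 2] else object$image)
  mk <- raster_df(if (length(dim(object$mask)) == 3L)
    object$mask[, , (dim(object$mask)[3] + 1) %/% 2] else object$mask)
  df$mask <- mk$value
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$mask), breaks = 0.5,
                          colour = "red", linewidth = 0.3) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("phantom (%s)", object$label),
                  x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot axunet_history
#' @export
autoplot.axunet_history <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "epoch", "loss", "cal",
                  "focal", "gdl"),
    -"epoch", names_to = "component", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$value,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss") +
    ggplot2::theme_minimal()
}

#' @method autoplot axunet_stat_report
#' @export
autoplot.axunet_stat_report <- function(object, features = NULL, ...) {
  long <- tidyr::pivot_longer(object$features, -"group",
                              names_to = "feature", values_to = "value")
  if (!is.null(features)) long <- dplyr::filter(long, .data$feature %in% features)
  ggplot2::ggplot(long, ggplot2::aes(.data$group, .data$value,
                                     fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, show.legend = FALSE) +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
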