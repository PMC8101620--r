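#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Scatter plot of an accuracy calibration
#'
#' CT versus reference values with the fitted calibration line and the
#' identity line.
#'
#' @param object an `accuracy_calibration`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot accuracy_calibration
#' @export
autoplot.accuracy_calibration <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$ct,
                                            y = .data$reference)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(intercept = object$intercept,
                         slope = object$slope, color = "steelblue") +
    ggplot2::geom_abline(intercept = 0, slope = 1, linetype = "dashed",
                         color = "grey50") +
    ggplot2::labs(x = "CT-derived value", y = "Reference value",
                  subtitle = sprintf("r = %.3f, n = %d", object$r,
                                     object$n)) +
    ggplot2::theme_minimal()
}

#' Effect-size dot plot for a group comparison
#'
#' @param object a `group_comparison` or `adjusted_comparison` tibble.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot group_comparison
#' @export
autoplot.group_comparison <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$effect_size,
                                       y = .data$measure)) +
    ggplot2::geom_vline(xintercept = 0, color = "grey70") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Effect size (Cohen's d)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot adjusted_comparison
#' @export
autoplot.adjusted_comparison <- function(object, ...) {
  autoplot.group_comparison(object, ...)
}

#' Axial slice plot of a volume with optional ROI overlay
#'
#' @param v a `density_volume` or `membership_volume`.
#' @param slice axial slice index.
#' @param roi optional `roi_mask` overlay.
#' @return A ggplot object.
#' @export
plot_slice <- function(v, slice, roi = NULL) {
  vals <- v$values[, , slice]
  df <- tidyr::expand_grid(x = seq_len(nrow(vals)), y = seq_len(ncol(vals)))
  df$value <- as.vector(vals)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
  if (!is.null(roi)) {
    rdf <- df
    rdf$in_roi <- as.vector(roi$mask[, , slice])
    p <- p + ggplot2::geom_raster(
      data = rdf[rdf$in_roi, ], fill = "red", alpha = 0.35)
  }
  p
}
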