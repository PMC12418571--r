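#' Plot an overlap series
#'
#' Median TD_VVO and STS_VVO over time with the default quality cutoffs
#' (90 / 80 / 55%) as reference lines.
#'
#' @param object A `vvo_series` from [compute_vvo()].
#' @param thresholds Horizontal reference lines, percent.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot vvo_series
#' @export
autoplot.vvo_series <- function(object, thresholds = c(90, 80, 55), ...) {
  long <- tidyr::pivot_longer(
    object[c("volume", "td_vvo_median", "sts_vvo_median")],
    cols = -"volume", names_to = "measure", values_to = "overlap"
  )
  long$measure <- factor(long$measure,
                         levels = c("td_vvo_median", "sts_vvo_median"),
                         labels = c("TD_VVO (median)", "STS_VVO (median)"))
  ggplot2::ggplot(long, ggplot2::aes(.data$volume, .data$overlap,
                                     colour = .data$measure)) +
    ggplot2::geom_hline(yintercept = thresholds, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 100)) +
    ggplot2::labs(x = "volume", y = "voxel volume overlap [%]",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.vvo_series
#' @param vvo A `vvo_series`.
#' @export
plot_vvo <- function(vvo, thresholds = c(90, 80, 55)) {
  autoplot.vvo_series(vvo, thresholds = thresholds)
}

#' Plot a calibration fit
#'
#' Scatter of the windowed (STS, STS_VVO) pairs with the constrained line
#' `overlap = 100 - a * STS`.
#'
#' @param object A `vvo_calibration` from [fit_constrained()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot vvo_calibration
#' @export
autoplot.vvo_calibration <- function(object, ...) {
  p <- ggplot2::ggplot(object$data,
                       ggplot2::aes(.data$sts, .data$sts_vvo)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = "STS [mm]", y = "STS_VVO [%]") +
    ggplot2::theme_minimal()
  if (object$included) {
    p <- p + ggplot2::geom_abline(intercept = 100, slope = -object$a,
                                  colour = "firebrick")
  }
  p
}

#' @rdname autoplot.vvo_calibration
#' @param fit A `vvo_calibration`.
#' @export
plot_calibration <- function(fit) {
  autoplot.vvo_calibration(fit)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
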