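# ggplot2 views of traces and fits.

#' Plot a color trace
#'
#' Delta E (or any other trace column) against time, colored by ROI.
#'
#' @param object A `color_trace`.
#' @param metric Column to plot (default `"delta_e"`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.color_trace <- function(object, metric = "delta_e", ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data[[metric]],
                                       color = .data$roi)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)",
                  y = if (metric == "delta_e") expression(Delta * E) else metric,
                  color = "ROI") +
    ggplot2::theme_minimal()
}

#' Plot a texture trace
#'
#' Contact and GLCM features over time, one facet per metric.
#'
#' @param object A `texture_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.texture_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              c("contact", "asm", "entropy", "homogeneity"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value,
                                     color = .data$roi)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL, color = "ROI") +
    ggplot2::theme_minimal()
}

#' Plot a rate fit over its data
#'
#' @param object A `rate_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rate_fit <- function(object, ...) {
  dat <- tibble(t = object$data$tt, delta_e = object$data$y)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$t, y = .data$delta_e)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = "time (s)", y = expression(Delta * E),
                  title = sprintf("%s fit%s", object$model,
                                  if (object$converged)
                                    sprintf(": k = %.4g", object$k) else " (not converged)")) +
    ggplot2::theme_minimal()
  if (object$converged) {
    tt <- seq(min(dat$t), max(dat$t), length.out = 200)
    f <- fractional_conversion(tt, object$model, object$k)
    p <- p + ggplot2::geom_line(data = tibble(t = tt, delta_e = object$amplitude * f),
                                color = "firebrick")
  }
  p
}
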