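# ggplot2 figure builders for the main result types.

#' Plot a force-clamp trace
#'
#' Exited length (or raw extension) versus time.
#'
#' @param trace A trace tibble.
#' @param params An [elastic_params()]; when supplied the exited-length
#'   series is shown, otherwise raw extension.
#' @return A ggplot object.
#' @export
plot_trace <- function(trace, params = elastic_params()) {
  s <- exited_length_series(trace, params)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$time_s, y = .data$exited_bp / 1000)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "DNA exited (kb)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.velocity_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_center,
                                       y = .data$mean_velocity)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_velocity - .data$se,
      ymax = .data$mean_velocity + .data$se)) +
    ggplot2::geom_line(linetype = 2, linewidth = 0.3) +
    ggplot2::scale_y_log10() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "capsid filling (%)", y = "exit velocity (bp/s)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.powerlaw_fit <- function(object, values = NULL, ...) {
  if (is.null(values)) {
    rlang::abort("supply the fitted sample via `values` to plot the CCDF")
  }
  cc <- ccdf(values)
  tail_x <- seq(object$xmin, max(values), length.out = 100)
  p_at_xmin <- mean(values >= object$xmin)
  fit_line <- tibble::tibble(
    t = tail_x,
    p = p_at_xmin * (tail_x / object$xmin)^(1 - object$alpha))
  ggplot2::ggplot(cc, ggplot2::aes(x = .data$t, y = .data$p_plot)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_line(data = fit_line, ggplot2::aes(y = .data$p),
                       colour = "red") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "pause duration t (s)", y = "P(T > t)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pt_fit <- function(object, ...) {
  ggplot2::ggplot(object$per_bin, ggplot2::aes(x = .data$bin_center,
                                               y = .data$d_nm)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$d_overall, linetype = 2) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "capsid filling (%)", y = "fitted d (nm)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
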