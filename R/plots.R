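# ggplot2 autoplot methods: kymographs, learning curves, weight histograms.

#' Kymograph of simulated muscle activity
#'
#' Muscle cell (head to tail within each row) against time, coloured by
#' activation; command switches drawn as horizontal lines.
#'
#' @param object A `trajectory`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.trajectory <- function(object, ...) {
  df <- tidy(object)
  sw <- object$schedule$switch_times[-1]
  ggplot2::ggplot(df, ggplot2::aes(.data$segment, .data$time,
                                   fill = .data$activity)) +
    ggplot2::geom_raster() +
    ggplot2::facet_grid(. ~ row) +
    ggplot2::geom_hline(yintercept = sw, linewidth = 0.2,
                        colour = "white") +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "muscle segment (head → tail)", y = "time [s]",
                  fill = "y") +
    ggplot2::theme_minimal()
}

#' Kymograph of teacher data
#' @param object A `teacher_data`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.teacher_data <- function(object, ...) {
  df <- tidy(object)
  sw <- object$schedule$switch_times[-1]
  ggplot2::ggplot(df, ggplot2::aes(.data$segment, .data$time,
                                   fill = .data$target)) +
    ggplot2::geom_raster() +
    ggplot2::facet_grid(. ~ row) +
    ggplot2::geom_hline(yintercept = sw, linewidth = 0.2,
                        colour = "white") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "muscle segment (head → tail)", y = "time [s]",
                  fill = "d") +
    ggplot2::theme_minimal()
}

#' Learning curve
#' @param object A `train_result`.
#' @param ... Unused.
#' @return A ggplot of E against iteration (log scale), with the
#'   termination tolerance as a dashed line.
#' @export
autoplot.train_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$iteration, .data$E)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$config$tolerance,
                        linetype = "dashed", colour = "red") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "evaluation function E") +
    ggplot2::theme_minimal()
}

#' Weight-strength histogram with optional Boltzmann fit
#' @param object A `weight_histogram`.
#' @param fit Optional `boltzmann_fit` to overlay.
#' @param ... Unused.
#' @return A ggplot: per-trial frequencies as points, mean as crosses, the
#'   fitted modified Boltzmann curve as a line.
#' @export
autoplot.weight_histogram <- function(object, fit = NULL, ...) {
  df <- tidy(object)
  gg <- ggplot2::ggplot(df, ggplot2::aes(.data$center, .data$count)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$trial)),
                        alpha = 0.6) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean_freq), shape = 3,
                        size = 2) +
    ggplot2::labs(x = paste(object$source, "strength |w|"),
                  y = "frequency", colour = "trial") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    gg <- gg + ggplot2::geom_line(
      data = dplyr::rename(fit$data, count = "fitted"),
      colour = "darkgreen")
  }
  gg
}
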