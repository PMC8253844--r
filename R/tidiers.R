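# broom-style tidiers: every result type flattens to a tibble.

#' Tidy a trajectory into long format
#'
#' @param x A `trajectory`.
#' @param cells `"muscles"` or `"neurons"`.
#' @param ... Unused.
#' @return Tibble with `time`, `cell`, `row`/`class`, `segment`, `activity`.
#' @export
tidy.trajectory <- function(x, cells = c("muscles", "neurons"), ...) {
  cells <- match.arg(cells)
  if (cells == "muscles") {
    tibble(
      time = rep(x$times, times = ncol(x$y_m)),
      cell = rep(colnames(x$y_m), each = nrow(x$y_m)),
      row = rep(x$map$muscle_row, each = nrow(x$y_m)),
      segment = rep(x$map$muscle_segment, each = nrow(x$y_m)),
      activity = as.numeric(x$y_m)
    )
  } else {
    tibble(
      time = rep(x$times, times = ncol(x$y_n)),
      cell = rep(colnames(x$y_n), each = nrow(x$y_n)),
      class = rep(x$map$neuron_class, each = nrow(x$y_n)),
      activity = as.numeric(x$y_n)
    )
  }
}

#' Tidy teacher data into long format
#' @param x A `teacher_data`.
#' @param ... Unused.
#' @return Tibble with `time`, `cell`, `row`, `segment`, `target`.
#' @export
tidy.teacher_data <- function(x, ...) {
  tibble(
    time = rep(x$times, times = ncol(x$d)),
    cell = rep(colnames(x$d), each = nrow(x$d)),
    row = rep(x$map$muscle_row, each = nrow(x$d)),
    segment = rep(x$map$muscle_segment, each = nrow(x$d)),
    target = as.numeric(x$d)
  )
}

#' Tidy a training result (learning curve)
#' @param x A `train_result`.
#' @param ... Unused.
#' @return Tibble with `iteration` and `E`.
#' @export
tidy.train_result <- function(x, ...) {
  tibble(iteration = seq_along(x$learning_curve), E = x$learning_curve)
}

#' One-row summary of a training result
#' @param x A `train_result`.
#' @param ... Unused.
#' @return Tibble with residuals, iteration count and convergence flag.
#' @export
glance.train_result <- function(x, ...) {
  tibble(
    pre_E = x$residuals$pre, final_E = x$final_E,
    verification_E = x$residuals$verification,
    iterations = x$iterations_used, converged = x$converged
  )
}

#' Tidy a weight histogram
#' @param x A `weight_histogram`.
#' @param ... Unused.
#' @return Per-trial bin counts with bin centers and the cross-trial mean.
#' @export
tidy.weight_histogram <- function(x, ...) {
  left_join(x$freq,
            tibble(bin = seq_along(x$centers), mean_freq = x$mean_freq),
            by = "bin")
}

#' Tidy a modified-Boltzmann fit
#' @param x A `boltzmann_fit`.
#' @param ... Unused.
#' @return Tibble of parameter estimates (term / estimate).
#' @export
tidy.boltzmann_fit <- function(x, ...) {
  tibble(term = c("A", "a", "beta", "n", "C", "lambda"),
         estimate = c(x$A, x$a, x$beta, x$n, x$C, x$lambda))
}

#' One-row summary of a modified-Boltzmann fit
#' @param x A `boltzmann_fit`.
#' @param ... Unused.
#' @return Tibble with `r_squared`, `fit_pvalue`, `n`, `source`.
#' @export
glance.boltzmann_fit <- function(x, ...) {
  tibble(r_squared = x$r_squared, fit_pvalue = x$fit_pvalue, n = x$n,
         source = x$source, converged = x$converged)
}

#' Tidy a residual summary
#' @param x A `residual_summary`.
#' @param ... Unused.
#' @return The per-trial tibble.
#' @export
tidy.residual_summary <- function(x, ...) x$trials

#' @rdname tidy.residual_summary
#' @export
glance.residual_summary <- function(x, ...) x$summary
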