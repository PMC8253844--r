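# Teacher data: target muscle-activation matrices d_u(t).
#
# Two generators: an analytic travelling sine wave with phase reversal at
# every command switch, and an emulator of a muscle-calcium fluorescence
# recording (per-segment dorsal/ventral traces -> dF/F0 rates -> sum-of-sines
# smoothing -> concatenation -> [0.25, 0.75] normalization).

new_teacher_data <- function(d, times, schedule, provenance, omega, map,
                             range) {
  structure(
    list(d = d, times = times, schedule = schedule, provenance = provenance,
         omega = omega, map = map, range = range),
    class = "teacher_data"
  )
}

#' @export
print.teacher_data <- function(x, ...) {
  cat("<teacher_data> ", nrow(x$d), " steps x ", ncol(x$d), " muscles, ",
      x$provenance, ", omega = ", signif(x$omega, 4), " rad/s, range [",
      x$range[1], ", ", x$range[2], "]\n", sep = "")
  invisible(x)
}

# phase per (epoch, segment): epoch 1 phase is -2*pi*q/n_segments (for the
# full-size map, -pi*q/12); at each later switch T_v the phase becomes
# pi - 2*omega*T_v - phi_previous, which reverses the propagation direction
# while keeping the wave continuous in value.
phase_table <- function(schedule, omega, n_segments) {
  q <- seq_len(n_segments)
  st <- schedule$switch_times
  phi <- matrix(NA_real_, length(st), n_segments)
  phi[1, ] <- -2 * pi * q / n_segments
  if (length(st) > 1) {
    for (v in 2:length(st)) {
      phi[v, ] <- pi - 2 * omega * st[v] - phi[v - 1, ]
    }
  }
  phi
}

#' Analytic travelling-wave teacher
#'
#' Target muscle activations: dorsal rows follow
#' `sin(omega * t + phi_q(t))`, ventral rows `sin(omega * t - pi + phi_q(t))`
#' (dorsal/ventral antiphase), where the initial phase `-2*pi*q/n_segments`
#' decreases head to tail (one body wavelength) so the wave travels from head
#' to tail; at every command switch the phase is replaced by
#' `pi - 2*omega*T_v - phi`, which time-reverses the wave (tail-to-head
#' propagation for backward epochs) without a jump in value.  The raw sine is
#' affinely rescaled from `[-1, 1]` to `range`, so a sigmoidal muscle output
#' can attain the target.  Left and right rows are identical.
#'
#' @param schedule A [command_schedule()].
#' @param omega Angular frequency in rad/s (default `1.6 * pi`).
#' @param Fs Step duration in seconds (default 0.05).
#' @param map A [neuron_index_map()].
#' @param range Output range (default `c(0.25, 0.75)`).
#' @return A `teacher_data` object; `$d` is a `T_steps x n_muscles` matrix on
#'   the time grid `Fs * (1:T_steps)`.
#' @export
analytic_teacher <- function(schedule, omega = 1.6 * pi, Fs = 0.05,
                             map = neuron_index_map(),
                             range = c(0.25, 0.75)) {
  n_steps <- round(schedule$total_time / Fs)
  times <- Fs * seq_len(n_steps)
  phi <- phase_table(schedule, omega, map$n_segments)
  v <- pmax(epoch_of(times, schedule), 1L)   # t = T includes last epoch
  q <- map$muscle_segment
  dorsal <- substr(map$muscle_row, 2, 2) == "D"

  # raw[t, u] = sin(omega t + phi_{v(t), q(u)} + (0 dorsal | -pi ventral))
  phase_tu <- phi[cbind(rep(v, times = length(q)),
                        rep(q, each = length(times)))]
  offset <- ifelse(dorsal, 0, -pi)
  raw <- sin(outer(omega * times, offset, "+") +
               matrix(phase_tu, nrow = length(times)))
  mid <- mean(range); half <- diff(range) / 2
  d <- mid + half * raw
  colnames(d) <- map$muscle_name
  new_teacher_data(d, times, schedule, "analytic", omega, map, range)
}

#' Fluorescence rate (dF/F0)
#'
#' Converts raw fluorescence intensities to rates
#' `R = (F - F0) / F0`, where `F0` is the per-trace minimum intensity, so the
#' minimum of every output series is exactly 0.
#'
#' @param trace Numeric vector, or matrix with one series per column.
#' @return Same shape as `trace`.
#' @export
fluorescence_rate <- function(trace) {
  rate1 <- function(f) {
    f0 <- min(f)
    if (f0 <= 0) abort("fluorescence baseline F0 must be positive.")
    (f - f0) / f0
  }
  if (is.matrix(trace)) apply(trace, 2, rate1) else rate1(trace)
}

# ---------------------------------------------------------------------------
# Sum-of-sines smoothing

# top-n spectral peak frequencies (rad/s) of a demeaned series
spectral_peaks <- function(x, dt, n) {
  x <- x - mean(x)
  m <- length(x)
  p <- Mod(fft(x))[seq_len(floor(m / 2))]
  freq <- 2 * pi * (seq_along(p) - 1) / (m * dt)
  p[1] <- 0                                   # drop DC
  ord <- order(p, decreasing = TRUE)
  top <- freq[ord[seq_len(min(n, length(ord)))]]
  if (length(top) < n) {                       # pad with jittered copies
    base <- if (any(top > 0)) max(top) else 2 * pi / (m * dt)
    top <- c(top, base * (1 + seq_len(n - length(top)) / n))
  }
  pmax(top, 1e-6)
}

# design matrix of intercept + sin/cos columns for frequencies om
sine_design <- function(times, om) {
  cbind(1, do.call(cbind, lapply(om, function(w) cbind(sin(w * times),
                                                       cos(w * times)))))
}

#' Fit a sum of sinusoids to a time series
#'
#' Least-squares fit of `c + sum_i a_i * sin(omega_i * t + phi_i)` with `n`
#' sinusoidal terms plus a constant offset `c` (fluorescence rates have a
#' nonzero mean, which a finite sine sum can only represent degenerately
#' through a near-zero frequency).  Frequencies are initialised at the
#' top-`n` discrete-spectrum peaks and refined by variable projection
#' (offset/amplitude/phase solved linearly for each candidate frequency
#' set, frequencies optimised quasi-Newton within the Nyquist band), which
#' is deterministic: no random restarts.
#'
#' @param series Numeric series to smooth.
#' @param times Time points (default an evenly spaced grid with step `dt`).
#' @param n Number of sinusoidal terms (default 8).
#' @param dt Grid step used when `times` is `NULL`.
#' @return A `sine_sum` object: tibble of `amplitude`, `omega`, `phase` per
#'   term, the RMS reconstruction error, and the fitted values.
#' @export
fit_sum_of_sines <- function(series, times = NULL, n = 8L, dt = 0.05) {
  n <- as.integer(n)
  if (n < 1L) abort("`n` must be >= 1.")
  if (length(series) < 4L * n)
    abort("series must have at least 4 * n points.")
  if (is.null(times)) times <- dt * (seq_along(series) - 1)
  dt <- times[2] - times[1]

  om_hi <- pi / dt            # Nyquist
  om_lo <- 2 * pi / (length(series) * dt) / 20
  rss_of <- function(logw) {
    om <- exp(logw)
    X <- sine_design(times, om)
    if (!all(is.finite(X))) return(1e300)
    cf <- lm.fit(X, series)$coefficients
    cf[is.na(cf)] <- 0
    sum((series - X %*% cf)^2)
  }

  om0 <- pmin(pmax(spectral_peaks(series, dt, n), om_lo), om_hi)
  if (sd(series) < 1e-14) {
    om <- om0   # constant series: any frequencies, zero amplitudes
  } else {
    opt <- optim(log(om0), rss_of, method = "L-BFGS-B",
                 lower = log(om_lo), upper = log(om_hi),
                 control = list(maxit = 300, factr = 10))
    # unconstrained polish from the banded solution; fine difference steps
    # matter near the optimum of the projected objective
    opt2 <- optim(opt$par, rss_of, method = "BFGS",
                  control = list(maxit = 300, reltol = 1e-15,
                                 ndeps = rep(1e-7, n)))
    if (opt2$value <= opt$value) opt <- opt2
    if (!is.finite(opt$value)) {
      abort("sum-of-sines fit failed to converge.",
            class = "wormcpg_fit_error", best = exp(opt$par))
    }
    om <- exp(opt$par)
  }
  X <- sine_design(times, om)
  cf <- lm.fit(X, series)$coefficients
  cf[is.na(cf)] <- 0
  offset <- cf[1]
  a_sin <- cf[1 + seq(1, 2 * n, by = 2)]
  a_cos <- cf[1 + seq(2, 2 * n, by = 2)]
  amplitude <- sqrt(a_sin^2 + a_cos^2)
  phase <- atan2(a_cos, a_sin)
  fitted_vals <- as.numeric(X %*% cf)
  structure(
    list(terms = tibble(amplitude = amplitude, omega = om, phase = phase),
         offset = unname(offset),
         rms = sqrt(mean((series - fitted_vals)^2)),
         times = times, fitted = fitted_vals),
    class = "sine_sum"
  )
}

#' Evaluate a fitted sum of sinusoids
#' @param object A `sine_sum` from [fit_sum_of_sines()].
#' @param t Times at which to evaluate.
#' @param ... Unused.
#' @return Numeric vector.
#' @export
predict.sine_sum <- function(object, t, ...) {
  tm <- object$terms
  out <- rep(object$offset, length(t))
  for (i in seq_len(nrow(tm))) {
    out <- out + tm$amplitude[i] * sin(tm$omega[i] * t + tm$phase[i])
  }
  out
}

#' @export
print.sine_sum <- function(x, ...) {
  cat("<sine_sum> ", nrow(x$terms), " terms, reconstruction RMS ",
      signif(x$rms, 4), "\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------

#' Normalize values to a range
#'
#' Affine min/max normalization: the observed minimum maps to `range[1]` and
#' the maximum to `range[2]` (per column or over the whole matrix).
#' Constant input maps to the midpoint.  Idempotent.
#'
#' @param x Numeric vector or matrix.
#' @param range Target range.
#' @param per `"column"` (default, per muscle trace) or `"all"`.
#' @return Same shape as `x`.
#' @export
normalize_range <- function(x, range = c(0.25, 0.75),
                            per = c("column", "all")) {
  per <- match.arg(per)
  norm1 <- function(v) {
    lo <- min(v); hi <- max(v)
    if (hi - lo < 1e-300) return(rep(mean(range), length(v)))
    range[1] + (v - lo) * diff(range) / (hi - lo)
  }
  if (is.matrix(x) && per == "column") {
    out <- apply(x, 2, norm1)
    dimnames(out) <- dimnames(x)
    out
  } else if (is.matrix(x)) {
    out <- matrix(norm1(as.numeric(x)), nrow(x), dimnames = dimnames(x))
    out
  } else {
    norm1(x)
  }
}

#' Emulated fluorescence-recording teacher
#'
#' Stands in for a muscle-calcium imaging session of a GCaMP strain: for each
#' of the `n_segments` body segments and each side (dorsal/ventral) it
#' synthesizes a fluorescence trace following one cycle of forward travelling
#' wave and one cycle of backward wave (with the same phase-reversal rule as
#' the analytic teacher), with per-segment amplitude heterogeneity and
#' additive Gaussian sensor noise on a fine imaging grid.  Traces are
#' converted to rates with [fluorescence_rate()], each cycle is smoothed by a
#' sum-of-sines fit ([fit_sum_of_sines()], `n = 8` terms), the fitted cycles
#' are concatenated to `cycles` repetitions of forward + backward, mapped
#' onto the four muscle rows (left = right; dorsal segments to dorsal rows,
#' ventral to ventral), and normalized per muscle to `range`.
#'
#' @param seed Integer seed for heterogeneity and noise.
#' @param schedule Optional [command_schedule()]; if supplied it must switch
#'   every wave period (the emulated recording is one forward cycle followed
#'   by one backward cycle).  Default: built from `omega` and `cycles`.
#' @param cycles Number of forward+backward cycle pairs in the output.
#' @param noise_sd Sensor noise, as a fraction of the fluorescence signal
#'   amplitude.
#' @param amp_heterogeneity Relative spread of per-segment response
#'   amplitudes.
#' @param omega Wave angular frequency (rad/s).
#' @param Fs Output step duration in seconds.
#' @param map A [neuron_index_map()].
#' @param n Number of sinusoidal terms per fitted cycle.
#' @param imaging_dt Fine grid step of the emulated camera, seconds.
#' @param baseline Baseline fluorescence (arbitrary units).
#' @param dff_amp Peak fluorescence response as a fraction of baseline.
#' @param range Output range.
#' @return A `teacher_data` with provenance `"measured_emulation"`.
#' @export
emulate_measured_teacher <- function(seed = 1L, schedule = NULL,
                                     cycles = 3L, noise_sd = 0.05,
                                     amp_heterogeneity = 0.2,
                                     omega = 1.6 * pi, Fs = 0.05,
                                     map = neuron_index_map(), n = 8L,
                                     imaging_dt = 0.01, baseline = 100,
                                     dff_amp = 0.5, range = c(0.25, 0.75)) {
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  period <- 2 * pi / omega
  n_sw <- 2L * cycles
  auto_sched <- command_schedule(period * (seq_len(n_sw) - 1),
                                 period * n_sw)
  if (is.null(schedule)) {
    schedule <- auto_sched
  } else if (!isTRUE(all.equal(schedule$switch_times,
                               auto_sched$switch_times)) ||
             !isTRUE(all.equal(schedule$total_time,
                               auto_sched$total_time))) {
    abort(paste0("the emulated recording switches every wave period; ",
                 "`schedule` must match the auto-generated one ",
                 "(or be NULL)."))
  }

  nseg <- map$n_segments
  rec_sched <- command_schedule(c(0, period), 2 * period)
  phi <- phase_table(rec_sched, omega, nseg)   # 2 epochs x nseg
  t_img <- seq(0, 2 * period - imaging_dt / 2, by = imaging_dt)
  ep <- pmax(epoch_of(t_img, rec_sched), 1L)

  sim <- function() {
    traces <- list(d = matrix(NA_real_, length(t_img), nseg),
                   v = matrix(NA_real_, length(t_img), nseg))
    for (q in seq_len(nseg)) {
      amp_d <- dff_amp * (1 + amp_heterogeneity * runif(1, -1, 1))
      amp_v <- dff_amp * (1 + amp_heterogeneity * runif(1, -1, 1))
      ph <- phi[ep, q]
      s_d <- 0.5 + 0.5 * sin(omega * t_img + ph)
      s_v <- 0.5 + 0.5 * sin(omega * t_img - pi + ph)
      traces$d[, q] <- baseline * (1 + amp_d * s_d) +
        rnorm(length(t_img), sd = noise_sd * baseline * dff_amp)
      traces$v[, q] <- baseline * (1 + amp_v * s_v) +
        rnorm(length(t_img), sd = noise_sd * baseline * dff_amp)
    }
    traces
  }
  traces <- withr::with_seed(seed, sim())

  fwd_idx <- which(t_img < period)
  bwd_idx <- which(t_img >= period)
  fit_side <- function(mat, side) {
    lapply(seq_len(nseg), function(q) {
      r <- fluorescence_rate(mat[, q])
      ffit <- tryCatch(
        fit_sum_of_sines(r[fwd_idx], times = t_img[fwd_idx], n = n),
        error = function(e) abort(paste0(
          "sum-of-sines fit failed for segment ", q, " (", side, " side, ",
          "forward cycle): ", conditionMessage(e))))
      bfit <- tryCatch(
        fit_sum_of_sines(r[bwd_idx], times = t_img[bwd_idx], n = n),
        error = function(e) abort(paste0(
          "sum-of-sines fit failed for segment ", q, " (", side, " side, ",
          "backward cycle): ", conditionMessage(e))))
      list(forward = ffit, backward = bfit)
    })
  }
  fits <- list(d = fit_side(traces$d, "dorsal"),
               v = fit_side(traces$v, "ventral"))

  n_steps <- round(schedule$total_time / Fs)
  times <- Fs * seq_len(n_steps)
  cyc <- pmin(floor(times / (2 * period)), cycles - 1L)
  tau <- times - 2 * period * cyc              # local time in (0, 2*period]
  seg_series <- function(fit_pair) {
    out <- numeric(n_steps)
    fwd <- tau <= period
    out[fwd] <- predict(fit_pair$forward, tau[fwd])
    out[!fwd] <- predict(fit_pair$backward, tau[!fwd])
    out
  }

  d <- matrix(NA_real_, n_steps, map$n_muscles)
  for (u in seq_len(map$n_muscles)) {
    sidek <- if (substr(map$muscle_row[u], 2, 2) == "D") "d" else "v"
    q <- map$muscle_segment[u]
    d[, u] <- seg_series(fits[[sidek]][[q]])
  }
  d <- normalize_range(d, range = range, per = "column")
  colnames(d) <- map$muscle_name
  new_teacher_data(d, times, schedule, "measured_emulation", omega, map,
                   range)
}
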