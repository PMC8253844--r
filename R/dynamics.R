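# Forward simulation of the coupled motor-neuron / muscle network.

#' Model state
#'
#' Input currents of the 69 motor neurons (`x_n`) and 95 muscles (`x_m`);
#' outputs are the logistic sigmoids of the currents, so they lie strictly
#' in (0, 1).  The default initial state is all-zero currents (outputs 0.5).
#'
#' @param x_n,x_m Numeric current vectors.
#' @return A `model_state`.
#' @export
model_state <- function(x_n, x_m) {
  structure(list(x_n = as.numeric(x_n), x_m = as.numeric(x_m),
                 y_n = plogis_(x_n), y_m = plogis_(x_m)),
            class = "model_state")
}

plogis_ <- function(x) 1 / (1 + exp(-as.numeric(x)))

zero_state <- function(map) {
  model_state(rep(0, map$n_neurons), rep(0, map$n_muscles))
}

#' Single synchronous network update (reference implementation)
#'
#' One step of the discrete-time dynamics, written out in plain R: currents
#' decay by `1/(1 + Fs*tau)` and integrate the drive (synaptic input, gap
#' difference currents, command drive, proprioceptive feedback and bias)
#' with gain `Fs*tau/(1 + Fs*tau)`; outputs are logistic sigmoids of the new
#' currents.  Neurons and muscles update synchronously from time-t values.
#' [simulate_network()] uses a compiled implementation of the same update;
#' the two are cross-checked in the test suite.
#'
#' @param state A [model_state()].
#' @param params A `model_parameters`.
#' @param L Length-10 binary command vector.
#' @param activation `"sigmoid"` (the model) or `"identity"` (linear test
#'   harness).
#' @return The next `model_state`.
#' @export
network_step <- function(state, params, L,
                         activation = c("sigmoid", "identity")) {
  activation <- match.arg(activation)
  act <- if (activation == "sigmoid") plogis_ else identity
  p <- apply_mask(params)
  xN <- state$x_n; xM <- state$x_m
  yN <- act(xN); yM <- act(xM)
  aN <- 1 / (1 + p$Fs * p$tau_n); bN <- 1 - aN
  aM <- 1 / (1 + p$Fs * p$tau_m); bM <- 1 - aM

  driveN <- as.numeric(
    p$w_nn %*% yN + p$w_mn %*% yM +
      p$g_nn %*% xN - rowSums(p$g_nn) * xN +
      p$g_mn %*% xM - rowSums(p$g_mn) * xN +
      p$w_in %*% L + p$bias_n)
  driveM <- as.numeric(
    p$w_nm %*% yN +
      t(p$g_mn) %*% xN - colSums(p$g_mn) * xM +
      p$g_mm %*% xM - rowSums(p$g_mm) * xM +
      p$bias_m)
  xN2 <- aN * xN + bN * driveN
  xM2 <- aM * xM + bM * driveM
  if (any(!is.finite(c(xN2, xM2)))) {
    bad <- c(which(!is.finite(xN2)), which(!is.finite(xM2)))[1]
    abort(paste0("non-finite state after update (first offending cell ",
                 bad, ")."))
  }
  st <- model_state(xN2, xM2)
  if (activation == "identity") {
    st$y_n <- xN2
    st$y_m <- xM2
  }
  st
}

#' Simulate the network under a command schedule
#'
#' Iterates the synchronous update for `round(total_time / Fs)` steps,
#' recording muscle and neuron outputs.  The state recorded at time
#' `k * Fs` results from the command evaluated at `(k - 1) * Fs`, so the
#' whole command schedule `[T_1, total_time)` is consumed.  Deterministic.
#'
#' @param params A `model_parameters`.
#' @param schedule A [command_schedule()].
#' @param x0 Initial [model_state()] (default: zero currents, outputs 0.5).
#' @param linear Use the identity activation (linear test harness) instead
#'   of the sigmoid.
#' @return A `trajectory`: time grid, muscle outputs `y_m` (steps x
#'   muscles), neuron outputs `y_n`, currents, and the command matrix.
#' @export
simulate_network <- function(params, schedule, x0 = NULL, linear = FALSE) {
  map <- params$mask$map
  p <- apply_mask(params)
  if (is.null(x0)) x0 <- zero_state(map)
  L <- command_matrix(schedule, Fs = p$Fs)
  res <- nmw_forward(p$w_nn, p$w_mn, p$w_in, p$bias_n, p$w_nm, p$bias_m,
                     p$g_nn, p$g_mn, p$g_mm, p$tau_n, p$tau_m, p$Fs,
                     L, x0$x_n, x0$x_m, linear)
  if (any(!is.finite(res$Ym)) || any(!is.finite(res$Yn))) {
    bad <- which(!is.finite(res$Ym), arr.ind = TRUE)
    if (nrow(bad) == 0) bad <- which(!is.finite(res$Yn), arr.ind = TRUE)
    abort(paste0("simulation diverged: non-finite output at step ",
                 bad[1, 1], ", cell ", bad[1, 2], "."))
  }
  times <- p$Fs * seq_len(nrow(L))
  colnames(res$Ym) <- map$muscle_name
  colnames(res$Yn) <- map$neuron_name
  structure(
    list(times = times, y_m = res$Ym, y_n = res$Yn,
         x_n = res$Xn, x_m = res$Xm, command = L,
         schedule = schedule, map = map),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", length(x$times), " steps x ", ncol(x$y_m),
      " muscles (", ncol(x$y_n), " neurons), t in (0, ",
      max(x$times), "] s\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Travelling-wave direction

# integer-lag cross-correlation argmax of y against ref, lags -maxlag..maxlag
best_lag <- function(ref, y, maxlag) {
  n <- length(ref)
  lags <- -maxlag:maxlag
  cc <- vapply(lags, function(l) {
    if (l >= 0) {
      a <- ref[1:(n - l)]; b <- y[(1 + l):n]
    } else {
      a <- ref[(1 - l):n]; b <- y[1:(n + l)]
    }
    if (sd(a) < 1e-12 || sd(b) < 1e-12) return(-Inf)
    cor(a, b)
  }, numeric(1))
  lags[which.max(cc)]
}

#' Direction of the muscle-activity travelling wave
#'
#' Estimates, within a time window, whether the activity wave along a muscle
#' row propagates from head to tail or tail to head.  Per-muscle phase is
#' measured as the cross-correlation lag between consecutive muscles
#' (accumulated along the row, so phase differences larger than one period
#' relative to the head are handled), the head-most muscles are excluded
#' (they are innervated by nerve-ring neurons absent from the model), and
#' the direction is the sign of the slope of phase against segment index.
#' Returns `"undetermined"` when oscillation amplitude is below
#' `min_amplitude` or the phase gradient is below `slope_threshold`.
#'
#' @param traj A `trajectory`, `teacher_data`, or a numeric matrix of muscle
#'   outputs (steps x muscles).
#' @param window Length-2 numeric time window in seconds; must span at least
#'   one oscillation period.
#' @param row Muscle row: `"LD"`, `"RD"`, `"LV"` or `"RV"`.
#' @param map Index map (taken from `traj` when available).
#' @param period Oscillation period in seconds; estimated from the dominant
#'   spectral peak when `NULL`.
#' @param exclude_head Number of head segments to drop (default
#'   `ceiling(n_segments / 3)`, i.e. 8 of 24 at full size).
#' @param min_amplitude Half peak-to-peak amplitude floor.
#' @param slope_threshold Minimum |phase gradient| in radians per segment.
#' @param times Time grid, required when `traj` is a bare matrix.
#' @return `"head_to_tail"`, `"tail_to_head"`, or `"undetermined"`.
#' @export
wave_direction <- function(traj, window, row = "LD", map = NULL,
                           period = NULL, exclude_head = NULL,
                           min_amplitude = 0.02, slope_threshold = 0.05,
                           times = NULL) {
  if (inherits(traj, "trajectory")) {
    y <- traj$y_m; times <- traj$times; map <- traj$map
  } else if (inherits(traj, "teacher_data")) {
    y <- traj$d; times <- traj$times; map <- traj$map
  } else {
    y <- traj
    if (is.null(times) || is.null(map))
      abort("`times` and `map` are required for a bare matrix.")
  }
  if (is.null(exclude_head)) exclude_head <- ceiling(map$n_segments / 3)
  dt <- times[2] - times[1]
  keep_t <- times > window[1] & times <= window[2]   # half-open epoch
  if (sum(keep_t) < 4) abort("window contains too few samples.")

  mus <- row_indices(map, row)
  q <- map$muscle_segment[mus]
  sel <- q > exclude_head
  mus <- mus[sel]; q <- q[sel]
  sub <- y[keep_t, mus, drop = FALSE]
  sub <- sweep(sub, 2, colMeans(sub))

  amp <- apply(sub, 2, function(v) (max(v) - min(v)) / 2)
  if (max(amp) < min_amplitude) return("undetermined")

  if (is.null(period)) {
    v <- sub[, which.max(amp)]
    sp <- Mod(fft(v))[seq_len(floor(length(v) / 2))]
    sp[1] <- 0
    kstar <- which.max(sp) - 1
    if (kstar < 1) return("undetermined")
    period <- length(v) * dt / kstar
  }
  if (diff(window) < period - dt / 2)
    abort("window must span at least one oscillation period.")

  keep_m <- amp >= min_amplitude
  if (sum(keep_m) < 3) return("undetermined")
  sub <- sub[, keep_m, drop = FALSE]
  q <- q[keep_m]

  maxlag <- max(2L, min(floor(period / dt / 2), floor(nrow(sub) / 3)))
  lags <- numeric(ncol(sub))
  for (k in seq_len(ncol(sub))[-1]) {
    lags[k] <- lags[k - 1] + best_lag(sub[, k - 1], sub[, k], maxlag)
  }
  phase <- 2 * pi * lags * dt / period
  slope <- coef(lm(phase ~ q))[2]
  if (!is.finite(slope) || abs(slope) < slope_threshold)
    return("undetermined")
  if (slope > 0) "head_to_tail" else "tail_to_head"
}

#' Wave direction in every epoch of a schedule
#'
#' Applies [wave_direction()] to each forward/backward epoch, trimming a
#' short transient after each switch.
#'
#' @inheritParams wave_direction
#' @param schedule Defaults to the schedule stored in `traj`.
#' @param transient Seconds discarded at the start of each epoch (the model
#'   needs a moment to re-phase after a command reversal).
#' @param ... Passed to [wave_direction()].
#' @return Tibble with `epoch`, `start`, `end`, `direction` (command) and
#'   `wave` (measured).
#' @export
epoch_wave_directions <- function(traj, schedule = NULL, row = "LD",
                                  transient = 0, ...) {
  if (is.null(schedule)) schedule <- traj$schedule
  ep <- schedule_epochs(schedule)
  ep$wave <- vapply(seq_len(nrow(ep)), function(i) {
    wave_direction(traj, window = c(ep$start[i] + transient, ep$end[i]),
                   row = row, ...)
  }, character(1))
  ep
}
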