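# Binary command-neuron drive: forward/backward epochs defined by switch
# times.  Epochs are half-open [T_v, T_{v+1}); odd epochs (starting at the
# first switch time) are forward, even epochs backward.

#' Command-neuron switching schedule
#'
#' @param switch_times Strictly increasing switch times in seconds; the first
#'   entry is the simulation start and opens a forward epoch.
#' @param total_time Total simulated time in seconds; the last epoch is
#'   truncated at `total_time`.
#' @return A `command_schedule`.
#' @examples
#' command_schedule(c(0, 8.7, 17.6, 22.8, 26.6), 30)
#' @export
command_schedule <- function(switch_times, total_time) {
  switch_times <- as.numeric(switch_times)
  if (length(switch_times) < 1L || is.unsorted(switch_times, strictly = TRUE))
    abort("`switch_times` must be strictly increasing.")
  if (total_time <= max(switch_times))
    abort("`total_time` must exceed the last switch time.")
  structure(list(switch_times = switch_times, total_time = total_time),
            class = "command_schedule")
}

#' @export
print.command_schedule <- function(x, ...) {
  cat("<command_schedule> switches at ",
      paste(x$switch_times, collapse = ", "), " s; T = ", x$total_time,
      " s\n", sep = "")
  invisible(x)
}

# epoch index of time t (1-based); last epoch includes t == total_time
epoch_of <- function(t, schedule) {
  findInterval(t, schedule$switch_times)
}

is_forward_epoch <- function(v) v %% 2L == 1L

#' Binary command-neuron outputs at a time point
#'
#' During forward epochs the four forward command lines (PVCL/R, AVBL/R)
#' output 1 and the six backward lines output 0; during backward epochs the
#' pattern is reversed.  Epochs are half-open, so the switch time itself
#' belongs to the new epoch.
#'
#' @param t Time in seconds, `schedule$switch_times[1] <= t < total_time`.
#' @param schedule A [command_schedule()].
#' @return Integer vector of length 10 (forward lines 1-4, backward 5-10).
#' @examples
#' sched <- command_schedule(c(0, 8.7, 17.6, 22.8, 26.6), 30)
#' command_signal(5, sched)    # forward epoch
#' command_signal(8.7, sched)  # boundary: backward epoch
#' @export
command_signal <- function(t, schedule) {
  if (length(t) != 1L || t < schedule$switch_times[1] ||
      t >= schedule$total_time) {
    abort("`t` must lie in [first switch time, total_time).")
  }
  v <- epoch_of(t, schedule)
  if (is_forward_epoch(v)) c(rep(1L, 4), rep(0L, 6)) else
    c(rep(0L, 4), rep(1L, 6))
}

# T_steps x 10 command matrix on the step grid; row k is the drive applied
# during the step that produces the state at time k * Fs, i.e. the command
# evaluated at (k - 1) * Fs.
command_matrix <- function(schedule, Fs = 0.05) {
  n <- round(schedule$total_time / Fs)
  t_pre <- (seq_len(n) - 1) * Fs
  v <- epoch_of(t_pre, schedule)
  fwd <- is_forward_epoch(v)
  m <- matrix(0L, n, 10L)
  m[fwd, 1:4] <- 1L
  m[!fwd, 5:10] <- 1L
  m
}

#' Epoch table of a schedule
#'
#' @param schedule A [command_schedule()].
#' @return Tibble with one row per epoch: `epoch`, `start`, `end`,
#'   `direction` (`"forward"` or `"backward"`).
#' @export
schedule_epochs <- function(schedule) {
  st <- schedule$switch_times
  en <- c(st[-1], schedule$total_time)
  tibble(
    epoch = seq_along(st),
    start = st,
    end = en,
    direction = ifelse(is_forward_epoch(seq_along(st)),
                       "forward", "backward")
  )
}
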