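# Index conventions for the ventral-cord motor circuit.
#
# Neurons are ordered by class: DA, DB, DD, VA, VB, VD, AS.  At full size the
# class sizes are the standard circuit's 8/8/6/12/11/13/11 (total 69).  Muscles are
# ordered row-major: left-dorsal, right-dorsal, left-ventral, right-ventral,
# head to tail within each row; the right-ventral row is one cell short
# (23 of 24), giving 95 cells in total.

MOTOR_CLASSES <- c("DA", "DB", "DD", "VA", "VB", "VD", "AS")
STD_CLASS_SIZES <- c(DA = 8L, DB = 8L, DD = 6L, VA = 12L, VB = 11L,
                     VD = 13L, AS = 11L)
EXCITATORY_CLASSES <- c("DA", "DB", "VA", "VB", "AS")
INHIBITORY_CLASSES <- c("DD", "VD")
MUSCLE_ROWS <- c("LD", "RD", "LV", "RV")
MUSCLE_ROW_PREFIX <- c(LD = "MDL", RD = "MDR", LV = "MVL", RV = "MVR")
FORWARD_COMMANDS <- c("PVCL", "PVCR", "AVBL", "AVBR")
BACKWARD_COMMANDS <- c("AVAL", "AVAR", "AVDL", "AVDR", "AVEL", "AVER")

#' Index map for motor neurons, muscles and command inputs
#'
#' Fixes the global index conventions of the model: motor-neuron classes and
#' their index ranges, the four muscle rows and the head-to-tail segment
#' position of every muscle cell, the ten binary command inputs (four forward,
#' six backward), and the anchor segment of each neuron used for local
#' wiring and proprioceptive feedback.
#'
#' The default is the full-size circuit: 69 neurons
#' (DA 1-8, DB 9-16, DD 17-22, VA 23-34, VB 35-45, VD 46-58, AS 59-69) and
#' 95 muscles (left-dorsal 1-24, right-dorsal 25-48, left-ventral 49-72,
#' right-ventral 73-95).  Smaller maps with the same class structure are
#' produced by lowering `n_segments` (see [scaled_index_map()]).
#'
#' A neuron's *anchor segment* is its class-local rank mapped proportionally
#' onto segments `1:n_segments`: the r-th of R neurons in a class anchors at
#' `round(r * n_segments / R)`.  Classes prefixed D (and AS, which is
#' dorsally innervating) act on the dorsal muscle rows; classes prefixed V on
#' the ventral rows.
#'
#' @param n_segments Number of head-to-tail body segments per muscle row
#'   (24 for the full-size circuit).
#' @param class_sizes Named integer vector of neurons per class in the order
#'   DA, DB, DD, VA, VB, VD, AS.  Defaults to the full-size counts scaled
#'   proportionally with `n_segments`.
#' @return A `neuron_index_map` object.
#' @examples
#' map <- neuron_index_map()
#' map$n_neurons   # 69
#' map$n_muscles   # 95
#' @export
neuron_index_map <- function(n_segments = 24L, class_sizes = NULL) {
  n_segments <- as.integer(n_segments)
  if (n_segments < 2L) abort("`n_segments` must be at least 2.")
  if (is.null(class_sizes)) {
    if (n_segments == 24L) {
      class_sizes <- STD_CLASS_SIZES
    } else {
      class_sizes <- pmax(1L, as.integer(round(STD_CLASS_SIZES *
                                                 n_segments / 24)))
      names(class_sizes) <- MOTOR_CLASSES
    }
  }
  if (!identical(sort(names(class_sizes)), sort(MOTOR_CLASSES))) {
    abort("`class_sizes` must be named with exactly the seven motor classes.")
  }
  class_sizes <- as.integer(class_sizes[MOTOR_CLASSES])
  names(class_sizes) <- MOTOR_CLASSES

  neuron_class <- rep(MOTOR_CLASSES, class_sizes)
  class_rank <- unlist(lapply(class_sizes, seq_len), use.names = FALSE)
  n_neurons <- length(neuron_class)
  neuron_name <- paste0(neuron_class, sprintf("%02d", class_rank))
  anchor <- as.integer(pmin(pmax(round(
    class_rank * n_segments / class_sizes[neuron_class]), 1L), n_segments))
  side <- ifelse(neuron_class %in% c("DA", "DB", "DD", "AS"), "D", "V")
  polarity <- ifelse(neuron_class %in% EXCITATORY_CLASSES, "excitatory",
                     "inhibitory")

  ends <- cumsum(class_sizes)
  classes <- tibble(
    class = MOTOR_CLASSES,
    size = class_sizes,
    from = ends - class_sizes + 1L,
    to = ends
  )

  row_sizes <- c(LD = n_segments, RD = n_segments, LV = n_segments,
                 RV = n_segments - 1L)
  muscle_row <- rep(MUSCLE_ROWS, row_sizes)
  muscle_segment <- unlist(lapply(row_sizes, seq_len), use.names = FALSE)
  n_muscles <- length(muscle_row)
  muscle_name <- paste0(MUSCLE_ROW_PREFIX[muscle_row],
                        sprintf("%02d", muscle_segment))
  row_ends <- cumsum(row_sizes)
  rows <- tibble(
    row = MUSCLE_ROWS,
    side = c("D", "D", "V", "V"),
    size = as.integer(row_sizes),
    from = as.integer(row_ends - row_sizes + 1L),
    to = as.integer(row_ends)
  )

  structure(
    list(
      n_neurons = n_neurons,
      n_muscles = n_muscles,
      n_segments = n_segments,
      n_commands = 10L,
      classes = classes,
      neuron_class = neuron_class,
      class_rank = class_rank,
      neuron_name = neuron_name,
      neuron_side = side,
      neuron_polarity = polarity,
      anchor_segment = anchor,
      rows = rows,
      muscle_row = muscle_row,
      muscle_segment = as.integer(muscle_segment),
      muscle_name = muscle_name,
      command_name = c(FORWARD_COMMANDS, BACKWARD_COMMANDS),
      forward_commands = 1:4,
      backward_commands = 5:10
    ),
    class = "neuron_index_map"
  )
}

#' Proportionally scaled-down index map
#'
#' Convenience wrapper producing a reduced circuit with the same seven-class
#' structure; class sizes and row lengths scale with `n_segments / 24`.
#'
#' @inheritParams neuron_index_map
#' @return A `neuron_index_map`.
#' @export
scaled_index_map <- function(n_segments) neuron_index_map(n_segments)

#' @export
print.neuron_index_map <- function(x, ...) {
  cat("<neuron_index_map> ", x$n_neurons, " motor neurons (",
      paste0(x$classes$class, ":", x$classes$size, collapse = " "), "), ",
      x$n_muscles, " muscles in 4 rows, ", x$n_segments,
      " segments, 10 command inputs\n", sep = "")
  invisible(x)
}

#' Neuron indices of one or more classes
#' @param map A [neuron_index_map()].
#' @param classes Character vector of class names.
#' @return Integer vector of global neuron indices.
#' @export
class_indices <- function(map, classes) {
  which(map$neuron_class %in% classes)
}

#' Muscle indices of a row
#' @param map A [neuron_index_map()].
#' @param row One of `"LD"`, `"RD"`, `"LV"`, `"RV"`.
#' @return Integer vector of global muscle indices, ordered head to tail.
#' @export
row_indices <- function(map, row) {
  which(map$muscle_row %in% row)
}

excitatory_indices <- function(map) class_indices(map, EXCITATORY_CLASSES)
inhibitory_indices <- function(map) class_indices(map, INHIBITORY_CLASSES)

# rows (dorsal or ventral pair) a neuron innervates, by its side
side_rows <- function(side) if (side == "D") c("LD", "RD") else c("LV", "RV")
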