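# Trainable model parameters.  Matrix orientation matches the masks:
# [postsynaptic, presynaptic].  Gap matrices are symmetric with zero
# diagonal; an unordered pair is one tied parameter stored in both slots.

PARAM_MATS <- c("w_nn", "w_mn", "w_in", "w_nm", "g_nn", "g_mn", "g_mm")
PARAM_VECS <- c("bias_n", "bias_m", "tau_n", "tau_m")
PARAM_NAMES <- c(PARAM_MATS, PARAM_VECS)

# mask slot corresponding to each weight matrix
MASK_OF <- c(w_nn = "syn_nn", w_mn = "syn_mn", w_in = "syn_in",
             w_nm = "syn_nm", g_nn = "gap_nn", g_mn = "gap_mn",
             g_mm = "gap_mm")

new_model_parameters <- function(values, mask, Fs = 0.05) {
  structure(c(values, list(mask = mask, Fs = Fs)),
            class = "model_parameters")
}

#' @export
print.model_parameters <- function(x, ...) {
  map <- x$mask$map
  cat("<model_parameters> ", map$n_neurons, " neurons / ", map$n_muscles,
      " muscles, Fs = ", x$Fs, " s\n  free parameters: ",
      n_free_parameters(x), "\n", sep = "")
  invisible(x)
}

# number of trainable scalars (gap pairs counted once)
n_free_parameters <- function(params) {
  m <- params$mask
  sum(m$syn_nn) + sum(m$syn_mn) + sum(m$syn_in) + sum(m$syn_nm) +
    sum(m$gap_nn[upper.tri(m$gap_nn)]) + sum(m$gap_mn) +
    sum(m$gap_mm[upper.tri(m$gap_mm)]) +
    2L * (m$map$n_neurons + m$map$n_muscles)   # biases and taus
}

# zero every masked-off entry (also clears non-finite placeholders there)
apply_mask <- function(params) {
  for (nm in names(MASK_OF)) {
    m <- params$mask[[MASK_OF[[nm]]]]
    v <- params[[nm]]
    v[!m] <- 0
    params[[nm]] <- v
  }
  params
}

#' Training configuration
#'
#' Bundles the optimizer settings, the termination tolerance on the
#' evaluation function (E <= 0.005 by default), and the uniform
#' initialization ranges: excitatory synapses `[0, 1]`, inhibitory synapses
#' `[-1, 0]`, muscle-to-neuron / command weights and biases `[-1, 1]`,
#' gap conductances `[0, 1]`, lag constants `[0, 0.01]`.
#'
#' @param tolerance Stop when E falls to this value or below.
#' @param max_iterations Iteration cap.
#' @param learning_rate Step size of the optimizer.
#' @param optimizer `"adam"` (adaptive per-parameter scaling, the default),
#'   `"momentum"`, or `"gd"` (plain gradient descent).
#' @param momentum Momentum coefficient (momentum optimizer) or first-moment
#'   decay (adam).
#' @param adam_beta2 Second-moment decay for adam.
#' @param seed Seed for parameter initialization.
#' @param init_ranges Named list of length-2 numeric ranges; override only
#'   for experiments.
#' @param divergence_patience Abort when no new best E has been seen for
#'   this many consecutive iterations.
#' @param backtrack_factor When an iteration's E exceeds
#'   `backtrack_factor * best E` (or the state goes non-finite), rewind to
#'   the best parameters, halve the step size and restart the optimizer
#'   moments.
#' @param clip_norm Global L2 gradient-norm ceiling applied before the
#'   update (`Inf` disables clipping).
#' @return A `training_config` list.
#' @export
training_config <- function(tolerance = 0.005, max_iterations = 3000L,
                            learning_rate = 0.1,
                            optimizer = c("adam", "momentum", "gd"),
                            momentum = 0.9, adam_beta2 = 0.99,
                            clip_norm = 1,
                            seed = NULL,
                            init_ranges = list(
                              excitatory = c(0, 1),
                              inhibitory = c(-1, 0),
                              mixed = c(-1, 1),
                              gap = c(0, 1),
                              tau = c(0, 0.01)
                            ),
                            divergence_patience = 5000L,
                            backtrack_factor = 2) {
  if (tolerance <= 0) abort("`tolerance` must be positive.")
  structure(
    list(tolerance = tolerance, max_iterations = as.integer(max_iterations),
         learning_rate = learning_rate, optimizer = match.arg(optimizer),
         momentum = momentum, adam_beta2 = adam_beta2,
         clip_norm = clip_norm, seed = seed,
         init_ranges = init_ranges,
         divergence_patience = as.integer(divergence_patience),
         backtrack_factor = backtrack_factor),
    class = "training_config"
  )
}

#' Random initial parameters respecting the mask and sign structure
#'
#' Uniform draws on mask-true entries only: columns (presynaptic neurons) of
#' the excitatory classes in `[0, 1]`, inhibitory classes in `[-1, 0]`,
#' muscle-to-neuron and command weights and biases in `[-1, 1]`, gap
#' conductances in `[0, 1]` (drawn on the upper triangle and mirrored), lag
#' constants in `[0, 0.01]`.  Reproducible under `config$seed`.
#'
#' @param mask A `connectome_mask`.
#' @param config A [training_config()].
#' @param Fs Step constant in seconds.
#' @return A `model_parameters` object.
#' @export
initialize_parameters <- function(mask, config = training_config(),
                                  Fs = 0.05) {
  map <- mask$map
  rg <- config$init_ranges
  draw <- function() {
    J <- map$n_neurons; U <- map$n_muscles; P <- map$n_commands
    exc <- map$neuron_polarity == "excitatory"

    signed_cols <- function(nr, msk) {
      m <- matrix(0, nr, J)
      lo <- ifelse(exc, rg$excitatory[1], rg$inhibitory[1])
      hi <- ifelse(exc, rg$excitatory[2], rg$inhibitory[2])
      m[] <- runif(nr * J, rep(lo, each = nr), rep(hi, each = nr))
      m[!msk] <- 0
      m
    }
    unif <- function(msk, range) {
      m <- matrix(runif(length(msk), range[1], range[2]), nrow(msk))
      m[!msk] <- 0
      m
    }
    sym_gap <- function(msk) {
      m <- matrix(0, nrow(msk), ncol(msk))
      ut <- upper.tri(m)
      m[ut] <- runif(sum(ut), rg$gap[1], rg$gap[2])
      m <- m + t(m)
      m[!msk] <- 0
      m
    }
    list(
      w_nn = signed_cols(J, mask$syn_nn),
      w_mn = unif(mask$syn_mn, rg$mixed),
      w_in = unif(mask$syn_in, rg$mixed),
      w_nm = signed_cols(U, mask$syn_nm),
      bias_n = runif(J, rg$mixed[1], rg$mixed[2]),
      bias_m = runif(U, rg$mixed[1], rg$mixed[2]),
      g_nn = sym_gap(mask$gap_nn),
      g_mn = unif(mask$gap_mn, rg$gap),
      g_mm = sym_gap(mask$gap_mm),
      tau_n = runif(J, rg$tau[1], rg$tau[2]),
      tau_m = runif(U, rg$tau[1], rg$tau[2])
    )
  }
  vals <- if (is.null(config$seed)) draw() else
    withr::with_seed(config$seed, draw())
  validate_parameters(new_model_parameters(vals, mask, Fs = Fs))
}

#' Project parameters onto the constraint set
#'
#' Clips excitatory synaptic entries to `>= 0` and inhibitory entries to
#' `<= 0` (by presynaptic class, for neuron-to-neuron and neuron-to-muscle
#' weights), gap conductances to `>= 0`, lag constants to `>= 0`;
#' re-symmetrizes gap matrices by averaging and re-zeros masked entries.
#' Idempotent on feasible parameters.
#'
#' @param params A `model_parameters`.
#' @return A feasible `model_parameters`.
#' @export
project_constraints <- function(params) {
  map <- params$mask$map
  exc <- map$neuron_polarity == "excitatory"
  clip_cols <- function(m) {
    m[, exc] <- pmax(m[, exc, drop = FALSE], 0)
    m[, !exc] <- pmin(m[, !exc, drop = FALSE], 0)
    m
  }
  sym <- function(m) {
    m <- (m + t(m)) / 2
    diag(m) <- 0
    m
  }
  params$w_nn <- clip_cols(params$w_nn)
  params$w_nm <- clip_cols(params$w_nm)
  params$g_nn <- sym(pmax(params$g_nn, 0))
  params$g_mn <- pmax(params$g_mn, 0)
  params$g_mm <- sym(pmax(params$g_mm, 0))
  params$tau_n <- pmax(params$tau_n, 0)
  params$tau_m <- pmax(params$tau_m, 0)
  apply_mask(params)
}

#' Validate model-parameter invariants
#'
#' Errors unless: masked-off entries are exactly zero; gap matrices are
#' symmetric, nonnegative, zero-diagonal; excitatory (inhibitory) synaptic
#' columns are nonnegative (nonpositive); lag constants are nonnegative.
#'
#' @param params A `model_parameters`.
#' @return `params`, invisibly usable in pipes.
#' @export
validate_parameters <- function(params) {
  m <- params$mask
  for (nm in names(MASK_OF)) {
    if (any(params[[nm]][!m[[MASK_OF[[nm]]]]] != 0))
      abort(paste0("masked-off entries of ", nm, " must be exactly zero."))
  }
  if (!isTRUE(all.equal(params$g_nn, t(params$g_nn))) ||
      !isTRUE(all.equal(params$g_mm, t(params$g_mm))))
    abort("gap matrices must be symmetric.")
  if (any(params$g_nn < 0) || any(params$g_mn < 0) || any(params$g_mm < 0))
    abort("gap conductances must be nonnegative.")
  if (any(diag(params$g_nn) != 0) || any(diag(params$g_mm) != 0))
    abort("no self gap junctions.")
  exc <- m$map$neuron_polarity == "excitatory"
  if (any(params$w_nn[, exc] < 0) || any(params$w_nm[, exc] < 0) ||
      any(params$w_nn[, !exc] > 0) || any(params$w_nm[, !exc] > 0))
    abort("synaptic sign constraints violated.")
  if (any(params$tau_n < 0) || any(params$tau_m < 0))
    abort("lag constants must be nonnegative.")
  params
}

#' Write / read model parameters as JSON
#'
#' @param params A `model_parameters`.
#' @param path File path (`.json`).
#' @return `write_parameters()` returns `path` invisibly;
#'   `read_parameters()` a `model_parameters`.
#' @export
write_parameters <- function(params, path) {
  payload <- list(
    Fs = params$Fs,
    n_segments = params$mask$map$n_segments,
    class_sizes = as.list(setNames(params$mask$map$classes$size,
                                   params$mask$map$classes$class)),
    values = lapply(params[PARAM_NAMES],
                    function(v) if (is.matrix(v)) unname(v) else unname(v)),
    masks = lapply(params$mask[c("syn_nn", "syn_nm", "syn_mn", "syn_in",
                                 "gap_nn", "gap_mn", "gap_mm")],
                   function(m) unname(m * 1L))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  sizes <- unlist(payload$class_sizes)
  map <- neuron_index_map(payload$n_segments, class_sizes = sizes)
  mk <- lapply(payload$masks, function(m) matrix(as.logical(m), nrow(m)))
  prop <- proprioceptive_wiring(map)
  mask <- mask_dimnames(new_connectome_mask(
    mk$syn_nn, mk$syn_nm, mk$syn_mn, mk$syn_in,
    mk$gap_nn, mk$gap_mn, mk$gap_mm, map, proprioceptive = prop))
  vals <- payload$values
  for (nm in PARAM_VECS) vals[[nm]] <- as.numeric(vals[[nm]])
  new_model_parameters(vals[PARAM_NAMES], mask, Fs = payload$Fs)
}
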