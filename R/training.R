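# Constrained BPTT training of the network against teacher data.

#' Evaluation function
#'
#' Mean over time steps and muscles of half the squared deviation between
#' muscle outputs and the teacher:
#' `E = (1/T)(1/U) * sum_t sum_u 0.5 * (y_u(t) - d_u(t))^2`.
#'
#' @param y Muscle-output matrix (steps x muscles) or a `trajectory`.
#' @param teacher A `teacher_data` or a matrix of the same shape as `y`.
#' @return Scalar E.
#' @examples
#' evaluate_error(matrix(0.6, 10, 4), matrix(0.5, 10, 4))  # 0.005
#' @export
evaluate_error <- function(y, teacher) {
  if (inherits(y, "trajectory")) y <- y$y_m
  d <- if (inherits(teacher, "teacher_data")) teacher$d else teacher
  if (!all(dim(y) == dim(d)))
    abort(paste0("shape mismatch: outputs are ", nrow(y), "x", ncol(y),
                 ", teacher is ", nrow(d), "x", ncol(d), "."))
  mean(0.5 * (y - d)^2)
}

#' Exact BPTT gradients of the evaluation function
#'
#' Differentiates E through the full unrolled recursion: synaptic sums, gap
#' difference currents (tied symmetric pairs; the gradient of a pair sums
#' the contributions of both directions), command drive, proprioceptive
#' entries, biases and lag constants.  Masked-off entries have zero
#' gradient.
#'
#' @param params A `model_parameters`.
#' @param schedule A [command_schedule()].
#' @param teacher A `teacher_data` (or matrix on the simulation grid).
#' @param x0 Initial state (default zero currents).
#' @return List with `E` (scalar) and one gradient per parameter, congruent
#'   to `params`.
#' @export
bptt_gradients <- function(params, schedule, teacher, x0 = NULL) {
  p <- apply_mask(params)
  map <- p$mask$map
  if (is.null(x0)) x0 <- zero_state(map)
  d <- if (inherits(teacher, "teacher_data")) teacher$d else teacher
  L <- command_matrix(schedule, Fs = p$Fs)
  if (nrow(d) != nrow(L) || ncol(d) != map$n_muscles)
    abort("teacher shape does not match the simulation grid.")
  g <- nmw_bptt(p$w_nn, p$w_mn, p$w_in, p$bias_n, p$w_nm, p$bias_m,
                p$g_nn, p$g_mn, p$g_mm, p$tau_n, p$tau_m, p$Fs,
                L, x0$x_n, x0$x_m, d)
  if (!is.finite(g$E) ||
      any(!vapply(g[PARAM_NAMES],
                  function(v) all(is.finite(v)), logical(1)))) {
    abort("non-finite gradient.", class = "wormcpg_gradient_error")
  }
  for (nm in names(MASK_OF)) {        # masked entries: zero gradient
    g[[nm]][!p$mask[[MASK_OF[[nm]]]]] <- 0
  }
  g$bias_n <- as.numeric(g$bias_n)
  g$bias_m <- as.numeric(g$bias_m)
  g$tau_n <- as.numeric(g$tau_n)
  g$tau_m <- as.numeric(g$tau_m)
  g
}

# global L2 gradient-norm clipping (standard for unrolled recurrent nets)
clip_gradients <- function(grads, clip_norm) {
  if (is.null(clip_norm) || !is.finite(clip_norm)) return(grads)
  nrm <- sqrt(sum(vapply(grads[PARAM_NAMES],
                         function(g) sum(g^2), numeric(1))))
  if (nrm > clip_norm) {
    s <- clip_norm / nrm
    for (nm in PARAM_NAMES) grads[[nm]] <- grads[[nm]] * s
  }
  grads
}

# one optimizer state per parameter tensor
new_opt_state <- function(params) {
  lapply(params[PARAM_NAMES], function(v) {
    list(m = v * 0, v = v * 0)
  })
}

opt_update <- function(params, grads, state, config, iter,
                       lr = config$learning_rate) {
  for (nm in PARAM_NAMES) {
    g <- grads[[nm]]
    st <- state[[nm]]
    if (config$optimizer == "gd") {
      params[[nm]] <- params[[nm]] - lr * g
    } else if (config$optimizer == "momentum") {
      st$m <- config$momentum * st$m + g
      params[[nm]] <- params[[nm]] - lr * st$m
    } else {                      # adam
      b1 <- config$momentum; b2 <- config$adam_beta2
      st$m <- b1 * st$m + (1 - b1) * g
      st$v <- b2 * st$v + (1 - b2) * g^2
      mhat <- st$m / (1 - b1^iter)
      vhat <- st$v / (1 - b2^iter)
      params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + 1e-8)
    }
    state[[nm]] <- st
  }
  list(params = params, state = state)
}

#' Train the network by constrained BPTT
#'
#' Repeats simulate -> evaluate -> backpropagate-through-time -> gradient
#' step -> constraint projection until the evaluation function satisfies
#' `E <= tolerance` or the iteration cap is reached.  Also records the
#' pre-training error of the random initialization and, when a verification
#' teacher is supplied, the error of the trained parameters under the
#' verification schedule (a command schedule the model was never trained
#' on).
#'
#' @param mask A `connectome_mask`.
#' @param teacher A `teacher_data` (its schedule drives training).
#' @param config A [training_config()].
#' @param verification_teacher Optional `teacher_data` on a different
#'   schedule.
#' @param x0 Initial state (default zero currents).
#' @param params Optional starting `model_parameters` (default: random
#'   initialization under `config`).
#' @param quiet Suppress the progress message.
#' @return A `train_result`: trained `params`, `learning_curve` (E per
#'   iteration), `final_E`, `iterations_used`, `converged`, and
#'   `residuals` (`pre`, `post`, `verification`).
#' @export
train_network <- function(mask, teacher, config = training_config(),
                          verification_teacher = NULL, x0 = NULL,
                          params = NULL, quiet = TRUE) {
  schedule <- teacher$schedule
  if (is.null(params)) params <- initialize_parameters(mask, config)
  params <- project_constraints(params)
  pre_E <- evaluate_error(simulate_network(params, schedule, x0 = x0),
                          teacher)

  curve <- numeric(0)
  state <- new_opt_state(params)
  best_E <- Inf
  best_params <- params
  worse_run <- 0L
  frozen_run <- 0L
  prev_E <- NA_real_
  plateau_marker <- Inf
  converged <- FALSE
  lr_scale <- 1

  for (iter in seq_len(config$max_iterations)) {
    g <- tryCatch(
      bptt_gradients(params, schedule, teacher, x0 = x0),
      wormcpg_gradient_error = function(e) NULL)
    blown <- is.null(g) || g$E > config$backtrack_factor * best_E
    if (!blown) {
      # a saturated attractor freezes E exactly (vanishing sigmoid slope);
      # treat a long exact freeze above tolerance as a blow-up
      if (!is.na(prev_E) &&
          abs(g$E - prev_E) <= 1e-13 * max(g$E, 1e-12)) {
        frozen_run <- frozen_run + 1L
        if (frozen_run >= 25L) blown <- TRUE
      } else {
        frozen_run <- 0L
      }
      prev_E <- g$E
    }
    if (!blown) {
      curve[iter] <- g$E
      if (g$E <= config$tolerance) {
        converged <- TRUE
        break
      }
      if (g$E < best_E) {
        best_E <- g$E
        best_params <- params
        worse_run <- 0L
      } else {
        worse_run <- worse_run + 1L
        if (worse_run >= config$divergence_patience) {
          abort("training diverged: E stopped decreasing.",
                class = "wormcpg_divergence", curve = curve)
        }
      }
      upd <- opt_update(params, clip_gradients(g, config$clip_norm),
                        state, config, iter,
                        lr = config$learning_rate * lr_scale)
      params <- project_constraints(upd$params)
      state <- upd$state
      # end-game plateau decay: once E is near tolerance, optimizer jitter
      # at a fixed step keeps it hovering; halve the step when the best E
      # improved < 0.5% over the last 1000 iterations
      if (iter %% 1000L == 0L) {
        if (is.finite(plateau_marker) &&
            best_E < 4 * config$tolerance &&
            best_E > (1 - 0.005) * plateau_marker && lr_scale > 1 / 1024) {
          lr_scale <- lr_scale / 2
        }
        plateau_marker <- best_E
      }
    } else {
      # blow-up (saturation or non-finite state): rewind to the best
      # parameters seen, drop the step size, restart the moments
      curve[iter] <- if (is.null(g)) NA_real_ else g$E
      lr_scale <- lr_scale / 2
      if (lr_scale < 1 / 1024) {
        abort("training diverged: step size collapsed.",
              class = "wormcpg_divergence", curve = curve)
      }
      params <- best_params
      state <- new_opt_state(params)
      prev_E <- NA_real_
      frozen_run <- 0L
      if (!quiet) {
        message("iter ", iter, "  blow-up; rewinding (lr scale ",
                signif(lr_scale, 3), ")")
      }
    }
    if (!quiet && iter %% 100 == 0) {
      message("iter ", iter, "  E = ", signif(curve[iter], 5))
    }
  }
  if (!converged) params <- best_params   # best parameters encountered
  curve <- curve[!is.na(curve)]
  if (!converged) {          # E of the final parameters
    final_E <- evaluate_error(simulate_network(params, schedule, x0 = x0),
                              teacher)
    curve <- c(curve, final_E)
  } else {
    final_E <- curve[length(curve)]
  }

  verification_E <- if (!is.null(verification_teacher)) {
    evaluate_error(
      simulate_network(params, verification_teacher$schedule, x0 = x0),
      verification_teacher)
  } else NA_real_

  structure(
    list(params = validate_parameters(params),
         learning_curve = curve,
         final_E = final_E,
         iterations_used = length(curve),
         converged = converged,
         residuals = list(pre = pre_E, post = final_E,
                          verification = verification_E),
         teacher_provenance = teacher$provenance,
         schedule = schedule,
         config = config),
    class = "train_result"
  )
}

#' @export
print.train_result <- function(x, ...) {
  cat("<train_result> ", x$iterations_used, " iterations, final E = ",
      signif(x$final_E, 4), if (x$converged) " (converged)" else "",
      "\n  residuals: pre = ", signif(x$residuals$pre, 4),
      ", post = ", signif(x$residuals$post, 4),
      ", verification = ", signif(x$residuals$verification, 4), "\n",
      sep = "")
  invisible(x)
}

#' Finite-difference gradient of the evaluation function
#'
#' Independent central-difference differentiation of
#' `evaluate_error(simulate_network(...))`, used as the oracle for
#' [bptt_gradients()].  Symmetric gap pairs are perturbed as one tied
#' parameter (both slots together).
#'
#' @param params A `model_parameters`.
#' @param schedule,teacher,x0 As in [bptt_gradients()].
#' @param name Parameter tensor name (e.g. `"w_nn"`).
#' @param index Integer vector indexing into the tensor.
#' @param h Step size.
#' @return Scalar derivative estimate.
#' @export
fd_gradient <- function(params, schedule, teacher, name, index, h = 1e-4,
                        x0 = NULL) {
  tied <- name %in% c("g_nn", "g_mm")
  bump <- function(delta) {
    p <- params
    v <- p[[name]]
    if (is.matrix(v)) {
      i <- index[1]; j <- index[2]
      v[i, j] <- v[i, j] + delta
      if (tied && i != j) v[j, i] <- v[j, i] + delta
    } else {
      v[index[1]] <- v[index[1]] + delta
    }
    p[[name]] <- v
    evaluate_error(simulate_network(p, schedule, x0 = x0), teacher)
  }
  (bump(h) - bump(-h)) / (2 * h)
}
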