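# Shared fixtures: everything is generated in code at test time.

tiny_map <- function(n_segments = 3) neuron_index_map(n_segments)

tiny_mask <- function(seed = 1, n_segments = 3, span = 2) {
  synthesize_connectome(neuron_index_map(n_segments),
                        locality_span = span, seed = seed)
}

# random feasible parameters with lag constants large enough that the
# dynamics actually move within a short test horizon
lively_params <- function(mask, seed = 1, tau_range = c(0.5, 8)) {
  p <- initialize_parameters(mask, training_config(seed = seed))
  withr::with_seed(seed + 500, {
    p$tau_n <- runif(length(p$tau_n), tau_range[1], tau_range[2])
    p$tau_m <- runif(length(p$tau_m), tau_range[1], tau_range[2])
  })
  p
}

# an all-false mask on a given map, for hand-built minimal circuits
empty_mask <- function(map) {
  J <- map$n_neurons; U <- map$n_muscles; P <- map$n_commands
  wormcpg:::new_connectome_mask(
    matrix(FALSE, J, J), matrix(FALSE, U, J), matrix(FALSE, J, U),
    matrix(FALSE, J, P), matrix(FALSE, J, J), matrix(FALSE, J, U),
    matrix(FALSE, U, U), map)
}

zero_params <- function(mask, Fs = 0.05, tau = 1) {
  map <- mask$map
  J <- map$n_neurons; U <- map$n_muscles; P <- map$n_commands
  wormcpg:::new_model_parameters(
    list(w_nn = matrix(0, J, J), w_mn = matrix(0, J, U),
         w_in = matrix(0, J, P), w_nm = matrix(0, U, J),
         bias_n = rep(0, J), bias_m = rep(0, U),
         g_nn = matrix(0, J, J), g_mn = matrix(0, J, U),
         g_mm = matrix(0, U, U),
         tau_n = rep(tau, J), tau_m = rep(tau, U)),
    mask, Fs = Fs)
}

standard_schedule <- function() command_schedule(c(0, 8.7, 17.6, 22.8, 26.6), 30)
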