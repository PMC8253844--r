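test_that("command signal follows the switching schedule", {
  sched <- standard_schedule()   # 0, 8.7, 17.6, 22.8, 26.6 s; T = 30 s
  fwd <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  expect_equal(command_signal(5.0, sched), fwd)
  # half-open epochs: the switch time belongs to the new epoch
  expect_equal(command_signal(8.7, sched), 1 - fwd)
  # third epoch (17.6 <= t < 22.8) is forward again
  expect_equal(command_signal(20.0, sched), fwd)
  expect_error(command_signal(30, sched), "must lie")
  expect_error(command_signal(-0.1, sched), "must lie")
})

test_that("zero-parameter model sits at the sigmoid midpoint", {
  mask <- tiny_mask()
  p <- zero_params(mask)
  sched <- command_schedule(c(0, 0.5), 1)
  traj <- simulate_network(p, sched)
  expect_equal(nrow(traj$y_m), 20L)            # T / Fs steps
  expect_true(all(traj$y_m == 0.5))
  expect_true(all(traj$y_n == 0.5))
})

test_that("simulation length and determinism match the protocol", {
  mask <- tiny_mask()
  p <- lively_params(mask, seed = 2)
  sched <- command_schedule(c(0, 8.7, 17.6, 22.8, 26.6), 30)
  t1 <- simulate_network(p, sched)
  expect_equal(nrow(t1$y_m), 600L)             # T = 30 s at Fs = 0.05 s
  t2 <- simulate_network(p, sched)
  expect_identical(t1$y_m, t2$y_m)             # bit-identical rerun
})

test_that("single-cell recursion matches the closed-form geometric sum", {
  map <- tiny_map()
  mask <- empty_mask(map)
  tau <- 2.5; b <- 0.8; Fs <- 0.05
  p <- zero_params(mask, tau = tau)
  p$bias_n <- rep(b, map$n_neurons)
  sched <- command_schedule(c(0, 0.3), 0.5)
  traj <- simulate_network(p, sched)

  # x(k) = beta*b * sum_{j<k} alpha^j = b * (1 - alpha^k)
  alpha <- 1 / (1 + Fs * tau)
  k <- seq_len(10)
  expected_x <- b * (1 - alpha^k)
  expect_equal(unname(traj$x_n[k + 1, 1]), expected_x, tolerance = 1e-12)
  expect_equal(unname(traj$y_m[10, 1]), 0.5, tolerance = 1e-12)
})

test_that("gap-junction difference currents are antisymmetric", {
  map <- tiny_map()
  mask <- empty_mask(map)
  mask$gap_nn[1, 2] <- mask$gap_nn[2, 1] <- TRUE
  p <- zero_params(mask, tau = 3)
  g <- 0.7
  p$g_nn[1, 2] <- p$g_nn[2, 1] <- g
  st <- model_state(c(0.9, -0.4, rep(0, map$n_neurons - 2)),
                    rep(0, map$n_muscles))
  nxt <- network_step(st, p, rep(0, 10))
  alpha <- 1 / (1 + p$Fs * 3); beta <- 1 - alpha
  drive1 <- (nxt$x_n[1] - alpha * st$x_n[1]) / beta
  drive2 <- (nxt$x_n[2] - alpha * st$x_n[2]) / beta
  expect_equal(drive1, g * (st$x_n[2] - st$x_n[1]), tolerance = 1e-12)
  expect_equal(drive1, -drive2, tolerance = 1e-12)

  # equal zero currents: the gap contributes nothing and x stays at 0
  st_eq <- zero_state_pair <- model_state(rep(0, map$n_neurons),
                                          rep(0, map$n_muscles))
  nxt_eq <- network_step(st_eq, p, rep(0, 10))
  expect_equal(nxt_eq$x_n[1:2], c(0, 0), tolerance = 1e-12)
  # equal nonzero currents: drive is zero, currents only decay
  st_eq2 <- model_state(c(0.3, 0.3, rep(0, map$n_neurons - 2)),
                        rep(0, map$n_muscles))
  nxt_eq2 <- network_step(st_eq2, p, rep(0, 10))
  expect_equal(nxt_eq2$x_n[1:2], alpha * c(0.3, 0.3), tolerance = 1e-12)
})

test_that("compiled simulation agrees with the R reference step", {
  mask <- tiny_mask(seed = 4)
  p <- lively_params(mask, seed = 4)
  sched <- command_schedule(c(0, 0.6), 1.2)
  traj <- simulate_network(p, sched)
  st <- wormcpg:::zero_state(mask$map)
  L <- wormcpg:::command_matrix(sched, Fs = p$Fs)
  for (k in seq_len(nrow(L))) {
    st <- network_step(st, p, L[k, ])
    expect_equal(st$y_m, unname(traj$y_m[k, ]), tolerance = 1e-12)
  }
})

test_that("linear-regime simulation matches the closed-form recursion", {
  mask <- tiny_mask(seed = 5)
  p <- lively_params(mask, seed = 5)
  map <- mask$map
  J <- map$n_neurons; U <- map$n_muscles
  sched <- command_schedule(c(0, 1), 2)
  traj <- simulate_network(p, sched, linear = TRUE)

  # with identity activation the full update is linear:
  # z(t+1) = M z(t) + c, z = (xN, xM)
  aN <- 1 / (1 + p$Fs * p$tau_n); bN <- 1 - aN
  aM <- 1 / (1 + p$Fs * p$tau_m); bM <- 1 - aM
  Ann <- diag(aN) + diag(bN) %*%
    (p$w_nn + p$g_nn - diag(rowSums(p$g_nn) + rowSums(p$g_mn)))
  Anm <- diag(bN) %*% (p$w_mn + p$g_mn)
  Amn <- diag(bM) %*% (p$w_nm + t(p$g_mn))
  Amm <- diag(aM) + diag(bM) %*%
    (p$g_mm - diag(colSums(p$g_mn) + rowSums(p$g_mm)))
  M <- rbind(cbind(Ann, Anm), cbind(Amn, Amm))
  L <- wormcpg:::command_matrix(sched, Fs = p$Fs)
  z <- rep(0, J + U)
  for (k in seq_len(nrow(L))) {
    cvec <- c(bN * (p$w_in %*% L[k, ] + p$bias_n), bM * p$bias_m)
    z <- as.numeric(M %*% z + cvec)
  }
  expect_equal(unname(c(traj$x_n[nrow(L) + 1, ], traj$x_m[nrow(L) + 1, ])),
               z, tolerance = 1e-10)
})

test_that("masked-off weights are never read (NaN poisoning)", {
  mask <- tiny_mask(seed = 6)
  p <- lively_params(mask, seed = 6)
  for (nm in names(wormcpg:::MASK_OF)) {
    v <- p[[nm]]
    v[!mask[[wormcpg:::MASK_OF[[nm]]]]] <- NaN
    p[[nm]] <- v
  }
  traj <- simulate_network(p, command_schedule(c(0, 0.5), 1))
  expect_true(all(is.finite(traj$y_m)))
  expect_true(all(is.finite(traj$y_n)))
})

test_that("outputs stay bounded in the unit interval", {
  # mathematically y lies strictly in (0, 1); in double precision the
  # sigmoid saturates to exactly 0/1 beyond |x| ~ 37, so the testable
  # invariant is finiteness plus containment in [0, 1]
  for (seed in 1:5) {
    mask <- tiny_mask(seed = seed, n_segments = 4)
    p <- lively_params(mask, seed = seed, tau_range = c(0.5, 20))
    traj <- simulate_network(p, command_schedule(c(0, 1.5), 3))
    expect_true(all(is.finite(traj$y_m)) && all(is.finite(traj$y_n)))
    expect_true(all(traj$y_m >= 0 & traj$y_m <= 1))
    expect_true(all(traj$y_n >= 0 & traj$y_n <= 1))
    # moderate currents stay strictly interior
    mid <- abs(traj$x_n) < 30
    expect_true(all(traj$y_n[mid[-1, ]] > 0 & traj$y_n[mid[-1, ]] < 1))
  }
})

test_that("wave direction recovers constructed phase gradients", {
  map <- neuron_index_map()
  times <- 0.05 * (1:200)
  omega <- 1.6 * pi
  q <- map$muscle_segment
  build <- function(sgn) {
    ph <- outer(omega * times, sgn * pi * q / 12, "+")
    0.5 + 0.3 * sin(ph)
  }
  y_fwd <- build(-1)    # phase decreases head to tail: delayed caudally
  y_bwd <- build(+1)
  win <- c(0.05, 10)
  expect_equal(wave_direction(y_fwd, win, row = "LD", map = map,
                              times = times), "head_to_tail")
  expect_equal(wave_direction(y_bwd, win, row = "LD", map = map,
                              times = times), "tail_to_head")
  y_flat <- matrix(0.5, length(times), map$n_muscles)
  expect_equal(wave_direction(y_flat, win, row = "LD", map = map,
                              times = times), "undetermined")
  expect_error(
    wave_direction(y_fwd, c(0.05, 0.6), row = "LD", map = map,
                   times = times, period = 1.25),
    "at least one oscillation period")
})
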