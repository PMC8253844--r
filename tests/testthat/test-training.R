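test_that("evaluation function is the mean half squared error", {
  expect_equal(evaluate_error(matrix(0.5, 7, 3), matrix(0.5, 7, 3)), 0)
  # constant offset 0.1 -> E = 0.5 * 0.01
  expect_equal(evaluate_error(matrix(0.6, 7, 3), matrix(0.5, 7, 3)), 0.005)
  # small random pair against independent double-loop arithmetic
  withr::with_seed(9, {
    y <- matrix(runif(6), 3, 2)
    d <- matrix(runif(6), 3, 2)
  })
  acc <- 0
  for (t in 1:3) for (u in 1:2) acc <- acc + 0.5 * (y[t, u] - d[t, u])^2
  expect_equal(evaluate_error(y, d), acc / (3 * 2))
  expect_error(evaluate_error(matrix(0, 3, 2), matrix(0, 2, 3)),
               "shape mismatch")
})

test_that("initialization respects seed, ranges and mask", {
  mask <- tiny_mask(seed = 2, n_segments = 4)
  map <- mask$map
  cfg <- training_config(seed = 11)
  p1 <- initialize_parameters(mask, cfg)
  p2 <- initialize_parameters(mask, cfg)
  expect_identical(p1[wormcpg:::PARAM_NAMES], p2[wormcpg:::PARAM_NAMES])

  exc <- map$neuron_polarity == "excitatory"
  expect_true(all(p1$w_nn[, exc] >= 0 & p1$w_nn[, exc] <= 1))
  expect_true(all(p1$w_nn[, !exc] >= -1 & p1$w_nn[, !exc] <= 0))
  expect_true(all(p1$w_mn >= -1 & p1$w_mn <= 1))
  expect_true(all(p1$g_nn >= 0 & p1$g_nn <= 1))
  expect_true(all(p1$tau_n >= 0 & p1$tau_n <= 0.01))
  expect_true(all(p1$tau_m >= 0 & p1$tau_m <= 0.01))
  # masked-off entries are exactly zero; gaps symmetric
  expect_true(all(p1$w_nn[!mask$syn_nn] == 0))
  expect_true(all(p1$g_mm[!mask$gap_mm] == 0))
  expect_identical(p1$g_nn, t(p1$g_nn))
})

test_that("constraint projection clips, re-zeros and is idempotent", {
  mask <- tiny_mask(seed = 3)
  map <- mask$map
  p <- initialize_parameters(mask, training_config(seed = 3))
  exc_j <- which(map$neuron_polarity == "excitatory")[1]
  inh_j <- which(map$neuron_polarity == "inhibitory")[1]
  i_exc <- which(mask$syn_nn[, exc_j])[1]
  i_inh <- which(mask$syn_nn[, inh_j])[1]
  skip_if(is.na(i_exc) || is.na(i_inh))
  p$w_nn[i_exc, exc_j] <- -0.3          # wrong-signed excitatory entry
  p$w_nn[i_inh, inh_j] <- 0.2           # wrong-signed inhibitory entry
  p$tau_n[1] <- -1
  q <- project_constraints(p)
  expect_equal(q$w_nn[i_exc, exc_j], 0)
  expect_equal(q$w_nn[i_inh, inh_j], 0)
  expect_equal(q$tau_n[1], 0)
  expect_identical(project_constraints(q)[wormcpg:::PARAM_NAMES],
                   q[wormcpg:::PARAM_NAMES])
  expect_silent(validate_parameters(q))
})

test_that("BPTT gradients match central finite differences", {
  # small random instances; every parameter family checked
  for (seed in 1:4) {
    mask <- tiny_mask(seed = seed, n_segments = 3, span = 2)
    p <- lively_params(mask, seed = seed, tau_range = c(0.2, 6))
    sched <- command_schedule(c(0, 1), 2)      # 40 steps
    teacher <- analytic_teacher(sched, map = mask$map)
    g <- bptt_gradients(p, sched, teacher)

    withr::with_seed(100 + seed, {
      for (nm in wormcpg:::PARAM_NAMES) {
        v <- p[[nm]]
        if (is.matrix(v)) {
          msk <- mask[[wormcpg:::MASK_OF[[nm]]]]
          idxs <- which(msk, arr.ind = TRUE)
          if (nm %in% c("g_nn", "g_mm")) {
            idxs <- idxs[idxs[, 1] < idxs[, 2], , drop = FALSE]
          }
        } else {
          idxs <- cbind(seq_along(v))
        }
        take <- min(8, nrow(idxs))
        idxs <- idxs[sample(nrow(idxs), take), , drop = FALSE]
        for (r in seq_len(take)) {
          ix <- idxs[r, ]
          an <- if (is.matrix(v)) g[[nm]][ix[1], ix[2]] else g[[nm]][ix[1]]
          fd <- fd_gradient(p, sched, teacher, nm, ix, h = 1e-6)
          expect_lt(abs(an - fd) / max(abs(an), abs(fd), 1e-7), 1e-5,
                    label = paste("grad", nm, paste(ix, collapse = ",")))
        }
      }
    })
  }
})

test_that("masked entries receive zero gradient", {
  mask <- tiny_mask(seed = 5)
  p <- lively_params(mask, seed = 5)
  sched <- command_schedule(c(0, 0.5), 1)
  g <- bptt_gradients(p, sched, analytic_teacher(sched, map = mask$map))
  for (nm in names(wormcpg:::MASK_OF)) {
    expect_true(all(g[[nm]][!mask[[wormcpg:::MASK_OF[[nm]]]]] == 0),
                label = nm)
  }
  # tied gap gradient is symmetric
  expect_equal(g$g_nn, t(g$g_nn), tolerance = 1e-12)
})

test_that("self-target training terminates immediately at E ~ 0", {
  mask <- tiny_mask(seed = 6)
  p <- lively_params(mask, seed = 6)
  sched <- command_schedule(c(0, 1), 2)
  own <- simulate_network(p, sched)$y_m
  teacher <- structure(list(d = own, times = 0.05 * seq_len(nrow(own)),
                            schedule = sched, provenance = "analytic",
                            omega = 1.6 * pi, map = mask$map,
                            range = range(own)),
                       class = "teacher_data")
  res <- train_network(mask, teacher, training_config(seed = 6),
                       params = p)
  expect_true(res$converged)
  expect_lte(res$iterations_used, 1L)
  expect_lt(res$final_E, 1e-10)
})

test_that("a model can re-learn the output of known feasible parameters", {
  # a smooth, attainable target: the output of moderate feasible parameters
  mask <- tiny_mask(seed = 7, n_segments = 4)
  target_params <- lively_params(mask, seed = 7, tau_range = c(0.5, 3))
  sched <- command_schedule(c(0, 2.5), 5)
  target <- simulate_network(target_params, sched)$y_m
  teacher <- structure(list(d = target,
                            times = 0.05 * seq_len(nrow(target)),
                            schedule = sched, provenance = "analytic",
                            omega = 1.6 * pi, map = mask$map,
                            range = range(target)),
                       class = "teacher_data")
  cfg <- training_config(seed = 17, tolerance = 1e-4,
                         max_iterations = 12000)
  res <- train_network(mask, teacher, cfg)
  # function-space recovery: outputs match, weights need not
  expect_lte(res$final_E, 1e-4)
})

test_that("training converges on small instances and keeps invariants", {
  # scaled-down convergence study: most random seeds must reach tolerance
  mask <- tiny_mask(seed = 8, n_segments = 4)     # 12 neurons, 15 muscles
  sched <- command_schedule(c(0, 5), 10)          # 200 steps
  teacher <- analytic_teacher(sched, map = mask$map)
  ok <- 0L
  for (seed in 1:10) {
    cfg <- training_config(seed = seed, max_iterations = 20000)
    res <- tryCatch(train_network(mask, teacher, cfg),
                    wormcpg_divergence = function(e) NULL)
    if (!is.null(res)) {
      expect_silent(validate_parameters(res$params))
      if (res$converged) ok <- ok + 1L
    }
  }
  expect_gte(ok, 8L)
})

test_that("smoothed learning curve of a converged run trends downward", {
  # same instance as the convergence study; a seed known to converge
  mask <- tiny_mask(seed = 8, n_segments = 4)
  sched <- command_schedule(c(0, 5), 10)
  teacher <- analytic_teacher(sched, map = mask$map)
  res <- train_network(mask, teacher,
                       training_config(seed = 2, max_iterations = 12000))
  expect_true(res$converged)
  expect_equal(res$final_E, tail(res$learning_curve, 1))
  curve <- res$learning_curve
  win <- 50
  smoothed <- stats::filter(curve, rep(1 / win, win), sides = 1)
  smoothed <- smoothed[!is.na(smoothed)]
  # non-increasing trend up to small optimizer jitter
  expect_true(all(diff(smoothed) < 0.05 * smoothed[-length(smoothed)]))
  expect_lt(res$residuals$post, res$residuals$pre)
})
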