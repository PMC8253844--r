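# Post-training analysis: distribution of trained connection strengths and
# the modified Boltzmann fit, plus residual-error summaries across trials.

#' Pool trained weight magnitudes into a histogram
#'
#' Pools `|w|` over all structurally allowed connections from one or more
#' training trials.  The `"synaptic"` source pools the neuron-to-neuron,
#' neuron-to-muscle, muscle-to-neuron and command weights; the
#' `"conductance"` source pools gap-junction conductances, counting each
#' unordered pair once.  Entries that are exactly zero (projection-induced
#' sparsity) are excluded: the fitted density describes the strength of
#' existing connections and diverges at zero strength.  Frequencies are
#' counted per trial on shared equal-width bins; the mean frequency across
#' trials is what the Boltzmann fit uses.
#'
#' @param results A `train_result` or list of them.
#' @param source `"synaptic"` or `"conductance"`.
#' @param bins Number of equal-width bins.
#' @return A `weight_histogram`: per-trial counts, bin edges/centers, mean
#'   frequencies, the pooled values, and `n_total` (structurally allowed
#'   connection count).
#' @export
pool_weights <- function(results, source = c("synaptic", "conductance"),
                         bins = 20L) {
  source <- match.arg(source)
  if (inherits(results, "train_result")) results <- list(results)
  if (length(results) < 1L) abort("need at least one training result.")

  extract <- function(res) {
    p <- res$params
    m <- p$mask
    if (source == "synaptic") {
      c(abs(p$w_nn[m$syn_nn]), abs(p$w_nm[m$syn_nm]),
        abs(p$w_mn[m$syn_mn]), abs(p$w_in[m$syn_in]))
    } else {
      ut_nn <- upper.tri(p$g_nn) & m$gap_nn
      ut_mm <- upper.tri(p$g_mm) & m$gap_mm
      c(abs(p$g_nn[ut_nn]), abs(p$g_mn[m$gap_mn]), abs(p$g_mm[ut_mm]))
    }
  }
  vals <- lapply(results, extract)
  n_total <- length(vals[[1]])
  vals <- lapply(vals, function(v) v[v > 0])
  pooled <- unlist(vals)
  if (length(pooled) == 0L) abort("no nonzero weights to pool.")

  edges <- seq(0, max(pooled), length.out = bins + 1L)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  count1 <- function(v) {
    idx <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE,
                                  left.open = TRUE), 1L), bins)
    tabulate(idx, nbins = bins)
  }
  counts <- vapply(vals, count1, integer(bins))   # bins x trials
  freq <- tibble(
    trial = rep(seq_along(vals), each = bins),
    bin = rep(seq_len(bins), times = length(vals)),
    center = rep(centers, times = length(vals)),
    count = as.integer(counts)
  )
  structure(
    list(freq = freq, bin_edges = edges, centers = centers,
         mean_freq = rowMeans(counts), source = source,
         n_total = n_total, n_trials = length(vals),
         values = vals),
    class = "weight_histogram"
  )
}

#' @export
print.weight_histogram <- function(x, ...) {
  cat("<weight_histogram> ", x$source, " strengths, ", x$n_trials,
      " trial(s), ", length(x$centers), " bins, ", x$n_total,
      " allowed connections\n", sep = "")
  invisible(x)
}

#' Fit the modified Boltzmann distribution to a weight histogram
#'
#' Nonlinear least squares of
#' `p(w) = A * exp(-beta * (a*|w|)) / (a*|w|)^(1 - 1/n)`
#' against the mean bin frequencies, with `n` fixed to the structural
#' connection count (it is not fitted).
#'
#' Two ways of turning the law into a per-bin model value are supported.
#' `method = "density"` (the default) evaluates the density at the bin
#' centre, the conventional frequency-vs-strength fit; its R-squared is
#' comparable across binnings and is the quantity this package reports for
#' trained-weight histograms.  `method = "mass"` integrates the density
#' over each bin (an incomplete-gamma expression); for data *sampled* from
#' the law this is the statistically consistent choice, because for large
#' `n` the `w^(1/n - 1)` singularity concentrates mass near zero and the
#' centre-density approximation is badly biased in the first bins.
#'
#' Only `C` (overall scale) and `lambda = beta * a` are identifiable.  The
#' fit profiles `C` out exactly (the model is linear in it), scans `lambda`
#' on a wide deterministic log-grid seeded by a log-domain linear pre-fit,
#' polishes by quasi-Newton, and reports `A`, `a`, `beta` under the
#' convention `a = 1 / mean(|w|)`.  No randomness anywhere.
#'
#' @param hist A [pool_weights()] histogram.
#' @param method `"density"` or `"mass"` (see Details).
#' @return A `boltzmann_fit` with fields `A`, `a`, `beta`, `n`,
#'   `lambda`, `r_squared`, `fit_pvalue`, and a tibble of observed vs
#'   fitted frequencies.
#' @export
fit_modified_boltzmann <- function(hist, method = c("density", "mass")) {
  method <- match.arg(method)
  y_all <- hist$mean_freq
  edges <- hist$bin_edges
  keep <- y_all > 0 & hist$centers > 0
  y <- y_all[keep]
  w <- hist$centers[keep]
  if (length(y) < 5L) abort("need at least 5 occupied bins to fit.")
  n_fix <- hist$n_total
  sh <- 1 / n_fix

  lo <- edges[-length(edges)][keep]
  hi <- edges[-1][keep]
  shape_fun <- if (method == "density") {
    function(lam) exp(-lam * w) * w^(sh - 1)
  } else {
    function(lam) {
      stats::pgamma(lo, shape = sh, rate = lam, lower.tail = FALSE) -
        stats::pgamma(hi, shape = sh, rate = lam, lower.tail = FALSE)
    }
  }
  # C profiled out exactly: for fixed lambda the model is linear in C
  rss_at <- function(lam) {
    g <- suppressWarnings(shape_fun(lam))   # extreme lambda under/overflows
    if (!all(is.finite(g)) || sum(g^2) <= 0) return(c(NA_real_, Inf))
    C <- sum(y * g) / sum(g^2)
    c(C, sum((y - C * g)^2))
  }

  # deterministic search: log-linear pre-fit seed + wide log-grid + polish
  z <- log(y) + (1 - sh) * log(w)
  pre <- lm(z ~ w)
  lam_pre <- max(-coef(pre)[2], 1e-8)
  grid <- unique(c(lam_pre, exp(seq(log(1e-4 / max(w)),
                                    log(500 / max(w)),
                                    length.out = 200))))
  rss_grid <- vapply(grid, function(l) rss_at(l)[2], numeric(1))
  lam0 <- grid[which.min(rss_grid)]
  op <- optim(log(lam0), function(p) rss_at(exp(p))[2], method = "BFGS",
              control = list(maxit = 500, reltol = 1e-14))
  lam_hat <- exp(op$par)
  sol <- rss_at(lam_hat)
  if (!is.finite(sol[2]) || !is.finite(sol[1])) {
    abort("modified-Boltzmann fit failed.",
          class = "wormcpg_fit_error",
          diagnostics = list(grid_best = lam0))
  }
  C_hat <- sol[1]

  pred <- C_hat * shape_fun(lam_hat)
  ss_res <- sum((y - pred)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- 1 - ss_res / ss_tot
  m <- length(y); p_n <- 2
  fstat <- ((ss_tot - ss_res) / p_n) / (ss_res / max(m - p_n - 1, 1))
  pval <- pf(fstat, p_n, max(m - p_n - 1, 1), lower.tail = FALSE)

  # density-scale parameters: the fitted count density is
  # dens_scale * w^(sh - 1) * exp(-lam w)
  a_conv <- 1 / mean(unlist(hist$values))
  dens_scale <- if (method == "density") C_hat else
    C_hat * lam_hat^sh / gamma(sh)
  structure(
    list(A = dens_scale * a_conv^(1 - sh), a = a_conv,
         beta = lam_hat / a_conv, n = n_fix,
         C = C_hat, lambda = lam_hat, method = method,
         r_squared = r2, fit_pvalue = pval,
         converged = op$convergence == 0,
         source = hist$source,
         data = tibble(center = w, observed = y, fitted = pred)),
    class = "boltzmann_fit"
  )
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat("<boltzmann_fit> ", x$source, ": R^2 = ", signif(x$r_squared, 4),
      " (p = ", format(x$fit_pvalue, digits = 3), "), beta = ",
      signif(x$beta, 4), ", a = ", signif(x$a, 4), ", n = ", x$n, "\n",
      sep = "")
  invisible(x)
}

#' Modified Boltzmann density (unnormalized)
#'
#' @param w Weight magnitudes.
#' @param A,a,beta,n Distribution parameters; `n` is the total connection
#'   count.
#' @return `A * exp(-beta * a * |w|) / (a * |w|)^(1 - 1/n)`.
#' @export
modified_boltzmann <- function(w, A, a, beta, n) {
  A * exp(-beta * (a * abs(w))) / (a * abs(w))^(1 - 1 / n)
}

#' Residual errors across training trials
#'
#' Tabulates pre-training, post-training and verification values of the
#' evaluation function per trial, with group means and standard deviations.
#' Errors if a converged trial failed to improve on its pre-training error.
#'
#' @param results A list of `train_result`s.
#' @return A `residual_summary`: `$trials` tibble (one row per trial) and
#'   `$summary` tibble (mean and sd per condition).
#' @export
residual_summary <- function(results) {
  if (inherits(results, "train_result")) results <- list(results)
  trials <- tibble(
    trial = seq_along(results),
    pre_E = map_dbl(results, ~ .x$residuals$pre),
    post_E = map_dbl(results, ~ .x$residuals$post),
    verification_E = map_dbl(results, ~ .x$residuals$verification),
    converged = vapply(results, function(r) r$converged, logical(1))
  )
  bad <- trials$converged & !(trials$post_E < trials$pre_E)
  if (any(bad)) {
    abort(paste0("converged trial(s) without improvement: ",
                 paste(trials$trial[bad], collapse = ", ")))
  }
  long <- pivot_longer(trials[, c("trial", "pre_E", "post_E",
                                  "verification_E")],
                       -"trial", names_to = "condition",
                       values_to = "E")
  summ <- summarise(group_by(long, .data$condition),
                    mean_E = mean(.data$E), sd_E = sd(.data$E),
                    .groups = "drop")
  structure(list(trials = trials, summary = summ),
            class = "residual_summary")
}

#' @export
print.residual_summary <- function(x, ...) {
  cat("<residual_summary> ", nrow(x$trials), " trial(s)\n", sep = "")
  print(x$trials)
  invisible(x)
}
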