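## Staged weighted nonlinear least-squares calibration of the switched
## logistic model against replicate colony-count series. All nonlinear
## minimisation goes through minpack.lm::nls.lm (bounded Levenberg-
## Marquardt) with a small deterministic multistart; linear fits use lm().

new_fit_result <- function(estimates, fixed, wssr, n_points, converged,
                           residual_series = NULL, fitted_series = NULL,
                           times = NULL, note = NULL) {
  structure(list(estimates = estimates, fixed = fixed, wssr = wssr,
                 n_points = n_points, converged = converged,
                 residual_series = residual_series,
                 fitted_series = fitted_series, times = times, note = note),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("Weighted least-squares growth fit\n")
  est <- paste(sprintf("%s = %.6g", names(x$estimates), x$estimates),
               collapse = ", ")
  cat("  estimates: ", est, "\n", sep = "")
  if (length(x$fixed))
    cat("  fixed:     ",
        paste(sprintf("%s = %.6g", names(x$fixed), x$fixed),
              collapse = ", "), "\n", sep = "")
  cat(sprintf("  wssr = %.6g over %d points; converged: %s\n",
              x$wssr, x$n_points, x$converged))
  if (!is.null(x$note)) cat("  note: ", x$note, "\n", sep = "")
  invisible(x)
}

## deterministic multistart around bounded Levenberg-Marquardt
lm_multistart <- function(resid_fun, starts, lower, upper) {
  best <- NULL
  best_dev <- Inf
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                     ptol = 1e-14, gtol = 0)
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], fn = resid_fun,
                         lower = lower, upper = upper, control = ctrl),
      error = function(e) NULL)
    if (is.null(fit)) next
    dev <- sum(fit$fvec^2)
    if (dev < best_dev) {
      best_dev <- dev
      best <- fit
    }
  }
  if (is.null(best)) stop("all optimizer starts failed")
  best
}

lm_converged <- function(fit) fit$info %in% 1:4

resid_weights <- function(summ, weighting) {
  w <- summ$weights
  if (weighting == "inverse_var") w <- w^2
  w
}

#' Fit intrinsic rate and carrying capacity with a fixed initial condition
#'
#' Calibrates one constant-parameter phase of the model (the never-induced
#' culture for `lambda0`, `kappa0`; the culture induced at t = 0 for
#' `lambda1`, `kappa1`) by weighted nonlinear least squares. The initial
#' condition `N(0)` is *fixed* to the mean of the first sample across
#' replicates and excluded from the objective; the weighted residual sum
#' `sum_k w(k) (N(k) - Ndata(k))^2` over the remaining points is minimised
#' over (`lambda`, `kappa`) with the discrete-time model (exact closed-form
#' propagation, since the parameters are constant). Fixing `N(0)` balances
#' the transient and stationary regimes of data spanning several orders of
#' magnitude: with a free initial condition a linear-scale fit is dominated
#' by the plateau (good `kappa`, poor `lambda`), while a log-scale fit has
#' the opposite problem.
#'
#' @param dataset a [growth_dataset()] with at least 3 time points.
#' @param model_mode which phase the estimates label: `"single_phase_off"`
#'   (never induced) or `"single_phase_on"` (induced at t = 0). The
#'   objective is identical; the label is carried into the result.
#' @param weighting `"inverse_sd"` (weights `1/SD`, default) or
#'   `"inverse_var"` (`1/SD^2`).
#' @param sd_floor_frac SD floor passed to [summarize_replicates()].
#' @param lambda_bounds,kappa_bounds optimizer box constraints; the kappa
#'   lower bound defaults to `10 * N(0)`, upper to `1e11` CFU/mL.
#' @return A `growth_fit` with estimates `lambda`, `kappa`, fixed `n0`, the
#'   weighted SSR, and a convergence flag.
#' @examples
#' p <- growth_params(0.9, 0.45, 1.2e8, 8e8)
#' sc <- experiment_scenario(noise_cv = 0)
#' d <- generate_dataset(sc, schedule_never(), label = "OFF")
#' fit_rate_capacity(d, "single_phase_off")
#' @export
fit_rate_capacity <- function(dataset,
                              model_mode = c("single_phase_off",
                                             "single_phase_on"),
                              weighting = c("inverse_sd", "inverse_var"),
                              sd_floor_frac = 1e-3,
                              lambda_bounds = c(0.01, 3),
                              kappa_bounds = NULL) {
  model_mode <- match.arg(model_mode)
  weighting <- match.arg(weighting)
  stopifnot(inherits(dataset, "growth_dataset"))
  if (length(dataset$times) < 3L)
    stop("at least 3 time points are required")
  summ <- summarize_replicates(dataset, sd_floor_frac)
  n0 <- summ$mean[1]
  if (is.null(kappa_bounds)) kappa_bounds <- c(10 * n0, 1e11)
  w <- resid_weights(summ, weighting)
  times <- dataset$times
  keep <- -1L  # k = 0 carries no information once N(0) is fixed
  sqw <- sqrt(w[keep])
  target <- summ$mean[keep]
  resid_fun <- function(p) {
    model <- logistic_closed_form(n0, p[1], 10^p[2], times[keep])
    sqw * (model - target)
  }
  lk <- log10(kappa_bounds)
  k_start <- min(max(log10(max(summ$mean)), lk[1]), lk[2])
  starts <- cbind(lambda = c(0.2, 0.5, 0.9, 1.5, 2.5),
                  log10_kappa = rep(k_start, 5))
  starts[, 1] <- pmin(pmax(starts[, 1], lambda_bounds[1]), lambda_bounds[2])
  fit <- lm_multistart(resid_fun, starts,
                       lower = c(lambda_bounds[1], lk[1]),
                       upper = c(lambda_bounds[2], lk[2]))
  est <- c(lambda = unname(fit$par[1]), kappa = unname(10^fit$par[2]))
  model <- logistic_closed_form(n0, est["lambda"], est["kappa"], times)
  new_fit_result(
    estimates = est, fixed = c(n0 = n0), wssr = sum(fit$fvec^2),
    n_points = length(target), converged = lm_converged(fit),
    residual_series = sqw * (model[keep] - target),
    fitted_series = model, times = times, note = model_mode)
}

#' Early-exponential growth-rate estimate
#'
#' Ordinary least-squares slope of `log(mean density)` against time over the
#' first `n_points` samples: the conventional exponential-phase rate
#' estimate, which sees only the low-density limit of the logistic model.
#'
#' @param dataset a [growth_dataset()].
#' @param n_points number of initial time points to use (default 6).
#' @return The exponential rate in 1/h.
#' @export
fit_exponential_rate <- function(dataset, n_points = 6) {
  stopifnot(inherits(dataset, "growth_dataset"))
  if (n_points < 2L) stop("n_points must be at least 2")
  if (length(dataset$times) < n_points)
    stop("dataset has fewer than n_points time points")
  idx <- seq_len(n_points)
  m <- colMeans(dataset$counts)[idx]
  unname(coef(lm(log(m) ~ dataset$times[idx]))[2])
}

#' Unweighted logistic (r, k) fit to a whole growth series
#'
#' Fits the closed-form logistic curve to the replicate-mean series by
#' plain (unweighted) nonlinear least squares over the initial density,
#' rate `r` and capacity `k` jointly — the conventional whole-curve summary
#' fit, deliberately distinct from the weighted fixed-`N(0)` calibration of
#' [fit_rate_capacity()]. A series that sits at carrying capacity
#' throughout pins `k` at the data level but leaves `r` unidentifiable,
#' which is flagged.
#'
#' @param dataset a [growth_dataset()] with at least 4 time points.
#' @return A `growth_fit` with estimates `n0`, `r`, `k`.
#' @export
fit_logistic_rk <- function(dataset) {
  stopifnot(inherits(dataset, "growth_dataset"))
  if (length(dataset$times) < 4L)
    stop("at least 4 time points are required")
  m <- colMeans(dataset$counts)
  times <- dataset$times
  if (diff(range(m)) / mean(m) < 1e-8) {
    return(new_fit_result(
      estimates = c(n0 = m[[1]], r = NA_real_, k = mean(m)),
      fixed = numeric(0), wssr = sum((m - mean(m))^2),
      n_points = length(m), converged = FALSE,
      fitted_series = rep(mean(m), length(m)), times = times,
      note = "series flat at carrying capacity; r unidentifiable"))
  }
  lo <- c(log10(min(m) / 100), 1e-3, log10(max(m) / 10))
  hi <- c(log10(max(m) * 100), 5, 12)
  resid_fun <- function(p)
    logistic_closed_form(10^p[1], p[2], 10^p[3], times) - m
  starts <- cbind(log10_n0 = rep(log10(m[[1]]), 5),
                  r = c(0.2, 0.6, 1, 1.8, 2.6),
                  log10_k = rep(log10(max(m)), 5))
  for (j in 1:3) starts[, j] <- pmin(pmax(starts[, j], lo[j]), hi[j])
  fit <- lm_multistart(resid_fun, starts, lower = lo, upper = hi)
  est <- c(n0 = unname(10^fit$par[1]), r = unname(fit$par[2]),
           k = unname(10^fit$par[3]))
  model <- logistic_closed_form(est["n0"], est["r"], est["k"], times)
  new_fit_result(estimates = est, fixed = numeric(0),
                 wssr = sum(fit$fvec^2), n_points = length(m),
                 converged = lm_converged(fit),
                 residual_series = model - m, fitted_series = model,
                 times = times)
}

#' Fit the capacity latency and initial condition for one induction time
#'
#' With the four switched growth constants already calibrated and held
#' fixed, estimates the capacity latency `D` (and, jointly, the initial
#' condition `N(0)`) for a culture induced at `t_i`, by minimising the
#' weighted residual sum over k = 1..T of the discrete-time switched model
#' against the replicate-mean series. `D` is constrained nonnegative. The
#' joint fit of `N(0)` is well behaved here because the growth constants
#' are fixed, so the transient/stationary imbalance that motivates fixing
#' `N(0)` in [fit_rate_capacity()] does not arise.
#'
#' @param dataset a [growth_dataset()] for a culture induced at `t_i`.
#' @param t_i external induction time in hours.
#' @param params calibrated [growth_params()] (held fixed).
#' @param weighting,sd_floor_frac as in [fit_rate_capacity()].
#' @param delay_bounds box constraint on `D` in hours.
#' @return A `growth_fit` with estimates `n0` and `delay`, the four fixed
#'   growth constants, and `activation_density` (the modelled density at
#'   `t_i`) in its `note`-adjacent fields; see `$activation_density`.
#' @export
fit_delay <- function(dataset, t_i, params,
                      weighting = c("inverse_sd", "inverse_var"),
                      sd_floor_frac = 1e-3, delay_bounds = c(0, 24)) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(dataset, "growth_dataset"),
            inherits(params, "growth_params"),
            length(t_i) == 1L, is.finite(t_i), t_i >= 0)
  summ <- summarize_replicates(dataset, sd_floor_frac)
  w <- resid_weights(summ, weighting)
  times <- dataset$times
  dts <- diff(times)
  if (diff(range(dts)) > 1e-8)
    stop("fit_delay requires a uniform time grid")
  dt <- dts[1]
  horizon <- max(times)
  sched <- schedule_external(t_i)
  keep <- -1L
  sqw <- sqrt(w[keep])
  target <- summ$mean[keep]
  sim_dens <- function(n0, D)
    simulate_growth_discrete(params, sched, delay_constant(D), n0,
                             dt = dt, horizon = horizon)$density
  resid_fun <- function(p) sqw * (sim_dens(10^p[1], p[2])[keep] - target)
  n0_hat <- summ$mean[1]
  lo <- c(log10(n0_hat / 100), delay_bounds[1])
  hi <- c(log10(n0_hat * 100), delay_bounds[2])
  d_starts <- pmin(pmax(c(0, 2, 5, 10, 15), delay_bounds[1]),
                   delay_bounds[2])
  starts <- cbind(log10_n0 = rep(log10(n0_hat), length(d_starts)),
                  delay = d_starts)
  fit <- lm_multistart(resid_fun, starts, lower = lo, upper = hi)
  est <- c(n0 = unname(10^fit$par[1]), delay = unname(fit$par[2]))
  traj <- simulate_growth_discrete(params, sched,
                                   delay_constant(est[["delay"]]),
                                   est[["n0"]], dt = dt, horizon = horizon)
  out <- new_fit_result(
    estimates = est,
    fixed = unlist(params[c("lambda0", "lambda1", "kappa0", "kappa1")]),
    wssr = sum(fit$fvec^2), n_points = length(target),
    converged = lm_converged(fit),
    residual_series = sqw * (traj$density[keep] - target),
    fitted_series = traj$density, times = times)
  out$activation_density <- traj$activation_density
  out$t_i <- t_i
  out
}

#' Default threshold-density search grid
#'
#' 60 log-spaced densities spanning 1e5 to 1e9 CFU/mL, the dynamic range of
#' plate-count growth curves.
#' @return Numeric vector of candidate thresholds.
#' @export
default_alpha_grid <- function() 10^seq(5, 9, length.out = 60)

#' Estimate the quorum-sensing activation threshold by residual scan
#'
#' For each candidate threshold `alpha`, simulates the quorum-sensing model
#' (activation the moment the density first reaches `alpha`, located in
#' closed form on the pre-activation logistic) from the fixed initial
#' condition (mean of the first samples), samples it on the data grid, and
#' computes the weighted residual sum against the replicate-mean series.
#' Returns the grid minimiser and the full residual curve. The scan is a
#' deterministic grid rather than a continuous optimiser: the objective is
#' non-smooth in `alpha` (flat wherever candidate thresholds are already
#' exceeded at inoculation, kinked where the crossing moves across data
#' points), so a reproducible grid plus the smaller-threshold tie rule is
#' more robust than gradient-based search.
#'
#' @param qs_dataset a [growth_dataset()] for the quorum-sensing condition.
#' @param params calibrated [growth_params()].
#' @param delay_fn a [delay_function()]; use [delay_zero()] for the pure
#'   indicator-threshold model without capacity latency.
#' @param alpha_grid sorted positive candidate thresholds (CFU/mL).
#' @param weighting,sd_floor_frac as in [fit_rate_capacity()].
#' @return A list of class `threshold_fit`: `alpha_star`, `wssr_curve`
#'   (data frame `alpha`, `wssr`), `n0`, and the index of the minimiser.
#' @export
fit_threshold <- function(qs_dataset, params, delay_fn = delay_zero(),
                          alpha_grid = default_alpha_grid(),
                          weighting = c("inverse_sd", "inverse_var"),
                          sd_floor_frac = 1e-3) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(qs_dataset, "growth_dataset"),
            inherits(params, "growth_params"),
            inherits(delay_fn, "delay_function"))
  if (length(alpha_grid) < 1L) stop("alpha_grid must be nonempty")
  if (any(alpha_grid <= 0)) stop("alpha_grid must be positive")
  if (is.unsorted(alpha_grid, strictly = TRUE))
    stop("alpha_grid must be sorted increasing")
  summ <- summarize_replicates(qs_dataset, sd_floor_frac)
  w <- resid_weights(summ, weighting)
  times <- qs_dataset$times
  n0 <- summ$mean[1]
  keep <- -1L
  wk <- w[keep]
  target <- summ$mean[keep]
  wssr <- vapply(alpha_grid, function(a) {
    dens <- simulate_growth(params, schedule_qs(a), delay_fn, n0,
                            t_grid = times)$density
    sum(wk * (dens[keep] - target)^2)
  }, numeric(1))
  i_min <- which.min(wssr)  # first minimum = smallest alpha on ties
  structure(list(alpha_star = alpha_grid[i_min],
                 wssr_curve = data.frame(alpha = alpha_grid, wssr = wssr),
                 index = i_min, n0 = n0),
            class = "threshold_fit")
}

#' @export
print.threshold_fit <- function(x, ...) {
  cat(sprintf(
    "Threshold scan: alpha* = %.4g CFU/mL (wssr %.6g over %d candidates)\n",
    x$alpha_star, x$wssr_curve$wssr[x$index], nrow(x$wssr_curve)))
  invisible(x)
}

#' Fit the hinge latency function to (activation density, delay) estimates
#'
#' Least-squares fit of a two-segment hinge `D(N) = s * max(0, N - n_break)`
#' with `s >= 0` to per-induction-time delay estimates: no latency up to a
#' breakpoint density, linearly growing latency above it. The breakpoint is
#' profiled over the observed density range (coarse grid then local
#' refinement); for each candidate breakpoint the optimal slope has a
#' closed form. If all delays are zero the trivial zero function is
#' returned with the breakpoint at the largest observed density.
#'
#' @param density activation densities (CFU/mL), at least 2.
#' @param delay estimated latencies (hours), same length.
#' @return A [delay_function()] with attributes `n_break`, `slope` and
#'   `sse` (residual sum of squares of the fit).
#' @export
fit_delay_function <- function(density, delay) {
  if (is.data.frame(density)) {
    delay <- density$delay
    density <- density$density
  }
  stopifnot(is.numeric(density), is.numeric(delay),
            length(density) == length(delay), length(density) >= 2L)
  if (any(density <= 0)) stop("densities must be positive")
  if (any(delay < 0)) stop("delays must be nonnegative")
  ord <- order(density)
  density <- density[ord]
  delay <- delay[ord]
  if (all(delay == 0)) {
    fn <- delay_function(max(density), 0)
    attr(fn, "n_break") <- max(density)
    attr(fn, "slope") <- 0
    attr(fn, "sse") <- 0
    return(fn)
  }
  sse_at <- function(b) {
    x <- pmax(0, density - b)
    sxx <- sum(x^2)
    s <- if (sxx > 0) max(0, sum(x * delay) / sxx) else 0
    sum((delay - s * x)^2)
  }
  lo <- min(density) / 2
  hi <- max(density)
  cand <- exp(seq(log(lo), log(hi), length.out = 400))
  sse <- vapply(cand, sse_at, numeric(1))
  i <- which.min(sse)
  bracket <- c(cand[max(1, i - 1)], cand[min(length(cand), i + 1)])
  opt <- optimize(sse_at, interval = bracket, tol = 1e-7 * hi)
  b <- if (opt$objective <= sse[i]) opt$minimum else cand[i]
  x <- pmax(0, density - b)
  s <- if (sum(x^2) > 0) max(0, sum(x * delay) / sum(x^2)) else 0
  fn <- delay_hinge(b, s)
  attr(fn, "sse") <- sse_at(b)
  fn
}
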