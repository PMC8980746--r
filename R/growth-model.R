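#' Switched logistic growth parameters
#'
#' The modified logistic model has two parameter regimes: before activation
#' of public-good production the population grows at intrinsic rate
#' `lambda0` toward carrying capacity `kappa0`; after activation the rate
#' drops to `lambda1` (the metabolic cost of producing the good) while the
#' carrying capacity rises to `kappa1` (the benefit of the extra nutrients
#' the good liberates), the capacity change possibly lagging activation
#' (see [delay_function()]).
#'
#' @param lambda0 pre-activation intrinsic growth rate (1/h).
#' @param lambda1 post-activation intrinsic growth rate (1/h).
#' @param kappa0 pre-activation carrying capacity (CFU/mL).
#' @param kappa1 post-activation carrying capacity (CFU/mL).
#' @param warn warn (once) if the cost/benefit orientation
#'   `lambda1 <= lambda0`, `kappa1 >= kappa0` does not hold. The model is
#'   still well defined either way.
#' @return An object of class `growth_params`.
#' @examples
#' growth_params(0.9, 0.45, 1.2e8, 8e8)
#' @export
growth_params <- function(lambda0, lambda1 = lambda0, kappa0, kappa1 = kappa0,
                          warn = TRUE) {
  vals <- c(lambda0 = lambda0, lambda1 = lambda1,
            kappa0 = kappa0, kappa1 = kappa1)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("all growth parameters must be finite and strictly positive")
  obj <- structure(as.list(vals), class = "growth_params")
  if (warn) validate_growth_params(obj)
  obj
}

#' Check the cost/benefit orientation of growth parameters
#'
#' Warns (does not error) when the parameters do not describe a costly
#' public good with a capacity benefit, i.e. when `lambda1 > lambda0` or
#' `kappa1 < kappa0`.
#'
#' @param params a [growth_params()] object.
#' @return `TRUE` invisibly if the orientation holds, `FALSE` otherwise.
#' @export
validate_growth_params <- function(params) {
  stopifnot(inherits(params, "growth_params"))
  ok <- TRUE
  if (params$lambda1 > params$lambda0) {
    warning("lambda1 > lambda0: activation speeds up growth; ",
            "the public good carries no rate cost", call. = FALSE)
    ok <- FALSE
  }
  if (params$kappa1 < params$kappa0) {
    warning("kappa1 < kappa0: activation lowers the carrying capacity; ",
            "the public good carries no capacity benefit", call. = FALSE)
    ok <- FALSE
  }
  invisible(ok)
}

#' @export
print.growth_params <- function(x, ...) {
  cat("Switched logistic growth parameters\n")
  cat(sprintf("  lambda0 = %.4g 1/h   kappa0 = %.4g CFU/mL  (pre-activation)\n",
              x$lambda0, x$kappa0))
  cat(sprintf("  lambda1 = %.4g 1/h   kappa1 = %.4g CFU/mL  (post-activation)\n",
              x$lambda1, x$kappa1))
  invisible(x)
}

#' Control schedules for public-good activation
#'
#' Activation of public-good production is driven by one of three control
#' policies: `schedule_never()` (the good is never produced; plain logistic
#' growth at `lambda0`, `kappa0`), `schedule_external(t_induction)` (a
#' saturating dose of autoinducer is added at a chosen time, as for
#' externally induced cultures), or `schedule_qs(alpha)` (quorum sensing:
#' production switches on the first time the population density reaches the
#' threshold `alpha`).
#'
#' @param t_induction induction time in hours (`>= 0`).
#' @param alpha quorum threshold density in CFU/mL (`> 0`).
#' @return An object of class `control_schedule`.
#' @examples
#' schedule_never()
#' schedule_external(5)
#' schedule_qs(5.3e7)
#' @export
schedule_never <- function() {
  structure(list(mode = "never"), class = "control_schedule")
}

#' @rdname schedule_never
#' @export
schedule_external <- function(t_induction) {
  stopifnot(length(t_induction) == 1L, is.finite(t_induction),
            t_induction >= 0)
  structure(list(mode = "external", t_induction = as.numeric(t_induction)),
            class = "control_schedule")
}

#' @rdname schedule_never
#' @export
schedule_qs <- function(alpha) {
  stopifnot(length(alpha) == 1L, is.finite(alpha), alpha > 0)
  structure(list(mode = "qs", alpha = as.numeric(alpha)),
            class = "control_schedule")
}

#' @export
print.control_schedule <- function(x, ...) {
  switch(x$mode,
    never = cat("Control schedule: never activated\n"),
    external = cat(sprintf(
      "Control schedule: external induction at t_i = %.3g h\n", x$t_induction)),
    qs = cat(sprintf(
      "Control schedule: quorum sensing, threshold alpha = %.4g CFU/mL\n",
      x$alpha)))
  invisible(x)
}

#' Intrinsic growth rate under the activation switch
#'
#' The rate switch is instantaneous: `lambda0` before activation, `lambda1`
#' after.
#'
#' @param params a [growth_params()] object.
#' @param activated logical (vectorised).
#' @return Growth rate(s) in 1/h.
#' @export
growth_rate <- function(params, activated) {
  stopifnot(inherits(params, "growth_params"), is.logical(activated),
            !anyNA(activated))
  ifelse(activated, params$lambda1, params$lambda0)
}

#' Time-varying carrying capacity during the latency ramp
#'
#' After activation at time `t_i` with population `n_at_ti`, the carrying
#' capacity climbs linearly from `kappa0` to `kappa1` over the latency
#' `D(n_at_ti)` given by `delay_fn`, and stays at `kappa1` afterwards.
#' Before `t_i` it is `kappa0`. With zero latency the capacity steps
#' directly to `kappa1` at `t_i`.
#'
#' @param t time(s) in hours at which to evaluate the capacity.
#' @param t_i activation time in hours (`>= 0`).
#' @param n_at_ti population density at activation (CFU/mL, `> 0`).
#' @param params a [growth_params()] object.
#' @param delay_fn a [delay_function()].
#' @return Carrying capacity in CFU/mL, one value per `t`, continuous in `t`
#'   whenever the latency is positive.
#' @export
capacity_at <- function(t, t_i, n_at_ti, params, delay_fn = delay_zero()) {
  stopifnot(inherits(params, "growth_params"), is.numeric(t),
            length(t_i) == 1L, length(n_at_ti) == 1L)
  if (!all(is.finite(t)) || !is.finite(t_i) || !is.finite(n_at_ti))
    stop("non-finite inputs")
  if (t_i < 0) stop("t_i must be >= 0")
  if (n_at_ti <= 0) stop("n_at_ti must be positive")
  D <- delay_at(delay_fn, n_at_ti)
  capacity_profile(t, t_i, D, params$kappa0, params$kappa1)
}

## kappa(t) for a frozen latency D (vectorised over t)
capacity_profile <- function(t, t_act, D, kappa0, kappa1) {
  if (is.na(t_act)) return(rep(kappa0, length(t)))
  out <- rep(kappa1, length(t))
  out[t < t_act] <- kappa0
  if (D > 0) {
    ramp <- t >= t_act & t <= t_act + D
    out[ramp] <- kappa0 + (kappa1 - kappa0) * (t[ramp] - t_act) / D
  }
  out
}

#' Closed-form logistic growth curve
#'
#' The textbook solution `N(t) = n0 k / (n0 + (k - n0) exp(-r t))` of the
#' logistic equation with constant rate `r` and capacity `k`. This is both
#' the no-switch limit of the full model and the curve fitted to whole
#' growth series by [fit_logistic_rk()].
#'
#' @param n0 initial density (CFU/mL, `> 0`).
#' @param r intrinsic growth rate (1/h).
#' @param k carrying capacity (CFU/mL, `> 0`).
#' @param t time(s) in hours.
#' @return Density in CFU/mL, one value per `t`; monotone toward `k`.
#' @examples
#' logistic_closed_form(1e6, 0.9, 1.2e8, 0:24)
#' @export
logistic_closed_form <- function(n0, r, k, t) {
  stopifnot(length(n0) == 1L, length(r) == 1L, length(k) == 1L)
  if (!is.finite(n0) || !is.finite(r) || !is.finite(k) || !all(is.finite(t)))
    stop("non-finite inputs")
  if (n0 <= 0) stop("n0 must be positive")
  if (k <= 0) stop("k must be positive")
  n0 * k / (n0 + (k - n0) * exp(-r * t))
}

## one exact logistic step of length dt with constant (r, k)
logistic_step <- function(n, r, k, dt) {
  n * k / (n + (k - n) * exp(-r * dt))
}

## Activation event under a schedule, on the exact pre-activation logistic.
## Returns NULL if the switch never fires before `horizon`, else
## list(t_act, n_act, D). For QS the threshold crossing is solved in closed
## form from the logistic solution, so it does not depend on any grid.
activation_event <- function(params, schedule, delay_fn, n0, horizon) {
  mode <- schedule$mode
  if (mode == "never") return(NULL)
  if (mode == "external") {
    t_i <- schedule$t_induction
    if (t_i > horizon) return(NULL)
    n_act <- logistic_closed_form(n0, params$lambda0, params$kappa0, t_i)
    return(list(t_act = t_i, n_act = n_act, D = delay_at(delay_fn, n_act)))
  }
  ## quorum sensing
  alpha <- schedule$alpha
  if (n0 >= alpha)
    return(list(t_act = 0, n_act = n0, D = delay_at(delay_fn, n0)))
  k0 <- params$kappa0
  ratio <- n0 * (k0 - alpha) / (alpha * (k0 - n0))
  if (!is.finite(ratio) || ratio <= 0) return(NULL)  # threshold unreachable
  t_act <- -log(ratio) / params$lambda0
  if (t_act > horizon) return(NULL)
  list(t_act = t_act, n_act = alpha, D = delay_at(delay_fn, alpha))
}

## integrate through the capacity ramp from (t_from, n) to t_to using exact
## logistic substeps with kappa frozen at each substep midpoint
integrate_ramp <- function(n, t_from, t_to, t_act, D, params, ramp_step,
                           floor_density) {
  if (t_to <= t_from) return(n)
  nstep <- max(1L, ceiling((t_to - t_from) / ramp_step))
  h <- (t_to - t_from) / nstep
  k0 <- params$kappa0
  dk <- params$kappa1 - k0
  lam <- params$lambda1
  for (i in seq_len(nstep)) {
    tm <- t_from + (i - 0.5) * h
    kap <- k0 + dk * (tm - t_act) / D
    n <- max(logistic_step(n, lam, kap, h), floor_density)
  }
  n
}

new_trajectory <- function(times, density, capacity, activation_time = NA_real_,
                           activation_density = NA_real_, delay = NA_real_) {
  structure(list(times = times, density = density, capacity = capacity,
                 activation_time = activation_time,
                 activation_density = activation_density,
                 delay = delay),
            class = "growth_trajectory")
}

#' Simulate the switched logistic growth model
#'
#' Integrates the modified logistic equation in which activation (per the
#' control `schedule`) instantaneously switches the intrinsic rate from
#' `lambda0` to `lambda1` and starts a linear carrying-capacity ramp from
#' `kappa0` to `kappa1` over the latency `D(N(t_act))`, with `D` evaluated
#' once at activation and frozen. If the density exceeds the current
#' capacity (possible during the ramp or after a parameter switch), growth
#' is negative and the density declines toward the capacity.
#'
#' Three integrators are available. `"piecewise_closed_form"` (default)
#' composes exact logistic solutions on the constant-parameter phases and
#' resolves the activation time analytically, using short exact substeps
#' with midpoint-frozen capacity across the ramp; it is exact outside the
#' ramp. `"fine_rk"` is a fixed-step fourth-order Runge-Kutta integrator
#' and `"euler"` a fixed-step forward-Euler integrator, both with threshold
#' crossings refined within the bracketing step; they serve as independent
#' numerical checks.
#'
#' @param params a [growth_params()] object.
#' @param schedule a [schedule_never()], [schedule_external()] or
#'   [schedule_qs()] control policy.
#' @param delay_fn a [delay_function()] giving the capacity latency as a
#'   function of activation density.
#' @param n0 initial density (CFU/mL, `> 0`).
#' @param t_grid strictly increasing times (hours) starting at 0 at which
#'   the trajectory is reported.
#' @param method integrator, see Details.
#' @param step fixed step (h) for the `fine_rk` and `euler` integrators.
#' @param ramp_step substep (h) used across the capacity ramp by the
#'   piecewise integrator.
#' @param floor_density densities are floored at this value (CFU/mL) to
#'   preserve positivity under extreme parameters.
#' @return A `growth_trajectory`: times, densities, the capacity series
#'   `kappa(t)`, and the realised activation time/density and latency
#'   (`NA` if the switch never fired).
#' @examples
#' p <- growth_params(0.9, 0.45, 1.2e8, 8e8)
#' simulate_growth(p, schedule_qs(5.3e7), delay_hinge(1e7, 5 / 9e7),
#'                 n0 = 1e6, t_grid = 0:24)
#' @export
simulate_growth <- function(params, schedule, delay_fn = delay_zero(), n0,
                            t_grid,
                            method = c("piecewise_closed_form", "fine_rk",
                                       "euler"),
                            step = 1e-3, ramp_step = 0.01, floor_density = 1) {
  method <- match.arg(method)
  stopifnot(inherits(params, "growth_params"),
            inherits(schedule, "control_schedule"),
            inherits(delay_fn, "delay_function"),
            length(n0) == 1L, is.finite(n0), n0 > 0,
            is.numeric(t_grid), length(t_grid) >= 1L, all(is.finite(t_grid)))
  if (t_grid[1] != 0) stop("t_grid must start at 0")
  if (is.unsorted(t_grid, strictly = TRUE))
    stop("t_grid must be strictly increasing")
  if (method == "piecewise_closed_form")
    sim_piecewise(params, schedule, delay_fn, n0, t_grid, ramp_step,
                  floor_density)
  else
    sim_stepper(params, schedule, delay_fn, n0, t_grid, step,
                scheme = if (method == "fine_rk") "rk4" else "euler",
                floor_density = floor_density)
}

sim_piecewise <- function(params, schedule, delay_fn, n0, t_grid, ramp_step,
                          floor_density) {
  horizon <- t_grid[length(t_grid)]
  act <- activation_event(params, schedule, delay_fn, n0, horizon)
  dens <- numeric(length(t_grid))
  if (is.null(act)) {
    dens <- logistic_closed_form(n0, params$lambda0, params$kappa0, t_grid)
    dens <- pmax(dens, floor_density)
    return(new_trajectory(t_grid, dens,
                          rep(params$kappa0, length(t_grid))))
  }
  t_act <- act$t_act; D <- act$D; n_act <- act$n_act
  t_end <- t_act + D
  pre <- t_grid <= t_act
  dens[pre] <- logistic_closed_form(n0, params$lambda0, params$kappa0,
                                    t_grid[pre])
  in_ramp <- t_grid > t_act & t_grid <= t_end
  t_cur <- t_act
  n_cur <- n_act
  for (idx in which(in_ramp)) {
    n_cur <- integrate_ramp(n_cur, t_cur, t_grid[idx], t_act, D, params,
                            ramp_step, floor_density)
    t_cur <- t_grid[idx]
    dens[idx] <- n_cur
  }
  n_end <- if (D > 0)
    integrate_ramp(n_cur, t_cur, t_end, t_act, D, params, ramp_step,
                   floor_density)
  else n_act
  post <- t_grid > t_end
  dens[post] <- logistic_closed_form(n_end, params$lambda1, params$kappa1,
                                     t_grid[post] - t_end)
  dens <- pmax(dens, floor_density)
  cap <- capacity_profile(t_grid, t_act, D, params$kappa0, params$kappa1)
  new_trajectory(t_grid, dens, cap, t_act, n_act, D)
}

## fixed-step integrator (RK4 or forward Euler) with event handling:
## external switches split the step sequence, QS crossings are refined by
## linear interpolation within the bracketing step
sim_stepper <- function(params, schedule, delay_fn, n0, t_grid, step, scheme,
                        floor_density) {
  lambda0 <- params$lambda0; lambda1 <- params$lambda1
  kappa0 <- params$kappa0; kappa1 <- params$kappa1
  mode <- schedule$mode
  alpha <- if (mode == "qs") schedule$alpha else Inf
  t_pend <- if (mode == "external") schedule$t_induction else Inf

  activated <- FALSE
  t_act <- NA_real_; n_act <- NA_real_; D <- NA_real_; t_end <- Inf

  activate <- function(t, n) {
    activated <<- TRUE
    t_act <<- t; n_act <<- n
    D <<- delay_at(delay_fn, n)
    t_end <<- t + D
  }
  if (mode == "external" && t_pend <= 0) activate(0, n0)
  if (mode == "qs" && n0 >= alpha) activate(0, n0)

  deriv <- function(t, n) {
    if (activated && t >= t_act) {
      kap <- if (D > 0 && t < t_end)
        kappa0 + (kappa1 - kappa0) * (t - t_act) / D
      else kappa1
      lambda1 * n * (1 - n / kap)
    } else {
      lambda0 * n * (1 - n / kappa0)
    }
  }
  take_step <- function(t, n, h) {
    if (scheme == "rk4") {
      k1 <- deriv(t, n)
      k2 <- deriv(t + h / 2, n + h * k1 / 2)
      k3 <- deriv(t + h / 2, n + h * k2 / 2)
      k4 <- deriv(t + h, n + h * k3)
      n + h * (k1 + 2 * k2 + 2 * k3 + k4) / 6
    } else {
      n + h * deriv(t, n)
    }
  }

  dens <- numeric(length(t_grid))
  dens[1] <- n0
  t_cur <- t_grid[1]
  n_cur <- n0
  eps <- 1e-12
  for (i_out in seq_along(t_grid)[-1]) {
    t_target <- t_grid[i_out]
    while (t_cur < t_target - eps) {
      b <- t_target
      if (!activated && mode == "external" && t_pend > t_cur)
        b <- min(b, t_pend)
      if (activated && is.finite(t_end) && t_end > t_cur)
        b <- min(b, t_end)
      h <- min(step, b - t_cur)
      n_new <- take_step(t_cur, n_cur, h)
      t_new <- t_cur + h
      if (!activated && mode == "qs" && n_new >= alpha) {
        frac <- if (n_new > n_cur) (alpha - n_cur) / (n_new - n_cur) else 0
        frac <- min(max(frac, 0), 1)
        t_x <- t_cur + frac * h
        n_x <- if (frac > 0) take_step(t_cur, n_cur, frac * h) else n_cur
        activate(t_x, n_x)
        n_new <- if (t_new > t_x + eps) take_step(t_x, n_x, t_new - t_x)
                 else n_x
      }
      n_new <- max(n_new, floor_density)
      if (!activated && mode == "external" && abs(t_new - t_pend) <= eps)
        activate(t_new, n_new)
      t_cur <- t_new
      n_cur <- n_new
    }
    dens[i_out] <- n_cur
  }
  cap <- capacity_profile(t_grid, t_act, if (is.na(D)) 0 else D,
                          kappa0, kappa1)
  new_trajectory(t_grid, dens, cap, t_act, n_act, D)
}

#' Discrete-time simulation of the switched logistic model
#'
#' Propagates the population over a uniform grid of step `dt`, holding the
#' rate and capacity constant within each step — the rate at its step-start
#' value, the capacity at its step-midpoint value (second-order accurate
#' across the latency ramp) — and applying either the exact logistic update
#' for the frozen parameters (`scheme = "closed_form"`, default) or a
#' forward-Euler update.
#' This is the discrete-time approximation used by the calibration stages:
#' activation fires at the first grid time at or past the induction time
#' (external mode) or at the first grid time where the density has reached
#' the threshold (QS mode), and the latency `D` is evaluated at the
#' activation-step density and frozen.
#'
#' With constant parameters (no switch) the closed-form update is exact at
#' every grid point for any `dt`.
#'
#' @inheritParams simulate_growth
#' @param dt step length in hours (`> 0`).
#' @param horizon final time in hours; must be a whole multiple of `dt`.
#' @param scheme per-step update rule.
#' @return A `growth_trajectory` on the grid `seq(0, horizon, by = dt)`.
#' @export
simulate_growth_discrete <- function(params, schedule,
                                     delay_fn = delay_zero(), n0, dt, horizon,
                                     scheme = c("closed_form", "euler"),
                                     floor_density = 1) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(params, "growth_params"),
            inherits(schedule, "control_schedule"),
            inherits(delay_fn, "delay_function"),
            length(n0) == 1L, is.finite(n0), n0 > 0,
            length(dt) == 1L, is.finite(dt))
  if (dt <= 0) stop("dt must be positive")
  nsteps <- round(horizon / dt)
  if (abs(nsteps * dt - horizon) > 1e-8 * max(1, horizon))
    stop("horizon must be a whole multiple of dt")
  times <- seq(0, by = dt, length.out = nsteps + 1L)
  mode <- schedule$mode
  dens <- numeric(nsteps + 1L)
  dens[1] <- n0
  activated <- FALSE
  t_act <- NA_real_; n_act <- NA_real_; D <- NA_real_
  for (k in seq_len(nsteps)) {
    t_k <- times[k]
    if (!activated) {
      fire <- switch(mode,
        never = FALSE,
        external = t_k >= schedule$t_induction - 1e-9,
        qs = dens[k] >= schedule$alpha)
      if (fire) {
        activated <- TRUE
        t_act <- t_k
        n_act <- dens[k]
        D <- delay_at(delay_fn, n_act)
      }
    }
    if (activated) {
      lam <- params$lambda1
      # capacity frozen at the step midpoint: second-order accurate across
      # the ramp, exact whenever the capacity is constant within the step
      kap <- capacity_profile(t_k + dt / 2, t_act, D,
                              params$kappa0, params$kappa1)
    } else {
      lam <- params$lambda0
      kap <- params$kappa0
    }
    n_next <- if (scheme == "closed_form")
      logistic_step(dens[k], lam, kap, dt)
    else
      dens[k] + dt * lam * dens[k] * (1 - dens[k] / kap)
    dens[k + 1L] <- max(n_next, floor_density)
  }
  cap <- capacity_profile(times, t_act, if (is.na(D)) 0 else D,
                          params$kappa0, params$kappa1)
  new_trajectory(times, dens, cap, t_act, n_act, D)
}

#' @export
print.growth_trajectory <- function(x, ...) {
  cat(sprintf("Growth trajectory: %d points over %.3g-%.3g h\n",
              length(x$times), min(x$times), max(x$times)))
  cat(sprintf("  density %.4g -> %.4g CFU/mL\n",
              x$density[1], x$density[length(x$density)]))
  if (!is.na(x$activation_time))
    cat(sprintf(
      "  activated at t = %.4g h (N = %.4g CFU/mL), capacity latency %.4g h\n",
      x$activation_time, x$activation_density, x$delay))
  else cat("  never activated\n")
  invisible(x)
}

#' @export
as.data.frame.growth_trajectory <- function(x, ...) {
  data.frame(time_h = x$times,
             density_cfu_per_ml = x$density,
             capacity_cfu_per_ml = x$capacity)
}

#' Plot a growth trajectory
#'
#' Density (solid) and carrying capacity (dashed) against time on a log
#' scale, with the activation time marked.
#' @param x a `growth_trajectory`.
#' @param ... passed to [plot()].
#' @return `x` invisibly.
#' @export
plot.growth_trajectory <- function(x, ...) {
  plot(x$times, x$density, type = "l", log = "y",
       xlab = "time (h)", ylab = "density (CFU/mL)", ...)
  lines(x$times, x$capacity, lty = 2)
  if (!is.na(x$activation_time))
    abline(v = x$activation_time, col = "grey50", lty = 3)
  invisible(x)
}
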