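test_that("capacity ramp: kappa0 before induction, linear ramp, kappa1 after", {
  p <- default_params()
  dfn <- delay_hinge(1e7, 5 / 9e7)  # D(1e8) = 5 h
  expect_equal(capacity_at(3, t_i = 5, n_at_ti = 1e8, p, dfn), p$kappa0)
  # midpoint of the ramp is the mid-capacity
  expect_equal(capacity_at(5 + 2.5, t_i = 5, n_at_ti = 1e8, p, dfn),
               (p$kappa0 + p$kappa1) / 2)
  expect_equal(capacity_at(5 + 5 + 1e-9, t_i = 5, n_at_ti = 1e8, p, dfn),
               p$kappa1)
  # zero delay: step straight to kappa1
  expect_equal(capacity_at(5.001, t_i = 5, n_at_ti = 1e6, p, dfn), p$kappa1)
  # continuity at the ramp ends
  ts <- c(5 - 1e-9, 5, 5 + 1e-9)
  caps <- capacity_at(ts, 5, 1e8, p, dfn)
  expect_lt(diff(range(caps)), 1)
  expect_error(capacity_at(NaN, 5, 1e8, p, dfn), "finite")
  expect_error(capacity_at(3, 5, -1, p, dfn), "positive")
})

test_that("rate switch is instantaneous and degenerate when costless", {
  p <- default_params()
  expect_equal(growth_rate(p, FALSE), p$lambda0)
  expect_equal(growth_rate(p, TRUE), p$lambda1)
  q <- growth_params(0.7, 0.7, 1e8, 1e8)
  expect_equal(growth_rate(q, TRUE), growth_rate(q, FALSE))
})

test_that("parameter validation warns on inverted cost/benefit orientation", {
  expect_warning(growth_params(0.4, 0.9, 1e8, 8e8), "lambda1 > lambda0")
  expect_warning(growth_params(0.9, 0.4, 8e8, 1e8), "kappa1 < kappa0")
  expect_error(growth_params(0.9, 0.4, -1e8, 8e8), "positive")
  expect_silent(growth_params(0.9, 0.45, 1.2e8, 8e8))
})

test_that("closed-form logistic matches a brute-force RK4 integration", {
  # fixed point and initial condition
  expect_equal(logistic_closed_form(1e8, 0.5, 1e8, c(0, 3, 10)),
               rep(1e8, 3))
  expect_equal(logistic_closed_form(1e6, 0.5, 1e8, 0), 1e6)
  expect_error(logistic_closed_form(1e6, 0.5, 0, 1), "positive")
  # independent oracle: RK4 at step 1e-3 on dN/dt = r N (1 - N/k)
  r <- 0.5; k <- 1e8; n <- 1e6; h <- 1e-3
  f <- function(x) r * x * (1 - x / k)
  for (i in seq_len(10 / h)) {
    k1 <- f(n); k2 <- f(n + h * k1 / 2)
    k3 <- f(n + h * k2 / 2); k4 <- f(n + h * k3)
    n <- n + h * (k1 + 2 * k2 + 2 * k3 + k4) / 6
  }
  expect_lt(abs(logistic_closed_form(1e6, r, k, 10) - n) / n, 1e-6)
})

test_that("no-switch and always-on simulations reduce to the plain logistic", {
  p <- default_params()
  tg <- 0:24
  off <- simulate_growth(p, schedule_never(), default_delay_fn(), 1e6, tg)
  expect_lt(max_rel_err(off$density,
                        logistic_closed_form(1e6, p$lambda0, p$kappa0, tg)),
            1e-9)
  expect_true(is.na(off$activation_time))
  expect_equal(off$capacity, rep(p$kappa0, length(tg)))
  on <- simulate_growth(p, schedule_external(0), delay_zero(), 1e6, tg)
  expect_lt(max_rel_err(on$density,
                        logistic_closed_form(1e6, p$lambda1, p$kappa1, tg)),
            1e-9)
  expect_equal(on$activation_time, 0)
})

test_that("an unreachable quorum threshold never fires and plateaus at kappa0", {
  p <- default_params()
  tg <- 0:36
  tr <- simulate_growth(p, schedule_qs(2 * p$kappa0), default_delay_fn(),
                        1e6, tg)
  expect_true(is.na(tr$activation_time))
  expect_equal(tr$density[length(tg)], p$kappa0, tolerance = 1e-6)
  rk <- simulate_growth(p, schedule_qs(2 * p$kappa0), default_delay_fn(),
                        1e6, tg, method = "fine_rk")
  expect_lt(max_rel_err(tr$density, rk$density), 1e-3)
})

test_that("trajectory invariants hold: positivity, lengths, capacity series", {
  p <- default_params()
  tr <- simulate_growth(p, schedule_external(5), default_delay_fn(), 1e6,
                        seq(0, 24, 0.5))
  expect_true(all(tr$density > 0))
  expect_length(tr$capacity, length(tr$times))
  t_end <- tr$activation_time + tr$delay
  expect_true(all(tr$capacity[tr$times < tr$activation_time] == p$kappa0))
  expect_true(all(tr$capacity[tr$times > t_end] == p$kappa1))
  # after the ramp, approach to kappa1 is monotone
  post <- tr$density[tr$times > t_end]
  expect_true(all(diff(abs(post - p$kappa1)) <= 0))
})

test_that("collapsed parameters make all three schedules coincide", {
  q <- growth_params(0.8, 0.8, 2e8, 2e8)
  tg <- 0:24
  a <- simulate_growth(q, schedule_never(), delay_zero(), 1e6, tg)$density
  b <- simulate_growth(q, schedule_external(4), default_delay_fn(), 1e6,
                       tg)$density
  c <- simulate_growth(q, schedule_qs(5e7), default_delay_fn(), 1e6,
                       tg)$density
  expect_lt(max_rel_err(b, a), 1e-9)
  expect_lt(max_rel_err(c, a), 1e-9)
})

test_that("the delayed model converges to the instantaneous-switch model as D -> 0", {
  p <- default_params()
  tg <- 0:24
  ref <- simulate_growth(p, schedule_external(5), delay_zero(), 1e6,
                         tg)$density
  sup <- vapply(c(1, 0.1, 0.01, 0.001), function(scl) {
    dfn <- delay_hinge(1e7, scl * 5 / 9e7)
    max_rel_err(simulate_growth(p, schedule_external(5), dfn, 1e6,
                                tg)$density, ref)
  }, numeric(1))
  expect_true(all(diff(sup) < 0))
  expect_lt(sup[length(sup)], 1e-3)
})

test_that("QS activation density and time do not depend on the output grid", {
  p <- default_params()
  dfn <- default_delay_fn()
  coarse <- simulate_growth(p, schedule_qs(5.3e7), dfn, 1e6, seq(0, 24, 4))
  fine <- simulate_growth(p, schedule_qs(5.3e7), dfn, 1e6, seq(0, 24, 0.25))
  expect_equal(coarse$activation_time, fine$activation_time)
  expect_equal(coarse$activation_density, 5.3e7)
})

test_that("discrete propagation is exact for constant parameters at any step", {
  p <- default_params()
  for (dt in c(2, 1, 0.25)) {
    tr <- simulate_growth_discrete(p, schedule_never(), delay_zero(), 1e6,
                                   dt, 24)
    expect_equal(tr$density,
                 logistic_closed_form(1e6, p$lambda0, p$kappa0, tr$times))
  }
  # fixed point stays put
  cst <- simulate_growth_discrete(p, schedule_never(), delay_zero(),
                                  p$kappa0, 1, 24)
  expect_equal(cst$density, rep(p$kappa0, 25))
})

test_that("discrete trajectories converge under grid refinement", {
  p <- default_params()
  dfn <- default_delay_fn()
  d1 <- simulate_growth_discrete(p, schedule_external(5), dfn, 1e6, 1, 24)
  d2 <- simulate_growth_discrete(p, schedule_external(5), dfn, 1e6, 0.01, 24)
  idx <- match(d1$times, round(d2$times, 9))
  expect_lt(max_rel_err(d1$density, d2$density[idx]), 1e-2)
  expect_error(simulate_growth_discrete(p, schedule_never(), delay_zero(),
                                        1e6, -1, 24), "positive")
  expect_error(simulate_growth_discrete(p, schedule_never(), delay_zero(),
                                        1e6, 1, 24.5), "multiple")
})

test_that("discrete and continuous integrators agree when switches sit on the grid", {
  p <- default_params()
  tg <- 0:24
  disc <- simulate_growth_discrete(p, schedule_external(5), delay_zero(),
                                   1e6, 1, 24)
  cont <- simulate_growth(p, schedule_external(5), delay_zero(), 1e6, tg)
  expect_lt(max_rel_err(disc$density, cont$density), 1e-12)
})

test_that("simulation inputs are validated", {
  p <- default_params()
  expect_error(simulate_growth(p, schedule_never(), delay_zero(), 1e6,
                               c(1, 2, 3)), "start at 0")
  expect_error(simulate_growth(p, schedule_never(), delay_zero(), 1e6,
                               c(0, 2, 2)), "increasing")
  expect_error(simulate_growth(p, schedule_never(), delay_zero(), -5, 0:4))
  expect_error(schedule_external(-1))
  expect_error(schedule_qs(0))
})
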