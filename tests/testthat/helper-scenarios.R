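# shared fixtures: the default calibrated-regime scenario and small builders

default_params <- function() growth_params(0.9, 0.45, 1.2e8, 8e8)
default_delay_fn <- function() delay_hinge(1e7, 5 / 9e7)

# a triplicate dataset whose replicates all equal one noiseless trajectory
triplicate_of <- function(density, times, label = "synthetic",
                          induction_time = NA_real_) {
  growth_dataset(times, rbind(density, density, density),
                 label = label, induction_time = induction_time)
}

# random switched scenario for property tests (draws from the current RNG)
random_scenario <- function() {
  lambda0 <- runif(1, 0.3, 1.5)
  lambda1 <- runif(1, 0.1, lambda0)
  kappa0 <- 10^runif(1, 7.5, 8.5)
  kappa1 <- kappa0 * runif(1, 1.5, 8)
  n0 <- 10^runif(1, 5.5, 6.5)
  n_break <- 10^runif(1, 6.5, 7.5)
  slope <- runif(1, 0, 6) / (1e8 - n_break)
  schedule <- if (runif(1) < 0.5) schedule_external(runif(1, 0, 12))
    else schedule_qs(10^runif(1, 6.8, log10(kappa0 * 0.9)))
  list(params = growth_params(lambda0, lambda1, kappa0, kappa1),
       delay_fn = delay_hinge(n_break, slope),
       schedule = schedule, n0 = n0)
}

max_rel_err <- function(a, b) max(abs(a - b) / abs(b))
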