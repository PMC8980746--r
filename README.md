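# qsgrowth

Growth-curve analysis for bacterial populations that produce a costly
**public good** under quorum-sensing control.

Secreting a shared enzyme (the guiding example is an extracellular
α-amylase that digests starch into usable sugars) poses an intertemporal
trade-off for a batch culture: production diverts energy from division and
lowers the intrinsic growth rate *now*, while the nutrients the enzyme
liberates raise the carrying capacity *later*. `qsgrowth` implements a
modified logistic growth model for this situation, the staged
least-squares procedure that calibrates it to replicate colony-count
(CFU/mL) time series, and the relative-fitness analysis that locates the
optimal time — equivalently, the optimal population density — at which to
switch production on.

## The model

The population density N(t) follows a logistic law whose parameters switch
when production is activated:

    dN/dt = λ(t) N (1 − N/κ(t))

* λ = λ₀ before activation, λ₁ ≤ λ₀ after (the switch is instantaneous —
  the metabolic cost starts with expression);
* κ ramps linearly from κ₀ to κ₁ over a latency D(N(tₐ)) that depends on
  the population density at activation: no latency below a breakpoint
  density (the *no-delay window*), an increasingly long one above it;
* activation is driven by a control policy: `never`, `external`
  (induction at a chosen time tᵢ), or `qs` — quorum sensing abstracted as
  a density threshold α, activating the first time N ≥ α.

The payoff of a policy is the relative fitness
RF = mean over the experiment of N(t)/N_off(t), the induced-to-uninduced
density ratio; RF is sharply peaked in the induction time, and the package
locates that optimum both from data and from the calibrated model.

Calibration stages (all exposed individually, and chained by
`run_pipeline()`):

1. `fit_rate_capacity()` — weighted NLS for (λ, κ) per phase, weights
   1/SD of replicates, with N(0) **fixed** to the mean first sample so the
   decades-spanning series identifies rate and capacity simultaneously;
2. `fit_delay()` — joint (N(0), D) fit per induction time with the growth
   constants held fixed;
3. `fit_delay_function()` — hinge fit of latency vs activation density,
   estimating the no-delay boundary;
4. `fit_threshold()` — deterministic residual scan for the quorum
   threshold α*;
5. `empirical_fitness_scan()` / `model_fitness_scan()` /
   `optimal_induction()` — the fitness analysis.

A seeded synthetic-data generator (`experiment_scenario()`,
`generate_experiment()`) emulates triplicate hourly plate counts over
0–24 h with multiplicative lognormal noise, so the whole pipeline is
testable without any experimental download.

## Worked example

```r
library(qsgrowth)

## simulate a quorum-sensing culture in the default regime
p   <- growth_params(0.9, 0.45, 1.2e8, 8e8)     # λ0, λ1 (1/h), κ0, κ1 (CFU/mL)
dfn <- delay_hinge(1e7, 5 / 9e7)                # no delay below 1e7; 5 h at 1e8
simulate_growth(p, schedule_qs(5.3e7), dfn, n0 = 1e6, t_grid = 0:24)
#> Growth trajectory: 25 points over 0-24 h
#>   density 1e+06 -> 7.975e+08 CFU/mL
#>   activated at t = 5.05 h (N = 5.3e+07 CFU/mL), capacity latency 2.389 h

## generate a full synthetic experiment and calibrate it end to end
scenario   <- experiment_scenario(seed = 7,
  conditions = c(conditions_induction(), list(QS = schedule_qs(5.3e7))))
experiment <- generate_experiment(scenario)
run_pipeline(experiment)
#> Public-good growth analysis report
#>   lambda0 = 0.8965 1/h, kappa0 = 1.201e+08 CFU/mL
#>   lambda1 = 0.4468 1/h, kappa1 = 8.296e+08 CFU/mL
#>   delays fitted for 5 induction times
#>   no-delay boundary: 1.983e+07 CFU/mL
#>   quorum threshold alpha* = 4.406e+07 CFU/mL
#>   optimal induction (empirical): 5 h
#>   optimal induction (model): 5 h
```

Reading the report: the uninduced culture grows fast (λ₀ ≈ 0.90 1/h) to a
low plateau (κ₀ ≈ 1.2×10⁸ CFU/mL); the always-induced culture grows at
half the rate but reaches κ₁ ≈ 8×10⁸ CFU/mL. The latency analysis puts the
no-delay boundary at ~2×10⁷ CFU/mL, the threshold scan recovers the
generating quorum density (5.3×10⁷, grid resolution ~17%), and both the
measured and the model-predicted fitness curves peak for induction at 5 h
— activating right at the edge of the no-delay window maximises fitness.

Real data enter through the same path: per-condition CSVs
(`time_h,replicate,density_cfu_per_ml` long format, or wide
`time_h,rep1,rep2,...`) listed in a `label,file,role,induction_time`
manifest, read by `read_growth_csv()` / `read_manifest()`, and passed to
`run_pipeline()`.

## Documentation

The methods vignette, `vignettes/switched-logistic-growth.Rmd`, describes
the model and its assumptions, the integrators and their cross-checks, the
calibration conventions (weighting, the fixed-N(0) strategy, optimizer
bounds and multistarts), what the synthetic generator does and does not
emulate, and known limitations.
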