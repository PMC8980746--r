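#' Synthetic experiment scenario
#'
#' Bundles everything needed to emulate the plate-count experiments:
#' switched growth parameters, a capacity-latency function, the initial
#' density, the sampling grid (hourly over 0-24 h), the number of replicate
#' cultures (triplicates), the measurement noise level, the set of
#' experimental conditions, and a seed.
#'
#' The defaults place the system in the regime of quorum-sensing-regulated
#' amylase production in minimal medium: fast growth at 0.9 1/h toward a
#' low capacity of 1.2e8 CFU/mL without the public good, slowed growth at
#' 0.45 1/h toward 8e8 CFU/mL with it, no capacity latency below 1e7 CFU/mL
#' rising to 5 h at 1e8 CFU/mL, inoculation at 1e6 CFU/mL, and a 10%
#' coefficient of variation on counts. These are package defaults chosen to
#' exercise that dynamic range, not measured values.
#'
#' @param params a [growth_params()] object.
#' @param delay_fn a [delay_function()].
#' @param n0 initial density (CFU/mL).
#' @param times sampling times (h).
#' @param n_replicates replicate cultures per condition (`>= 1`).
#' @param noise_cv coefficient of variation of the multiplicative count
#'   noise (`>= 0`).
#' @param conditions named list of [control_schedule][schedule_never]
#'   objects, one per condition.
#' @param seed integer seed for reproducibility.
#' @return An object of class `experiment_scenario`.
#' @seealso [conditions_induction()], [conditions_strategies()],
#'   [generate_dataset()], [generate_experiment()]
#' @export
experiment_scenario <- function(params = growth_params(0.9, 0.45, 1.2e8, 8e8),
                                delay_fn = delay_hinge(1e7, 5 / 9e7),
                                n0 = 1e6, times = 0:24, n_replicates = 3,
                                noise_cv = 0.1,
                                conditions = conditions_induction(),
                                seed = 1L) {
  stopifnot(inherits(params, "growth_params"),
            inherits(delay_fn, "delay_function"),
            is.finite(n0), n0 > 0, n_replicates >= 1L, noise_cv >= 0,
            is.list(conditions), length(conditions) >= 1L)
  if (is.null(names(conditions)) || anyDuplicated(names(conditions)))
    stop("conditions must be uniquely named")
  structure(list(params = params, delay_fn = delay_fn, n0 = n0,
                 times = times, n_replicates = as.integer(n_replicates),
                 noise_cv = noise_cv, conditions = conditions,
                 seed = as.integer(seed)),
            class = "experiment_scenario")
}

#' Condition sets for the two experimental designs
#'
#' `conditions_induction()` reproduces the induction-timing design: one
#' externally induced culture per induction time (default 0, 3, 5, 8 and
#' 12 h) plus an uninduced control. `conditions_strategies()` reproduces
#' the three-strategy design: OFF (never produces the good), ON (induced at
#' t = 0) and QS (density-threshold activation at `alpha`).
#'
#' @param induction_times external induction times in hours.
#' @param alpha quorum threshold (CFU/mL) for the QS condition.
#' @return A named list of control schedules.
#' @export
conditions_induction <- function(induction_times = c(0, 3, 5, 8, 12)) {
  out <- lapply(induction_times, schedule_external)
  names(out) <- paste0("induced_", induction_times)
  c(out, list(uninduced = schedule_never()))
}

#' @rdname conditions_induction
#' @export
conditions_strategies <- function(alpha = 5.3e7) {
  list(OFF = schedule_never(), ON = schedule_external(0),
       QS = schedule_qs(alpha))
}

lognormal_sdlog <- function(cv) sqrt(log1p(cv^2))

#' Generate one noisy replicate dataset for a condition
#'
#' Simulates the noiseless trajectory under `schedule` and multiplies each
#' replicate count independently by a lognormal factor with median 1 and
#' coefficient of variation `scenario$noise_cv` — the standard dispersion
#' model for serial-dilution plate counts, whose error is multiplicative
#' across the decades of the growth curve. With `noise_cv = 0` every
#' replicate equals the noiseless trajectory.
#'
#' @param scenario an [experiment_scenario()].
#' @param schedule a [control_schedule][schedule_never] for this condition.
#' @param label condition label.
#' @param seed integer seed, or `NULL` to draw from the current RNG stream
#'   (used by [generate_experiment()] so one top-level seed drives all
#'   conditions).
#' @return A [growth_dataset()]; its `induction_time` is taken from the
#'   schedule (`NA` unless external).
#' @export
generate_dataset <- function(scenario, schedule, label = "condition",
                             seed = scenario$seed) {
  stopifnot(inherits(scenario, "experiment_scenario"),
            inherits(schedule, "control_schedule"))
  if (!is.null(seed)) set.seed(seed)
  traj <- simulate_growth(scenario$params, schedule, scenario$delay_fn,
                          scenario$n0, scenario$times)
  nrep <- scenario$n_replicates
  nt <- length(scenario$times)
  mult <- if (scenario$noise_cv > 0)
    exp(matrix(rnorm(nrep * nt, 0, lognormal_sdlog(scenario$noise_cv)),
               nrow = nrep))
  else matrix(1, nrow = nrep, ncol = nt)
  counts <- sweep(mult, 2, traj$density, `*`)
  growth_dataset(scenario$times, counts, label = label,
                 induction_time = if (schedule$mode == "external")
                   schedule$t_induction else NA_real_)
}

#' Generate a full synthetic experiment
#'
#' One noisy [growth_dataset()] per condition in the scenario, all sharing
#' the initial density and time grid, with independent noise. The
#' scenario's single seed drives the whole experiment, so identical
#' scenarios produce identical data.
#'
#' @param scenario an [experiment_scenario()].
#' @return A named list of [growth_dataset()] objects with a `"roles"`
#'   attribute inferred from the schedules (`uninduced`, `on`, `induced`,
#'   `qs`, or `off` for a condition labelled OFF).
#' @export
generate_experiment <- function(scenario) {
  stopifnot(inherits(scenario, "experiment_scenario"))
  set.seed(scenario$seed)
  labels <- names(scenario$conditions)
  out <- vector("list", length(labels))
  names(out) <- labels
  roles <- character(length(labels))
  for (i in seq_along(labels)) {
    sched <- scenario$conditions[[i]]
    out[[i]] <- generate_dataset(scenario, sched, label = labels[i],
                                 seed = NULL)
    roles[i] <- switch(sched$mode,
      never = if (toupper(labels[i]) == "OFF") "off" else "uninduced",
      qs = "qs",
      external = if (sched$t_induction == 0) "on" else "induced")
  }
  attr(out, "roles") <- setNames(roles, labels)
  out
}

#' Write a synthetic experiment to CSV files plus a manifest
#'
#' One wide-format growth CSV per condition and a `manifest.csv` readable
#' by [read_manifest()].
#'
#' @param experiment output of [generate_experiment()].
#' @param dir output directory (created if needed).
#' @param dialect CSV dialect for the per-condition files.
#' @return The manifest path, invisibly.
#' @export
write_experiment <- function(experiment, dir, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  roles <- attr(experiment, "roles")
  rows <- lapply(names(experiment), function(lab) {
    f <- paste0(lab, ".csv")
    write_growth_csv(experiment[[lab]], file.path(dir, f), dialect)
    data.frame(label = lab, file = f,
               role = if (is.null(roles)) "induced" else roles[[lab]],
               induction_time = ifelse(
                 is.na(experiment[[lab]]$induction_time), "none",
                 experiment[[lab]]$induction_time))
  })
  man <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  write.csv(man, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
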