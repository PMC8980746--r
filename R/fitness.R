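#' Relative fitness of an induced culture
#'
#' The time-averaged ratio of the induced culture's density to the
#' uninduced reference, `RF = sum_k N(k)/Noff(k)` over the shared grid
#' (including the k = 0 inoculation point, whose ratio is ~1 by
#' construction). Because transient and stationary densities are orders of
#' magnitude apart but cancel inside the ratio, the integrand is of order 1
#' across the whole experiment. With `normalization = "mean"` (default) the
#' sum is divided by the number of points, so identical curves give
#' `RF = 1`; `"sum"` returns the raw sum.
#'
#' @param induced positive densities of the induced culture (CFU/mL).
#' @param reference positive densities of the uninduced reference on the
#'   same time grid.
#' @param normalization `"mean"` or `"sum"`.
#' @return Dimensionless relative fitness.
#' @examples
#' relative_fitness(c(1, 2, 4), c(1, 2, 4))        # 1
#' relative_fitness(2 * c(1, 2, 4), c(1, 2, 4))    # 2
#' @export
relative_fitness <- function(induced, reference,
                             normalization = c("mean", "sum")) {
  normalization <- match.arg(normalization)
  stopifnot(is.numeric(induced), is.numeric(reference))
  if (length(induced) != length(reference))
    stop("induced and reference series must have equal length")
  if (any(!is.finite(reference)) || any(reference <= 0))
    stop("reference densities must be positive and finite")
  if (any(!is.finite(induced)) || any(induced <= 0))
    stop("induced densities must be positive and finite")
  s <- sum(induced / reference)
  if (normalization == "mean") s / length(induced) else s
}

new_fitness_curve <- function(induction_times, rf_values, normalization) {
  ord <- order(induction_times)
  induction_times <- induction_times[ord]
  rf_values <- rf_values[ord]
  structure(list(induction_times = induction_times, rf_values = rf_values,
                 t_opt = induction_times[which.max(rf_values)],
                 normalization = normalization),
            class = "fitness_curve")
}

#' @export
print.fitness_curve <- function(x, ...) {
  cat(sprintf(
    "Relative-fitness curve (%d induction times, normalization = %s)\n",
    length(x$induction_times), x$normalization))
  cat(sprintf("  max RF = %.4g at t_i = %.3g h\n",
              max(x$rf_values), x$t_opt))
  invisible(x)
}

#' @export
as.data.frame.fitness_curve <- function(x, ...) {
  data.frame(induction_time_h = x$induction_times,
             relative_fitness = x$rf_values)
}

#' Plot a relative-fitness curve
#' @param x a `fitness_curve`.
#' @param ... passed to [plot()].
#' @return `x` invisibly.
#' @export
plot.fitness_curve <- function(x, ...) {
  plot(x$induction_times, x$rf_values, type = "b",
       xlab = "induction time (h)", ylab = "relative fitness", ...)
  abline(v = x$t_opt, col = "grey50", lty = 3)
  invisible(x)
}

#' Empirical relative-fitness scan over induction times
#'
#' Applies [relative_fitness()] to the replicate-mean series of each
#' induced dataset against the replicate-mean uninduced reference, all on
#' the reference's time grid, and locates the optimal induction time.
#'
#' @param datasets a list of [growth_dataset()] objects, each with its
#'   `induction_time` set.
#' @param reference the uninduced [growth_dataset()].
#' @param normalization as in [relative_fitness()].
#' @return A `fitness_curve` (sorted by induction time) with its maximiser
#'   `t_opt`; ties resolve to the earliest induction time.
#' @export
empirical_fitness_scan <- function(datasets, reference,
                                   normalization = c("mean", "sum")) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(reference, "growth_dataset"), length(datasets) >= 1L)
  ref_mean <- colMeans(reference$counts)
  t_i <- numeric(length(datasets))
  rf <- numeric(length(datasets))
  for (i in seq_along(datasets)) {
    d <- datasets[[i]]
    stopifnot(inherits(d, "growth_dataset"))
    if (length(d$times) != length(reference$times) ||
        any(d$times != reference$times))
      stop("dataset '", d$label,
           "' is not on the reference time grid")
    if (is.na(d$induction_time))
      stop("dataset '", d$label, "' has no induction time")
    t_i[i] <- d$induction_time
    rf[i] <- relative_fitness(colMeans(d$counts), ref_mean, normalization)
  }
  new_fitness_curve(t_i, rf, normalization)
}

#' Model-predicted relative-fitness scan over induction times
#'
#' Simulates, from a common initial density, the uninduced trajectory and
#' one externally induced trajectory per candidate induction time with the
#' calibrated model, and computes the relative fitness of each. The result
#' is deterministic.
#'
#' @param params calibrated [growth_params()].
#' @param delay_fn calibrated [delay_function()].
#' @param n0 initial density (CFU/mL).
#' @param induction_times candidate induction times in hours.
#' @param horizon experiment length in hours (must exceed every induction
#'   time).
#' @param dt sampling interval of the fitness sum, in hours.
#' @param normalization as in [relative_fitness()].
#' @return A `fitness_curve` with its maximiser `t_opt`.
#' @examples
#' model_fitness_scan(growth_params(0.9, 0.45, 1.2e8, 8e8),
#'                    delay_hinge(1e7, 5 / 9e7), 1e6,
#'                    induction_times = c(0, 3, 5, 8, 12))
#' @export
model_fitness_scan <- function(params, delay_fn, n0, induction_times,
                               horizon = 24, dt = 1,
                               normalization = c("mean", "sum")) {
  normalization <- match.arg(normalization)
  stopifnot(length(induction_times) >= 1L, all(is.finite(induction_times)),
            all(induction_times >= 0))
  if (horizon <= max(induction_times))
    stop("horizon must exceed the largest induction time")
  t_grid <- seq(0, horizon, by = dt)
  ref <- simulate_growth(params, schedule_never(), delay_fn, n0, t_grid)
  rf <- vapply(induction_times, function(ti) {
    ind <- simulate_growth(params, schedule_external(ti), delay_fn, n0,
                           t_grid)
    relative_fitness(ind$density, ref$density, normalization)
  }, numeric(1))
  new_fitness_curve(induction_times, rf, normalization)
}

#' Optimal induction time of a fitness curve
#'
#' @param curve a `fitness_curve`.
#' @return The induction time (h) maximising relative fitness; ties are
#'   broken toward the earliest time.
#' @export
optimal_induction <- function(curve) {
  stopifnot(inherits(curve, "fitness_curve"))
  if (!length(curve$induction_times)) stop("empty fitness curve")
  curve$induction_times[which.max(curve$rf_values)]
}

#' Write a fitness curve to CSV
#'
#' Columns `induction_time_h,relative_fitness`.
#' @param curve a `fitness_curve`.
#' @param path output file.
#' @return `path` invisibly.
#' @export
write_fitness_csv <- function(curve, path) {
  stopifnot(inherits(curve, "fitness_curve"))
  write.csv(as.data.frame(curve), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
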