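#' Run the staged calibration and fitness analysis end to end
#'
#' Executes, in order: (1) `growth` — weighted fixed-`N(0)` rate/capacity
#' fits for the uninduced (or OFF) and the t = 0 induced (ON) cultures,
#' yielding the four switched growth constants; (2) `delays` — joint
#' (`N(0)`, `D`) fits for every induced culture; (3) `delay_function` — the
#' hinge latency-vs-activation-density fit; (4) `threshold` — the
#' quorum-threshold residual scan (if a QS condition is present); (5)
#' `fitness` — the empirical relative-fitness scan over the measured
#' induction times and the model-predicted scan over a fine induction-time
#' grid, each with its optimal induction time.
#'
#' @param experiment a named list of [growth_dataset()] objects with a
#'   `"roles"` attribute (as returned by [generate_experiment()] or
#'   [read_manifest()]), or a manifest CSV path. Roles missing from the
#'   attribute are inferred from induction times (`NA` -> uninduced,
#'   0 -> on, `> 0` -> induced).
#' @param stages character subset of
#'   `c("growth","delays","delay_function","threshold","fitness")`; stages
#'   not listed are skipped (an empty selection validates the inputs and
#'   returns an empty report). Later stages require the earlier ones.
#' @param alpha_grid candidate thresholds for the threshold stage.
#' @param model_induction_times induction-time grid for the model fitness
#'   scan; defaults to quarter-hour steps up to the largest measured
#'   induction time.
#' @param out_dir if non-`NULL`, per-stage CSV outputs and a JSON report
#'   are written here (see [write_report()]); partial outputs are preserved
#'   if a later stage fails.
#' @return A list of class `qs_report` with elements `params`
#'   ([growth_params()]), `growth_fits`, `delays` (data frame), `delay_fn`,
#'   `threshold`, `fitness` (list `empirical`, `model`), `t_opt_empirical`,
#'   `t_opt_model`, and `stages`.
#' @examples
#' exp <- generate_experiment(experiment_scenario(seed = 42))
#' rep <- run_pipeline(exp)
#' rep$t_opt_empirical
#' @export
run_pipeline <- function(experiment,
                         stages = c("growth", "delays", "delay_function",
                                    "threshold", "fitness"),
                         alpha_grid = default_alpha_grid(),
                         model_induction_times = NULL,
                         out_dir = NULL) {
  if (is.character(experiment)) experiment <- read_manifest(experiment)
  stopifnot(is.list(experiment), length(experiment) >= 1L)
  if (length(stages)) stages <- match.arg(stages, several.ok = TRUE)
  roles <- attr(experiment, "roles")
  if (is.null(roles)) roles <- setNames(rep(NA_character_,
                                            length(experiment)),
                                        names(experiment))
  for (lab in names(experiment)) {
    d <- experiment[[lab]]
    stopifnot(inherits(d, "growth_dataset"))
    if (is.na(roles[[lab]]))
      roles[[lab]] <- if (is.na(d$induction_time)) "uninduced"
        else if (d$induction_time == 0) "on" else "induced"
  }
  report <- structure(list(stages = stages, roles = roles), class = "qs_report")
  if (!length(stages)) return(report)

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(out_dir)) try(write_report(report, out_dir), silent = TRUE)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  pick <- function(role) {
    lab <- names(roles)[roles == role]
    if (!length(lab)) NULL else experiment[[lab[1]]]
  }

  if ("growth" %in% stages) {
    report <- run_stage("growth", {
      off_ds <- pick("off")
      if (is.null(off_ds)) off_ds <- pick("uninduced")
      on_ds <- pick("on")
      if (is.null(off_ds) || is.null(on_ds))
        stop("growth stage needs an uninduced (or OFF) and a t_i = 0 (ON) ",
             "condition")
      fit_off <- fit_rate_capacity(off_ds, "single_phase_off")
      fit_on <- fit_rate_capacity(on_ds, "single_phase_on")
      report$growth_fits <- list(off = fit_off, on = fit_on)
      report$params <- growth_params(
        lambda0 = fit_off$estimates[["lambda"]],
        lambda1 = fit_on$estimates[["lambda"]],
        kappa0 = fit_off$estimates[["kappa"]],
        kappa1 = fit_on$estimates[["kappa"]])
      report
    })
  }
  if ("delays" %in% stages) {
    report <- run_stage("delays", {
      if (is.null(report$params))
        stop("requires the growth stage")
      labs <- names(roles)[roles %in% c("on", "induced")]
      rows <- lapply(labs, function(lab) {
        d <- experiment[[lab]]
        fd <- fit_delay(d, d$induction_time, report$params)
        data.frame(label = lab, induction_time_h = d$induction_time,
                   n0 = fd$estimates[["n0"]],
                   delay_h = fd$estimates[["delay"]],
                   activation_density = fd$activation_density,
                   wssr = fd$wssr, converged = fd$converged)
      })
      report$delays <- do.call(rbind, rows)
      report
    })
  }
  if ("delay_function" %in% stages) {
    report <- run_stage("delay_function", {
      if (is.null(report$delays)) stop("requires the delays stage")
      report$delay_fn <- fit_delay_function(
        report$delays$activation_density, report$delays$delay_h)
      report
    })
  }
  if ("threshold" %in% stages) {
    report <- run_stage("threshold", {
      qs_ds <- pick("qs")
      if (!is.null(qs_ds)) {
        if (is.null(report$params)) stop("requires the growth stage")
        dfn <- if (!is.null(report$delay_fn)) report$delay_fn
               else delay_zero()
        report$threshold <- fit_threshold(qs_ds, report$params, dfn,
                                          alpha_grid)
      }
      report
    })
  }
  if ("fitness" %in% stages) {
    report <- run_stage("fitness", {
      ref <- pick("uninduced")
      if (is.null(ref)) ref <- pick("off")
      labs <- names(roles)[roles %in% c("on", "induced")]
      if (is.null(ref) || !length(labs))
        stop("fitness stage needs an uninduced reference and induced ",
             "conditions")
      emp <- empirical_fitness_scan(experiment[labs], ref)
      report$fitness <- list(empirical = emp)
      report$t_opt_empirical <- optimal_induction(emp)
      if (!is.null(report$params)) {
        dfn <- if (!is.null(report$delay_fn)) report$delay_fn
               else delay_zero()
        n0 <- mean(ref$counts[, 1])
        ti_grid <- model_induction_times
        if (is.null(ti_grid))
          ti_grid <- seq(0, max(emp$induction_times), by = 0.25)
        mod <- model_fitness_scan(report$params, dfn, n0, ti_grid,
                                  horizon = max(ref$times))
        report$fitness$model <- mod
        report$t_opt_model <- optimal_induction(mod)
      }
      report
    })
  }
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.qs_report <- function(x, ...) {
  cat("Public-good growth analysis report\n")
  if (!is.null(x$params)) {
    cat(sprintf("  lambda0 = %.4g 1/h, kappa0 = %.4g CFU/mL\n",
                x$params$lambda0, x$params$kappa0))
    cat(sprintf("  lambda1 = %.4g 1/h, kappa1 = %.4g CFU/mL\n",
                x$params$lambda1, x$params$kappa1))
  }
  if (!is.null(x$delays))
    cat(sprintf("  delays fitted for %d induction times\n", nrow(x$delays)))
  if (!is.null(x$delay_fn))
    cat(sprintf("  no-delay boundary: %.4g CFU/mL\n",
                attr(x$delay_fn, "n_break")))
  if (!is.null(x$threshold))
    cat(sprintf("  quorum threshold alpha* = %.4g CFU/mL\n",
                x$threshold$alpha_star))
  if (!is.null(x$t_opt_empirical))
    cat(sprintf("  optimal induction (empirical): %.3g h\n",
                x$t_opt_empirical))
  if (!is.null(x$t_opt_model))
    cat(sprintf("  optimal induction (model): %.3g h\n", x$t_opt_model))
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Per-stage CSV files (`delays.csv`, `threshold_scan.csv`,
#' `fitness_empirical.csv`, `fitness_model.csv`) plus a `report.json`
#' summary of all scalar estimates; every CSV is re-readable with
#' [read.csv()] and the package's own readers.
#'
#' @param report a `qs_report` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return `dir` invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "qs_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(report$delays))
    write.csv(report$delays, file.path(dir, "delays.csv"),
              row.names = FALSE, quote = FALSE)
  if (!is.null(report$threshold))
    write.csv(report$threshold$wssr_curve,
              file.path(dir, "threshold_scan.csv"),
              row.names = FALSE, quote = FALSE)
  if (!is.null(report$fitness$empirical))
    write_fitness_csv(report$fitness$empirical,
                      file.path(dir, "fitness_empirical.csv"))
  if (!is.null(report$fitness$model))
    write_fitness_csv(report$fitness$model,
                      file.path(dir, "fitness_model.csv"))
  summary <- list(stages = report$stages)
  if (!is.null(report$params))
    summary$params <- report$params[c("lambda0", "lambda1",
                                      "kappa0", "kappa1")]
  if (!is.null(report$growth_fits))
    summary$wssr <- list(off = report$growth_fits$off$wssr,
                         on = report$growth_fits$on$wssr)
  if (!is.null(report$delay_fn))
    summary$delay_function <- list(
      n_break = attr(report$delay_fn, "n_break"),
      slope = attr(report$delay_fn, "slope"))
  if (!is.null(report$threshold))
    summary$alpha_star <- report$threshold$alpha_star
  if (!is.null(report$t_opt_empirical))
    summary$t_opt_empirical <- report$t_opt_empirical
  if (!is.null(report$t_opt_model))
    summary$t_opt_model <- report$t_opt_model
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
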