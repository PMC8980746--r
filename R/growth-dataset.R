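#' Replicate growth-curve dataset
#'
#' Container for colony-count time series of one experimental condition:
#' a shared time axis (typically hourly samples over 0-24 h) and one row of
#' CFU/mL counts per replicate culture (typically triplicates).
#'
#' @param times sampling times in hours, strictly increasing.
#' @param counts numeric matrix, replicates x times, of CFU/mL counts; a
#'   vector is treated as a single replicate. All counts must be positive.
#' @param label condition label (e.g. `"OFF"`, `"induced_5"`).
#' @param induction_time external induction time in hours, or `NA` for an
#'   uninduced/never condition.
#' @return An object of class `growth_dataset`.
#' @examples
#' d <- growth_dataset(0:5, rbind(1e6 * exp(0.9 * 0:5),
#'                                1.1e6 * exp(0.9 * 0:5)), label = "demo")
#' summarize_replicates(d)
#' @export
growth_dataset <- function(times, counts, label = "condition",
                           induction_time = NA_real_) {
  if (is.vector(counts)) counts <- matrix(counts, nrow = 1L)
  counts <- as.matrix(counts)
  stopifnot(is.numeric(times), is.numeric(counts))
  if (!all(is.finite(times))) stop("times must be finite")
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  if (ncol(counts) != length(times))
    stop("counts must have one column per time point")
  if (nrow(counts) < 1L) stop("at least one replicate is required")
  if (!all(is.finite(counts)) || any(counts <= 0))
    stop("all counts must be finite and strictly positive")
  if (!is.na(induction_time) && induction_time < 0)
    stop("induction_time must be >= 0 or NA")
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("rep", seq_len(nrow(counts)))
  structure(list(times = as.numeric(times), counts = counts,
                 label = as.character(label),
                 induction_time = as.numeric(induction_time)),
            class = "growth_dataset")
}

#' @export
print.growth_dataset <- function(x, ...) {
  cat(sprintf("Growth dataset '%s': %d replicate(s) x %d time points (%g-%g h)\n",
              x$label, nrow(x$counts), length(x$times),
              min(x$times), max(x$times)))
  if (!is.na(x$induction_time))
    cat(sprintf("  induced at t_i = %g h\n", x$induction_time))
  invisible(x)
}

#' Per-time replicate summary and regression weights
#'
#' Computes the replicate mean, the sample standard deviation (n-1
#' denominator), and the weights `w(k)` used by the weighted least-squares
#' calibration stages. Weights are the inverse of the SD; where the SD
#' vanishes (identical replicates) or for a single replicate the SD is
#' floored at `sd_floor_frac` times the mean so weights stay finite. For a
#' single replicate all weights are 1 (no dispersion information).
#'
#' @param dataset a [growth_dataset()].
#' @param sd_floor_frac floor on the SD, as a fraction of the mean.
#' @return A list with `mean`, `sd` and `weights`, each one value per time
#'   point.
#' @export
summarize_replicates <- function(dataset, sd_floor_frac = 1e-3) {
  stopifnot(inherits(dataset, "growth_dataset"))
  m <- colMeans(dataset$counts)
  if (nrow(dataset$counts) == 1L) {
    s <- rep(NA_real_, length(m))
    w <- rep(1, length(m))
  } else {
    s <- apply(dataset$counts, 2, sd)
    w <- 1 / pmax(s, sd_floor_frac * m)
  }
  list(mean = m, sd = s, weights = w)
}
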