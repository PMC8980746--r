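#' Piecewise-linear capacity-latency function
#'
#' The latency `D(N)` between activation of public-good production and the
#' moment the full carrying-capacity benefit is realised depends on the
#' population density `N` at activation: activating while the population is
#' still small incurs no latency, activating late (close to, or at, the low
#' carrying capacity) incurs an increasingly long one. The latency is
#' represented as a piecewise-linear function of activation density defined
#' by knots `(density, delay)`. Below the first knot the function is
#' constant at the first knot's delay; above the last knot the last linear
#' segment is continued.
#'
#' @param density numeric vector of knot densities (CFU/mL), strictly
#'   increasing and positive.
#' @param delay numeric vector of knot delays (hours), nonnegative and
#'   nondecreasing, same length as `density`.
#' @return An object of class `delay_function`.
#' @seealso [delay_zero()], [delay_constant()], [delay_hinge()],
#'   [delay_at()], [fit_delay_function()]
#' @examples
#' fn <- delay_function(c(1e7, 1e8), c(0, 5))
#' delay_at(fn, c(1e6, 1e7, 5.5e7, 2e8))
#' @export
delay_function <- function(density, delay) {
  stopifnot(is.numeric(density), is.numeric(delay),
            length(density) == length(delay), length(density) >= 1L)
  if (!all(is.finite(density)) || !all(is.finite(delay)))
    stop("delay_function knots must be finite")
  if (any(density <= 0)) stop("knot densities must be positive")
  if (is.unsorted(density, strictly = TRUE))
    stop("knot densities must be strictly increasing")
  if (any(delay < 0)) stop("delays must be nonnegative")
  if (is.unsorted(delay)) stop("delays must be nondecreasing in density")
  structure(list(density = as.numeric(density), delay = as.numeric(delay)),
            class = "delay_function")
}

#' Zero latency function
#'
#' `D(N) = 0` for all densities: the carrying-capacity gain is instantaneous,
#' recovering the pure indicator-threshold model.
#' @return A `delay_function` that is identically zero.
#' @export
delay_zero <- function() delay_function(1, 0)

#' Constant latency function
#'
#' `D(N) = delay` for all densities. Used internally when the delay is a
#' free scalar parameter of a fit.
#' @param delay latency in hours (scalar, nonnegative).
#' @return A `delay_function`.
#' @export
delay_constant <- function(delay) {
  stopifnot(length(delay) == 1L, is.finite(delay), delay >= 0)
  delay_function(1, delay)
}

#' Hinge (two-segment) latency function
#'
#' `D(N) = 0` for `N <= n_break` and `D(N) = slope * (N - n_break)` above:
#' a no-delay window up to a breakpoint density, then a linearly growing
#' latency. This is the parametric family fitted by [fit_delay_function()].
#'
#' @param n_break breakpoint density (CFU/mL) below which there is no delay.
#' @param slope latency increase per unit density above the break
#'   (h per CFU/mL), nonnegative.
#' @return A `delay_function`.
#' @examples
#' delay_at(delay_hinge(1e7, 5 / 9e7), 1e8)  # 5 h at 1e8 CFU/mL
#' @export
delay_hinge <- function(n_break, slope) {
  stopifnot(is.finite(n_break), n_break > 0, is.finite(slope), slope >= 0)
  fn <- delay_function(c(n_break, 2 * n_break), c(0, slope * n_break))
  attr(fn, "n_break") <- n_break
  attr(fn, "slope") <- slope
  fn
}

#' Evaluate a latency function
#'
#' @param fn a [delay_function()].
#' @param density numeric vector of activation densities (CFU/mL).
#' @return Latencies in hours, one per density, always `>= 0`.
#' @export
delay_at <- function(fn, density) {
  stopifnot(inherits(fn, "delay_function"), is.numeric(density))
  if (any(!is.finite(density)) || any(density <= 0))
    stop("densities must be positive and finite")
  x <- fn$density
  y <- fn$delay
  if (length(x) == 1L) return(rep(y, length(density)))
  out <- approx(x, y, xout = density, rule = 2)$y
  slope_last <- (y[length(y)] - y[length(y) - 1L]) /
    (x[length(x)] - x[length(x) - 1L])
  above <- density > x[length(x)]
  out[above] <- y[length(y)] + slope_last * (density[above] - x[length(x)])
  pmax(out, 0)
}

#' @export
print.delay_function <- function(x, ...) {
  cat("Capacity-latency function D(N), piecewise linear\n")
  cat(sprintf("  knots: %s\n", paste(
    sprintf("(%.4g CFU/mL, %.4g h)", x$density, x$delay), collapse = " ")))
  if (!is.null(attr(x, "n_break")))
    cat(sprintf("  hinge: no delay below %.4g CFU/mL, slope %.4g h per CFU/mL\n",
                attr(x, "n_break"), attr(x, "slope")))
  invisible(x)
}
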