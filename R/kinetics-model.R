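#' Kinetic parameters of the autocatalytic aggregation model
#'
#' Bundles the rate constants of the two-process amyloid aggregation
#' scheme: spontaneous nucleation of monomers (rate constant `k_n`,
#' first order in free monomer) and aggregate-catalysed elongation
#' (rate constant `k_e`, second order). For an initial monomer
#' concentration `a` the model collapses to two effective parameters:
#' the composite rate `k = k_e * a` (units s^-1) and the dimensionless
#' nucleation-to-growth ratio `rho = k_n / k`. Small `rho` produces a
#' pronounced lag phase; `rho >= 1` (nucleation at least as fast as
#' growth) is representable but flagged because the sigmoid then has no
#' lag and its inflection lies at non-positive time.
#'
#' @param k_n nucleation rate constant, s^-1. Must be > 0.
#' @param k_e elongation rate constant, M^-1 s^-1. Must be > 0.
#' @param a initial monomeric protein concentration, M. Must be > 0.
#' @return An object of class `kinetic_params`: a list with fields
#'   `k_n`, `k_e`, `a` and the derived `k = k_e * a`, `rho = k_n / k`,
#'   plus `rho_ge_1` flagging the no-lag regime.
#' @examples
#' p <- kinetic_params(k_n = 3.09e-5, k_e = 486.9, a = 1e-5)
#' p$k    # composite rate k_e * a
#' p$rho  # nucleation-to-growth ratio
#' @export
kinetic_params <- function(k_n, k_e, a) {
  stopifnot(is.numeric(k_n), length(k_n) == 1L, is.finite(k_n),
            is.numeric(k_e), length(k_e) == 1L, is.finite(k_e),
            is.numeric(a), length(a) == 1L, is.finite(a))
  if (k_n <= 0) stop("k_n must be > 0 (got ", k_n, ")")
  if (k_e <= 0) stop("k_e must be > 0 (got ", k_e, ")")
  if (a <= 0) stop("a must be > 0 (got ", a, ")")
  k <- k_e * a
  rho <- k_n / k
  structure(
    list(k_n = k_n, k_e = k_e, a = a, k = k, rho = rho,
         rho_ge_1 = rho >= 1),
    class = "kinetic_params"
  )
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Autocatalytic kinetic parameters\n")
  cat(sprintf("  k_n = %.4g s^-1   k_e = %.4g M^-1 s^-1   a = %.4g M\n",
              x$k_n, x$k_e, x$a))
  cat(sprintf("  k = k_e*a = %.4g s^-1   rho = k_n/k = %.4g%s\n",
              x$k, x$rho,
              if (x$rho_ge_1) "  [rho >= 1: no lag phase]" else ""))
  invisible(x)
}

#' Build kinetic parameters from the effective pair (rho, k)
#'
#' Inverse of the `(k_n, k_e) -> (rho, k)` reduction: given the
#' dimensionless ratio `rho`, the composite rate `k` and the monomer
#' concentration `a`, reconstructs `k_n = rho * k` and `k_e = k / a`.
#' Used by the fitting layer, which estimates `(rho, k)`.
#'
#' @param rho dimensionless nucleation-to-growth ratio, > 0.
#' @param k composite rate constant, s^-1, > 0.
#' @param a initial monomer concentration, M, > 0.
#' @return A `kinetic_params` object.
#' @export
kinetic_params_from_rho_k <- function(rho, k, a) {
  stopifnot(rho > 0, k > 0, a > 0)
  kinetic_params(k_n = rho * k, k_e = k / a, a = a)
}

#' Fraction aggregated under the autocatalytic model
#'
#' Closed-form solution of the autocatalytic rate law
#' `df/dt = k (1 - f) (rho + f)` with `f(0) = 0`:
#' \deqn{f(t) = \frac{\rho\,(e^{(1+\rho)kt} - 1)}{1 + \rho\,e^{(1+\rho)kt}}}
#' evaluated in an overflow-safe form. Writing `y = (1+rho) k t +
#' log(rho)`, the curve is `f = 1 - (1+rho) / (1 + e^y)`; for `y < 0`
#' the equivalent `rho * expm1(x) / (1 + e^y)` avoids the catastrophic
#' cancellation of `1 - (almost 1)` near the baseline, and for `y >= 0`
#' the logistic form is evaluated through `plogis`, which is stable for
#' arbitrarily large arguments.
#'
#' @param params a `kinetic_params` object.
#' @param t time(s), seconds, each >= 0. Vectorised.
#' @return Fraction aggregated in `[0, 1)`, same length as `t`.
#' @examples
#' p <- kinetic_params(3.09e-5, 486.9, 1e-5)
#' aggregated_fraction(p, c(0, 989, 5000))
#' @export
aggregated_fraction <- function(params, t) {
  stopifnot(inherits(params, "kinetic_params"), is.numeric(t))
  if (any(!is.finite(t)) || any(t < 0))
    stop("t must be finite and >= 0")
  rho <- params$rho
  x <- (1 + rho) * params$k * t
  y <- x + log(rho)
  f <- numeric(length(t))
  lo <- y < 0
  # y < 0 implies x < log(1/rho), so exp(x) cannot overflow here
  f[lo] <- rho * expm1(x[lo]) / (1 + exp(y[lo]))
  f[!lo] <- 1 - (1 + rho) * stats::plogis(-y[!lo])
  f
}

#' Instantaneous aggregation rate df/dt
#'
#' The autocatalytic rate law `k (1 - f)(rho + f)` evaluated along the
#' closed-form trajectory.
#'
#' @inheritParams aggregated_fraction
#' @return df/dt in s^-1, same length as `t`.
#' @export
aggregation_rate <- function(params, t) {
  f <- aggregated_fraction(params, t)
  params$k * (1 - f) * (params$rho + f)
}

#' Independent ODE solution of the autocatalytic rate law
#'
#' Numerically integrates `df/dt = k (1 - f)(rho + f)` from `f(0) = 0`
#' with an implicit stiff solver (radau, relative tolerance 1e-12) as an
#' independent cross-check of the closed form. Verification plumbing;
#' not used by the fitting path.
#'
#' @param params a `kinetic_params` object.
#' @param grid sorted, non-negative times (s).
#' @return Numeric vector of f values on `grid`.
#' @export
ode_oracle <- function(params, grid) {
  stopifnot(inherits(params, "kinetic_params"), is.numeric(grid),
            length(grid) >= 1L)
  if (any(!is.finite(grid)) || any(grid < 0))
    stop("grid must be finite and >= 0")
  if (is.unsorted(grid, strictly = FALSE))
    stop("grid must be sorted increasing")
  if (length(grid) == 1L && grid[1] == 0) return(0)
  times <- if (grid[1] > 0) c(0, grid) else grid
  rhs <- function(t, y, parms) {
    list(parms$k * (1 - y[1]) * (parms$rho + y[1]))
  }
  sol <- deSolve::ode(
    y = c(f = 0), times = times, func = rhs,
    parms = list(k = params$k, rho = params$rho),
    method = "radau", rtol = 1e-12, atol = 1e-16
  )
  istate <- attr(sol, "istate")
  if (!is.null(istate) && istate[1] < 0)
    stop("ODE solver failed to converge (istate = ", istate[1], ")")
  f <- sol[, "f"]
  if (grid[1] > 0) f <- f[-1]
  unname(f)
}

#' Time at which a given fraction is aggregated
#'
#' Closed-form inverse of the sigmoid:
#' `t = log((f + rho) / (rho (1 - f))) / ((1 + rho) k)`.
#' At `f = 0.5` this is the half-aggregation time t_1/2.
#'
#' @param params a `kinetic_params` object.
#' @param f_target fraction(s) in `[0, 1)`. Vectorised.
#' @return Time(s) in seconds.
#' @examples
#' p <- kinetic_params(3.09e-5, 486.9, 1e-5)
#' time_at_fraction(p, 0.5)  # half-aggregation time
#' @export
time_at_fraction <- function(params, f_target) {
  stopifnot(inherits(params, "kinetic_params"), is.numeric(f_target))
  if (any(f_target < 0) || any(f_target >= 1))
    stop("f_target must lie in [0, 1)")
  rho <- params$rho
  log((f_target + rho) / (rho * (1 - f_target))) / ((1 + rho) * params$k)
}

#' Characteristic times of the aggregation sigmoid
#'
#' Implements the tangent construction used to read lag and end times
#' off a fitted sigmoid: the tangent at the inflection point
#' `t_i = log(1/rho) / ((1+rho) k)`, where the curve passes through
#' `f_i = (1 - rho)/2` with maximal slope `v_max = k (1+rho)^2 / 4`,
#' is extrapolated to the abscissa (f = 0), giving the lag time `t0`,
#' and to the normalized plateau (f = 1), giving the end time `t1`.
#' Two half-times are reported: `t_half`, the analytic f = 0.5
#' crossing, and `t_half_tangent = (t0 + t1)/2`, the midpoint of the
#' tangent construction (the two agree to order rho^2 and coincide in
#' the symmetric-logistic limit rho -> 0).
#'
#' When `rho >= 1` the inflection lies at t <= 0 (no lag phase); the
#' result is flagged (`flagged = TRUE`) and `t0` is clamped at 0.
#'
#' @param params a `kinetic_params` object.
#' @return An object of class `characteristic_times`: list with `t0`,
#'   `t_half`, `t_half_tangent`, `t1`, `t_inflection`, `v_max`,
#'   `f_inflection`, `flagged`.
#' @examples
#' p <- kinetic_params(3.09e-5, 486.9, 1e-5)
#' characteristic_times(p)
#' @export
characteristic_times <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  rho <- params$rho
  k <- params$k
  flagged <- rho >= 1
  if (flagged) warning("rho >= 1: inflection at t <= 0; t0 clamped to 0")
  t_i <- log(1 / rho) / ((1 + rho) * k)
  f_i <- (1 - rho) / 2
  v_max <- k * (1 + rho)^2 / 4
  t0 <- t_i - f_i / v_max
  t1 <- t_i + (1 - f_i) / v_max
  if (flagged) t0 <- max(t0, 0)
  structure(
    list(t0 = t0,
         t_half = time_at_fraction(params, 0.5),
         t_half_tangent = (t0 + t1) / 2,
         t1 = t1,
         t_inflection = t_i,
         v_max = v_max,
         f_inflection = f_i,
         flagged = flagged),
    class = "characteristic_times"
  )
}

#' @export
print.characteristic_times <- function(x, ...) {
  cat("Characteristic aggregation times (s)\n")
  cat(sprintf("  t0 = %.4g   t_half = %.4g   t1 = %.4g\n",
              x$t0, x$t_half, x$t1))
  cat(sprintf("  inflection at t = %.4g (f = %.4g), v_max = %.4g s^-1\n",
              x$t_inflection, x$f_inflection, x$v_max))
  if (x$flagged) cat("  [flagged: rho >= 1, no lag phase]\n")
  invisible(x)
}
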