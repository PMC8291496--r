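#' Normalize a raw ThT trace to fraction aggregated
#'
#' Maps raw fluorescence to fraction aggregated by the two-point
#' anchor rule `f = (F - F_base) / (F_plateau - F_base)`, with
#' `F_base` the mean of the first `n_base` points and `F_plateau` the
#' mean of the last `n_plateau` points. The anchors are recorded on the
#' result for reporting. Accurate anchoring requires the trace to
#' include a flat pre-lag baseline and a reached plateau; if the first
#' points already sit on the rising phase the baseline estimate is
#' biased upward (see the methods vignette).
#'
#' @param raw a raw `tht_series` with >= 8 points.
#' @param n_base,n_plateau number of points averaged for the baseline
#'   and plateau anchors (default 3 each).
#' @return A normalized `tht_series` with a `normalization` record.
#' @export
normalize_trace <- function(raw, n_base = 3L, n_plateau = 3L) {
  stopifnot(inherits(raw, "tht_series"))
  if (raw$is_normalized) return(raw)
  n <- length(raw$times)
  if (n < 8L)
    stop("normalization needs at least 8 points spanning the sigmoid ",
         "(got ", n, ")")
  stopifnot(n_base >= 1L, n_plateau >= 1L, n_base + n_plateau <= n)
  f_base <- mean(raw$values[seq_len(n_base)])
  f_plateau <- mean(raw$values[seq.int(n - n_plateau + 1L, n)])
  if (f_plateau <= f_base)
    stop("flat trace: plateau (", signif(f_plateau, 4),
         ") does not exceed baseline (", signif(f_base, 4),
         "); no aggregation signal to normalize")
  f <- (raw$values - f_base) / (f_plateau - f_base)
  # clip tiny numerical excursions so the container invariant holds
  f <- pmin(pmax(f, -0.1), 1.1)
  tht_series(raw$times, f, replicate_id = raw$replicate_id,
             condition = raw$condition, protein_conc = raw$protein_conc,
             is_normalized = TRUE,
             normalization = list(f_base = f_base, f_plateau = f_plateau))
}

# Deterministic starting values from curve geometry:
# t_half0 = first empirical crossing of f = 0.5 (linear interpolation),
# k0 = 4 * max finite-difference slope (v_max = k(1+rho)^2/4 ~ k/4),
# rho0 = exp(-k0 * t_half0) (from t_i ~ log(1/rho)/k), clamped to
# [1e-8, 1].
fit_start_values <- function(times, f) {
  above <- which(f >= 0.5)
  if (length(above) == 0L || above[1] == 1L) {
    t_half0 <- if (length(above)) times[1] else max(times)
  } else {
    i <- above[1]
    t_half0 <- times[i - 1] +
      (0.5 - f[i - 1]) / (f[i] - f[i - 1]) * (times[i] - times[i - 1])
  }
  slopes <- diff(f) / diff(times)
  slopes <- slopes[is.finite(slopes)]  # pooled grids may repeat times
  k0 <- 4 * max(slopes)
  if (!is.finite(k0) || k0 <= 0) k0 <- 1 / max(times)
  k0 <- min(max(k0, 1e-8), 1)
  rho0 <- exp(-k0 * t_half0)
  rho0 <- min(max(rho0, 1e-8), 1)
  c(rho = rho0, k = k0)
}

#' Fit the autocatalytic model to a normalized trace
#'
#' Estimates the effective pair `(rho, k)` by bounded nonlinear least
#' squares on the fraction-aggregated curve (Levenberg-Marquardt,
#' `minpack.lm`), then maps back to the rate constants `k_e = k / a`
#' and `k_n = rho * k`. The fit is unweighted, runs in
#' log10-parameter space for conditioning, and is deterministic:
#' starting values come from the curve geometry (see the vignette) and
#' up to 3 restarts from fixed perturbations of the start are taken if
#' the optimizer fails to converge. Bounds: rho in [1e-10, 10],
#' k in [1e-8, 1] s^-1; ftol/xtol 1e-12 (values are rounded only at
#' the reporting layer).
#'
#' @param trace a normalized `tht_series` (or a raw trace, which is
#'   normalized first).
#' @param a initial monomer concentration, M, > 0.
#' @return An object of class `agg_fit`: list with `params`
#'   (`kinetic_params`), `times` (`characteristic_times`), `rho_hat`,
#'   `k_hat`, `residual_rms`, `converged`, `n_points`, `n_replicates`,
#'   `condition`.
#' @examples
#' p <- kinetic_params(3.09e-5, 486.9, 1e-5)
#' tt <- seq(0, 3000, by = 300)
#' tr <- tht_series(tt, aggregated_fraction(p, tt), is_normalized = TRUE)
#' fit <- fit_autocatalytic(tr, a = 1e-5)
#' fit$params$k_n
#' @export
fit_autocatalytic <- function(trace, a) {
  stopifnot(inherits(trace, "tht_series"), is.numeric(a), a > 0)
  if (!trace$is_normalized) trace <- normalize_trace(trace)
  keep <- is.finite(trace$values)
  times <- trace$times[keep]
  f_obs <- trace$values[keep]
  if (length(times) < 8L)
    stop("fitting needs at least 8 points spanning the sigmoid (got ",
         length(times), ")")
  if (sum(f_obs >= 0.5) < 3L)
    stop("insufficient sigmoid coverage: fewer than 3 points beyond ",
         "half-max; extend the time span")

  start <- fit_start_values(times, f_obs)
  lower <- log10(c(1e-10, 1e-8))
  upper <- log10(c(10, 1))
  resid_fun <- function(theta) {
    rho <- 10^theta[1]; k <- 10^theta[2]
    p <- kinetic_params_from_rho_k(rho, k, a)
    aggregated_fraction(p, times) - f_obs
  }

  # fixed deterministic perturbations for restarts on failure
  perturb <- list(c(0, 0), c(0.5, 0.25), c(-0.5, -0.25), c(1, 0.5))
  fit <- NULL
  converged <- FALSE
  for (shift in perturb) {
    theta0 <- pmin(pmax(log10(start) + shift, lower), upper)
    out <- tryCatch(
      minpack.lm::nls.lm(
        par = theta0, lower = lower, upper = upper, fn = resid_fun,
        control = minpack.lm::nls.lm.control(
          ftol = 1e-12, ptol = 1e-12, maxiter = 500)
      ),
      error = function(e) NULL
    )
    if (!is.null(out) && out$info %in% 1:4) {
      fit <- out
      converged <- TRUE
      break
    }
    if (is.null(fit) && !is.null(out)) fit <- out
  }
  if (is.null(fit))
    stop("optimizer failed without producing any iterate")

  rho_hat <- unname(10^fit$par[1])
  k_hat <- unname(10^fit$par[2])
  params <- kinetic_params_from_rho_k(rho_hat, k_hat, a)
  res <- resid_fun(fit$par)
  structure(
    list(params = params,
         times = characteristic_times(params),
         rho_hat = rho_hat, k_hat = k_hat,
         residual_rms = sqrt(mean(res^2)),
         converged = converged,
         n_points = length(times),
         n_replicates = 1L,
         condition = trace$condition),
    class = "agg_fit"
  )
}

#' @export
print.agg_fit <- function(x, ...) {
  cat(sprintf("Autocatalytic fit ('%s', %d points, %d replicate%s)%s\n",
              x$condition, x$n_points, x$n_replicates,
              if (x$n_replicates > 1) "s" else "",
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat(sprintf("  rho = %.4g   k = %.4g s^-1   RMS = %.3g\n",
              x$rho_hat, x$k_hat, x$residual_rms))
  cat(sprintf("  k_n = %.4g s^-1   k_e = %.4g M^-1 s^-1 (a = %.3g M)\n",
              x$params$k_n, x$params$k_e, x$params$a))
  cat(sprintf("  t0 = %.0f s   t_half = %.0f s   t1 = %.0f s\n",
              x$times$t0, x$times$t_half, x$times$t1))
  invisible(x)
}

#' Fit one condition from replicate traces
#'
#' Combines replicate ThT traces of one condition and fits the
#' autocatalytic model. The default `"averaged"` strategy fits the
#' pointwise-mean trace (replicates must share a time grid; matches
#' reporting one parameter set per condition), `"pooled"` fits all
#' points of all replicates jointly.
#'
#' @param replicates list of `tht_series` (raw traces are normalized
#'   individually before combination).
#' @param a initial monomer concentration, M.
#' @param strategy `"averaged"` (default) or `"pooled"`.
#' @return An `agg_fit`, with `n_replicates` recorded.
#' @export
fit_condition <- function(replicates, a, strategy = c("averaged", "pooled")) {
  strategy <- match.arg(strategy)
  stopifnot(is.list(replicates), length(replicates) >= 1L,
            all(vapply(replicates, inherits, logical(1), "tht_series")))
  replicates <- lapply(replicates, function(r)
    if (r$is_normalized) r else normalize_trace(r))
  n_rep <- length(replicates)
  if (n_rep == 1L) {
    fit <- fit_autocatalytic(replicates[[1]], a)
    return(fit)
  }
  cond <- replicates[[1]]$condition
  if (strategy == "averaged") {
    grids <- lapply(replicates, `[[`, "times")
    same <- all(vapply(grids[-1], function(g)
      length(g) == length(grids[[1]]) && all(g == grids[[1]]), logical(1)))
    if (!same)
      stop("replicates have mismatched time grids; use strategy = \"pooled\"")
    mean_f <- rowMeans(vapply(replicates, `[[`, numeric(length(grids[[1]])),
                              "values"))
    trace <- tht_series(grids[[1]], pmin(pmax(mean_f, -0.1), 1.1),
                        replicate_id = "mean", condition = cond,
                        is_normalized = TRUE)
    fit <- fit_autocatalytic(trace, a)
  } else {
    all_t <- unlist(lapply(replicates, `[[`, "times"))
    all_f <- unlist(lapply(replicates, `[[`, "values"))
    ord <- order(all_t)
    all_t <- all_t[ord]; all_f <- all_f[ord]
    # jitter-free pooled fit: duplicate times are legitimate here, so
    # bypass the strictly-increasing container and fit directly
    trace <- structure(
      list(times = all_t, values = pmin(pmax(all_f, -0.1), 1.1),
           replicate_id = "pooled", condition = cond,
           protein_conc = a, is_normalized = TRUE, normalization = NULL),
      class = "tht_series")
    fit <- fit_autocatalytic(trace, a)
  }
  fit$n_replicates <- n_rep
  fit
}
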