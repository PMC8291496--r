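# Reference fit conditions: the published rate constants for Abeta40
# aggregation without inhibitor and in the presence of compounds 18
# and 21, all at a = 10 uM monomer.
ref_conditions <- function() {
  list(
    control = kinetic_params(k_n = 3.09e-5, k_e = 486.9, a = 1e-5),
    cmp18 = kinetic_params(k_n = 1.45e-6, k_e = 299.5, a = 1e-5),
    cmp21 = kinetic_params(k_n = 1.41e-5, k_e = 338.8, a = 1e-5)
  )
}

# Published characteristic times (s) read off the fitted experimental
# curves for the same three conditions.
ref_times <- function() {
  data.frame(
    condition = c("control", "cmp18", "cmp21"),
    t0 = c(535, 1855, 995),
    t_half = c(989, 2570, 1710),
    t1 = c(1444, 3284, 2424)
  )
}

# Noise-free fraction-aggregated trace on a uniform grid.
fraction_trace <- function(params, t_step = 300, span_factor = 2,
                           condition = "ref") {
  t1 <- characteristic_times(params)$t1
  tt <- seq(0, span_factor * t1, by = t_step)
  tht_series(tt, aggregated_fraction(params, tt),
             condition = condition, protein_conc = params$a,
             is_normalized = TRUE)
}

# Independent ODE solution of df/dt = k (1 - f)(rho + f) used as an
# oracle against the package's closed form; calls deSolve directly so
# it shares no code with the implementation under test.
desolve_fraction <- function(params, grid) {
  times <- if (grid[1] > 0) c(0, grid) else grid
  sol <- deSolve::ode(
    y = c(f = 0), times = times,
    func = function(t, y, p) list(p$k * (1 - y[1]) * (p$rho + y[1])),
    parms = list(k = params$k, rho = params$rho),
    method = "radau", rtol = 1e-12, atol = 1e-16)
  f <- unname(sol[, "f"])
  if (grid[1] > 0) f[-1] else f
}
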