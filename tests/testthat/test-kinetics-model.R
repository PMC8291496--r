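test_that("parameter container derives k and rho and round-trips them", {
  p <- kinetic_params(k_n = 3.09e-5, k_e = 486.9, a = 1e-5)
  expect_equal(p$k, 486.9 * 1e-5)
  expect_equal(p$rho, 3.09e-5 / (486.9 * 1e-5))
  expect_equal(p$rho * p$k, p$k_n)
  expect_equal(p$k_e * p$a, p$k)
  expect_false(p$rho_ge_1)
  expect_true(kinetic_params(1, 1, 1)$rho_ge_1)
  expect_error(kinetic_params(-1, 486.9, 1e-5), "k_n")
  expect_error(kinetic_params(3e-5, 0, 1e-5), "k_e")
  expect_error(kinetic_params(3e-5, 486.9, 0), "a")
  q <- kinetic_params_from_rho_k(p$rho, p$k, p$a)
  expect_equal(q$k_n, p$k_n)
  expect_equal(q$k_e, p$k_e)
})

test_that("aggregated fraction obeys its boundary conditions", {
  p <- ref_conditions()$control
  expect_identical(aggregated_fraction(p, 0), 0)
  # strictly increasing up to the point where f is within double
  # precision of the plateau
  tt <- seq(0, time_at_fraction(p, 1 - 1e-12), length.out = 400)
  f <- aggregated_fraction(p, tt)
  expect_true(all(diff(f) > 0))
  expect_true(all(f >= 0 & f <= 1))
  expect_equal(aggregated_fraction(p, 1e9), 1, tolerance = 1e-12)
  expect_error(aggregated_fraction(p, -1), "t must")
})

test_that("closed form is overflow-safe for huge exponents", {
  p <- kinetic_params(k_n = 1e-7, k_e = 100, a = 1e-5)  # rho = 1e-4
  x_big <- 900 / ((1 + p$rho) * p$k)  # (1+rho) k t = 900 > exp overflow
  f <- aggregated_fraction(p, c(x_big, 10 * x_big))
  expect_true(all(is.finite(f)))
  expect_equal(f, c(1, 1), tolerance = 1e-12)
})

test_that("closed form agrees with independent ODE integration", {
  # fixed reference condition, then randomized parameter draws
  p <- ref_conditions()$control
  grid <- seq(0, 5000, by = 300)
  expect_lt(max(abs(aggregated_fraction(p, grid) -
                      desolve_fraction(p, grid))), 1e-8)

  set.seed(42)
  for (i in 1:20) {
    rho <- 10^stats::runif(1, -8, 0)
    k <- 10^stats::runif(1, -5, -2)
    a <- 1e-5
    pr <- kinetic_params(k_n = rho * k, k_e = k / a, a = a)
    t1 <- characteristic_times(pr)$t1
    g <- seq(0, 10 * t1, length.out = 60)
    expect_lt(max(abs(aggregated_fraction(pr, g) -
                        desolve_fraction(pr, g))), 1e-8)
  }
  # rho = 1 edge: no lag phase, still exact
  p1 <- kinetic_params(k_n = 1e-3, k_e = 100, a = 1e-5)
  expect_equal(p1$rho, 1)
  g <- seq(0, 5000, by = 100)
  expect_lt(max(abs(aggregated_fraction(p1, g) -
                      desolve_fraction(p1, g))), 1e-8)
})

test_that("packaged ODE oracle matches the closed form and guards input", {
  p <- ref_conditions()$control
  grid <- seq(0, 5000, by = 300)
  expect_lt(max(abs(ode_oracle(p, grid) -
                      aggregated_fraction(p, grid))), 1e-8)
  expect_identical(ode_oracle(p, 0), 0)
  expect_error(ode_oracle(p, c(300, 0)), "sorted")
  expect_error(ode_oracle(p, -1), "grid")
})

test_that("fraction at the published control condition matches integration", {
  # independent stiff integration puts f(989 s) near 0.443
  p <- ref_conditions()$control
  f_ode <- desolve_fraction(p, 989)
  expect_equal(f_ode, 0.443, tolerance = 1e-3)
  expect_equal(aggregated_fraction(p, 989), f_ode, tolerance = 1e-9)
})

test_that("time_at_fraction inverts the sigmoid", {
  p <- ref_conditions()$control
  expect_identical(time_at_fraction(p, 0), 0)
  for (f in c(0.01, 0.25, 0.5, 0.9, 0.999)) {
    t <- time_at_fraction(p, f)
    expect_equal(aggregated_fraction(p, t), f, tolerance = 1e-10)
  }
  expect_error(time_at_fraction(p, 1), "f_target")
  # bisection oracle for the half time (expected value ~1035 s)
  bisect <- function(lo, hi) {
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (aggregated_fraction(p, mid) < 0.5) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  t_half_oracle <- bisect(0, 1e4)
  expect_equal(time_at_fraction(p, 0.5), t_half_oracle, tolerance = 1e-8)
  expect_equal(t_half_oracle, 1035.2, tolerance = 1e-4)
  # inflection fraction (1 - rho)/2 sits at ln(1/rho)/((1+rho)k) ~ 1033 s
  expect_equal(time_at_fraction(p, (1 - p$rho) / 2),
               log(1 / p$rho) / ((1 + p$rho) * p$k))
  expect_equal(time_at_fraction(p, (1 - p$rho) / 2), 1032.65,
               tolerance = 1e-4)
})

test_that("characteristic times match a numeric tangent construction", {
  # oracle: densely sample the curve, take the tangent at the max
  # finite-difference slope, intersect with f = 0 and f = 1
  for (p in ref_conditions()) {
    tt <- seq(0, 4 * time_at_fraction(p, 0.99), length.out = 2e5)
    f <- aggregated_fraction(p, tt)
    sl <- diff(f) / diff(tt)
    i <- which.max(sl)
    t_mid <- (tt[i] + tt[i + 1]) / 2
    f_mid <- (f[i] + f[i + 1]) / 2
    t0_num <- t_mid - f_mid / sl[i]
    t1_num <- t_mid + (1 - f_mid) / sl[i]
    ct <- characteristic_times(p)
    expect_equal(ct$t0, t0_num, tolerance = 1e-3)
    expect_equal(ct$t1, t1_num, tolerance = 1e-3)
    expect_equal(ct$t_inflection, t_mid, tolerance = 1e-3)
    expect_equal(ct$v_max, sl[i], tolerance = 1e-3)
  }
  # frozen values for the control condition
  ct <- characteristic_times(ref_conditions()$control)
  expect_equal(ct$t0, 629.6, tolerance = 1e-3)
  expect_equal(ct$t_inflection, 1032.7, tolerance = 1e-3)
  expect_equal(ct$t1, 1440.8, tolerance = 1e-3)
  expect_true(ct$t0 < ct$t_inflection, ct$t_inflection < ct$t1)
  expect_true(ct$t0 < ct$t_half && ct$t_half < ct$t1)
})

test_that("tangent-midpoint identity holds on analytic curves", {
  set.seed(7)
  for (i in 1:25) {
    rho <- 10^stats::runif(1, -8, -0.05)
    k <- 10^stats::runif(1, -5, -2)
    p <- kinetic_params(k_n = rho * k, k_e = k / 1e-5, a = 1e-5)
    ct <- characteristic_times(p)
    lhs <- (ct$t0 + ct$t1) / 2
    rhs <- ct$t_inflection +
      (1 - 2 * ct$f_inflection) / (2 * ct$v_max)
    expect_lt(abs(lhs - rhs), 1e-9 * ct$t1)
    expect_equal(ct$t_half_tangent, lhs)
  }
})

test_that("rho >= 1 is flagged and the lag time clamped at zero", {
  p <- kinetic_params(k_n = 2e-3, k_e = 100, a = 1e-5)  # rho = 2
  expect_warning(ct <- characteristic_times(p), "rho >= 1")
  expect_true(ct$flagged)
  expect_identical(ct$t0, 0)
})

test_that("faster nucleation shortens all times, faster elongation the rise", {
  base <- ref_conditions()$control
  ct <- characteristic_times(base)
  for (mult in c(2, 5, 10)) {
    up_n <- kinetic_params(base$k_n * mult, base$k_e, base$a)
    ct_n <- characteristic_times(up_n)
    expect_lt(ct_n$t0, ct$t0)
    expect_lt(ct_n$t_half, ct$t_half)
    expect_lt(ct_n$t1, ct$t1)
    up_e <- kinetic_params(base$k_n, base$k_e * mult, base$a)
    ct_e <- characteristic_times(up_e)
    expect_lt(ct_e$t1 - ct_e$t0, ct$t1 - ct$t0)
  }
})

test_that("small rho reduces to the symmetric logistic", {
  for (rho in c(1e-6, 1e-7)) {
    k <- 1e-3
    p <- kinetic_params(k_n = rho * k, k_e = k / 1e-5, a = 1e-5)
    ct <- characteristic_times(p)
    tt <- seq(ct$t0, ct$t1, length.out = 200)
    logistic <- 1 / (1 + exp(-(1 + rho) * k * (tt - ct$t_inflection)))
    expect_lt(max(abs(aggregated_fraction(p, tt) - logistic)), 10 * rho)
    # in the same limit the analytic half time collapses onto the
    # inflection time
    expect_lt(abs(ct$t_half - ct$t_inflection), 3 * rho / k)
  }
})

test_that("the curve is covariant under time/rate rescaling", {
  p <- ref_conditions()$control
  tt <- seq(0, 5000, by = 250)
  f0 <- aggregated_fraction(p, tt)
  for (c_scale in c(0.1, 3, 100)) {
    p_scaled <- kinetic_params(p$k_n * c_scale, p$k_e * c_scale, p$a)
    expect_equal(aggregated_fraction(p_scaled, tt / c_scale), f0,
                 tolerance = 1e-12)
  }
})
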