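test_that("noiseless traces are exactly the affine-mapped model curve", {
  p <- ref_conditions()$control
  cfg <- generator_config(p, t_span = 5000, noise_cv = 0, seed = 3)
  traces <- generate_timecourse(cfg)
  expect_length(traces, 3L)
  expect_length(traces[[1]]$times, 17L)  # 0..5000 s every 300 s
  f <- aggregated_fraction(p, traces[[1]]$times)
  for (tr in traces) expect_identical(tr$values, 100 + 1000 * f)
})

test_that("the generator is deterministic and replicates use substreams", {
  p <- ref_conditions()$control
  cfg <- generator_config(p, t_span = 5000, noise_cv = 0.05, seed = 123)
  a <- generate_timecourse(cfg)
  b <- generate_timecourse(cfg)
  for (i in 1:3) expect_identical(a[[i]]$values, b[[i]]$values)
  expect_false(identical(a[[1]]$values, a[[2]]$values))
  # a different master seed changes every replicate
  cfg2 <- generator_config(p, t_span = 5000, noise_cv = 0.05, seed = 124)
  c <- generate_timecourse(cfg2)
  expect_false(identical(a[[1]]$values, c[[1]]$values))
  # generation does not disturb the caller's RNG stream
  set.seed(99); before <- stats::runif(1)
  set.seed(99); invisible(generate_timecourse(cfg))
  expect_identical(stats::runif(1), before)
})

test_that("a too-short span warns that the fit will be poorly constrained", {
  p <- ref_conditions()$control  # t_half ~ 1035 s
  cfg <- generator_config(p, t_span = 1500, noise_cv = 0)
  expect_warning(generate_timecourse(cfg), "poorly constrained")
})

test_that("endpoint plates invert the metric exactly at zero noise", {
  for (kind in c("inhibition_in_vitro", "disaggregation",
                 "inhibition_in_cellulo")) {
    pl <- generate_endpoint_plate(c(x = 80, y = 0, z = -25), kind,
                                  noise_cv = 0, seed = 1)
    r <- screen_plate(pl, kind)
    expect_equal(r$percent[r$compound == "x"], 80)
    expect_equal(r$percent[r$compound == "y"], 0)
    expect_equal(r$percent[r$compound == "z"], -25)
    expect_equal(r$sem, rep(0, 3))
  }
  # p = 0 compound wells coincide with the 0% control level
  pl <- generate_endpoint_plate(c(y = 0), "inhibition_in_cellulo",
                                noise_cv = 0, seed = 1)
  expect_equal(pl$fluorescence[pl$compound == "y" & !is.na(pl$compound)],
               pl$fluorescence[pl$role == "induced_dmso_control"])
  expect_error(generate_endpoint_plate(c(x = 300), "disaggregation"),
               "unphysical")
  expect_error(generate_endpoint_plate(c(x = -150), "disaggregation"),
               "unphysical")
})

test_that("2*SEM coverage of noisy plates matches its t-distribution value", {
  # with triplicates the pivot (mean - p)/SEM is Student t (2 df), so
  # the within-2*SEM rate must sit near P(|t2| <= 2) = 0.8165, not at
  # the normal-theory 95% -- a direct check that the SEM is computed
  # from the replicate spread with the n-1 denominator
  hits <- vapply(0:199, function(s) {
    pl <- generate_endpoint_plate(c(x = 41), "inhibition_in_vitro",
                                  noise_cv = 0.02, seed = s)
    r <- screen_plate(pl, "inhibition_in_vitro")
    abs(r$percent - 41) <= 2 * r$sem
  }, logical(1))
  p_t2 <- 2 * stats::pt(2, df = 2) - 1
  expect_lt(abs(mean(hits) - p_t2), 3 * sqrt(p_t2 * (1 - p_t2) / 200))
})

test_that("recovered percents are unbiased over many seeded plates", {
  for (p_true in c(41, 16.7, 63.2)) {
    est <- vapply(0:199, function(s) {
      pl <- generate_endpoint_plate(c(x = p_true), "disaggregation",
                                    noise_cv = 0.02, seed = s)
      screen_plate(pl, "disaggregation")$percent
    }, numeric(1))
    grand_sem <- stats::sd(est) / sqrt(length(est))
    expect_lt(abs(mean(est) - p_true), 2 * grand_sem + 1e-9)
  }
})

test_that("replicate SEM scales as noise_cv over sqrt(n)", {
  mean_sem <- function(cv, n) {
    mean(vapply(0:499, function(s) {
      pl <- generate_endpoint_plate(c(x = 50), "inhibition_in_cellulo",
                                    noise_cv = cv, seed = s,
                                    n_replicates = n)
      screen_plate(pl, "inhibition_in_cellulo")$sem
    }, numeric(1)))
  }
  s_2_3 <- mean_sem(0.02, 3)
  expect_lt(abs(mean_sem(0.04, 3) / s_2_3 - 2), 0.4)        # x2 noise
  expect_lt(abs(mean_sem(0.02, 12) / s_2_3 - 0.5), 0.1)     # x4 replicates
})

test_that("disaggregation series saturate monotonically with compound ratio", {
  p <- ref_conditions()$control
  pl <- generate_disaggregation_series(p, compound_effect = 0.343,
                                       ratios = c(1, 10), compound = "c18",
                                       noise_cv = 0, seed = 1)
  r <- screen_plate(pl, "disaggregation")
  at1 <- r$percent[r$compound == "c18@1"]
  at10 <- r$percent[r$compound == "c18@10"]
  expect_equal(at1, 34.3)
  expect_gt(at10, at1)
  # effect 0 leaves the fibril signal untouched; effect 1 removes it
  r0 <- screen_plate(generate_disaggregation_series(p, 0, c(1, 10),
                                                    noise_cv = 0),
                     "disaggregation")
  expect_equal(r0$percent, c(0, 0))
  r1 <- screen_plate(generate_disaggregation_series(p, 1, c(1, 10),
                                                    noise_cv = 0),
                     "disaggregation")
  expect_equal(r1$percent, c(100, 100))
  expect_error(generate_disaggregation_series(p, -0.1, 1), "effect")
})

test_that("the full synthetic pipeline closes on the generator parameters", {
  # noise-free closure: generate -> normalize -> fit recovers the rate
  # constants to better than 0.1%. The baseline anchor (mean of the
  # first 3 points) is biased by ~k_n * t_step, so the closure is a
  # fine-sampling property: at 1 s it holds, at plate-reader cadence
  # (300 s) the residual bias is the accuracy floor discussed in the
  # vignette.
  for (p in ref_conditions()) {
    t1 <- characteristic_times(p)$t1
    cfg <- generator_config(p, t_span = ceiling(3 * t1), t_step = 1,
                            noise_cv = 0, n_replicates = 1)
    tr <- generate_timecourse(cfg)[[1]]
    fit <- fit_autocatalytic(normalize_trace(tr), a = p$a)
    expect_lt(abs(fit$params$k_n / p$k_n - 1), 1e-3)
    expect_lt(abs(fit$params$k_e / p$k_e - 1), 1e-3)
  }
})
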