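#!/usr/bin/env Rscript
# Simulate the raw data the downstream analyses consume: triplicate
# ThT aggregation time courses for the three kinetic conditions
# (no inhibitor, compound 18, compound 21; 10 uM monomer, readings
# every 5 min, 5% multiplicative noise), plus 24 h endpoint plates for
# the in vitro inhibition, fibril disaggregation and in cellulo ThS
# screens. Writes CSVs under results/data/.

suppressPackageStartupMessages(library(amylokin))

seed <- 20260927L
out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

conditions <- list(
  control = kinetic_params(k_n = 3.09e-5, k_e = 486.9, a = 1e-5),
  cmp18 = kinetic_params(k_n = 1.45e-6, k_e = 299.5, a = 1e-5),
  cmp21 = kinetic_params(k_n = 1.41e-5, k_e = 338.8, a = 1e-5)
)

for (nm in names(conditions)) {
  p <- conditions[[nm]]
  t1 <- characteristic_times(p)$t1
  cfg <- generator_config(p, t_span = 300 * ceiling(2.2 * t1 / 300),
                          t_step = 300, noise_cv = 0.05,
                          n_replicates = 3, seed = seed)
  traces <- generate_timecourse(cfg)
  path <- file.path(out_dir, paste0("timecourse_", nm, ".csv"))
  write_timecourse_csv(traces, path)
  cat(sprintf("%s: %d points x 3 replicates -> %s\n",
              nm, length(traces[[1]]$times), path))
}

# Endpoint plates seeded with the published percentages as truth.
plates <- list(
  inhibition_in_vitro = generate_endpoint_plate(
    c(cmp18 = 41.0, cmp21 = 16.7), "inhibition_in_vitro",
    noise_cv = 0.02, seed = seed),
  inhibition_in_cellulo = generate_endpoint_plate(
    c(cmp18 = 80.0), "inhibition_in_cellulo",
    noise_cv = 0.02, seed = seed + 1L)
)
# Disaggregation at 1:1 and 1:10 compound ratios; the 1:1 effects are
# the published equimolar percents.
plates$disaggregation <- rbind(
  generate_disaggregation_series(conditions$control, 0.343, c(1, 10),
                                 compound = "cmp18", noise_cv = 0.02,
                                 seed = seed + 2L),
  generate_disaggregation_series(conditions$control, 0.268, c(1, 10),
                                 compound = "cmp21", noise_cv = 0.02,
                                 seed = seed + 3L)
)

for (nm in names(plates)) {
  path <- file.path(out_dir, paste0("plate_", nm, ".csv"))
  utils::write.csv(plates[[nm]], path, row.names = FALSE)
  cat(sprintf("%s plate: %d records -> %s\n", nm, nrow(plates[[nm]]), path))
}
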