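#!/usr/bin/env Rscript
# Endpoint screening arithmetic on the simulated 24 h plates: percent
# inhibition of aggregation (in vitro ThT), percent disaggregation of
# preformed fibrils at 1:1 and 1:10 compound ratios, and the in
# cellulo ThS inclusion-body screen with its OD620 toxicity control.
# Requires analysis/01_simulate.R to have run.

suppressPackageStartupMessages(library(amylokin))

kinds <- c("inhibition_in_vitro", "disaggregation", "inhibition_in_cellulo")
reports <- lapply(kinds, function(kind) {
  plate <- utils::read.csv(file.path("results/data",
                                     paste0("plate_", kind, ".csv")),
                           stringsAsFactors = FALSE)
  screen_plate(plate, kind)
})
combined <- do.call(rbind, reports)
write_screen_report(combined, "results/screen_report.csv")

cat("screening summary (mean of 3 replicates +/- SEM):\n")
print(combined, row.names = FALSE)
cat("\nwrote results/screen_report.csv\n")
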