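#!/usr/bin/env Rscript
# Operating characteristics of the IVW estimator run through the full
# instrument-selection pipeline: type-I error under the null and confidence
# coverage at a planted effect of 0.3.

suppressPackageStartupMessages(library(pqtlmr))
dir.create("results", showWarnings = FALSE)

null_cal <- mr_calibration(n_reps = 500, seed = 11, alpha_true = 0)
cov_cal <- mr_calibration(n_reps = 200, seed = 12, alpha_true = 0.3)

tab <- data.frame(
  quantity = c("null_rejection_rate", "coverage_alpha_0.3", "mean_beta_hat"),
  value = c(null_cal$rejection_rate, cov_cal$coverage, cov_cal$mean_beta),
  n_valid = c(null_cal$n_valid, cov_cal$n_valid, cov_cal$n_valid)
)
write.table(tab, "results/calibration.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("Null rejection rate at 0.05: %.3f (%d valid replicates)\n",
            null_cal$rejection_rate, null_cal$n_valid))
cat(sprintf("95%% CI coverage of alpha = 0.3: %.3f (mean beta %.3f)\n",
            cov_cal$coverage, cov_cal$mean_beta))
cat("The mild conservatism (rate < 0.05) comes from the multiplicative\n")
cat("overdispersion factor max(1, Q/df) applied to the standard errors.\n")
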