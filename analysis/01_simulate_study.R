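#!/usr/bin/env Rscript
# Simulate one protein locus end to end and write the raw materials the rest
# of the analysis consumes: a reference dosage panel, discovery pQTL summary
# statistics, and outcome GWAS summary statistics with a planted causal
# effect of 0.3 SD outcome per SD protein.

suppressPackageStartupMessages(library(pqtlmr))

dir.create("results/data", recursive = TRUE, showWarnings = FALSE)
cfg <- simulation_config(seed = 1, n_ref = 5000, n_exposure = 10000,
                         n_outcome = 10000, n_variants = 24, ld_decay = 0.5,
                         alpha_true = 0.3)
panel <- simulate_reference_panel(cfg)
study <- simulate_gwas_pair(cfg, panel)

write_reference_panel(panel, "results/data/reference_panel.tsv")
write_summary_stats(study$exposure_stats, "results/data/exposure_gwas.tsv")
write_summary_stats(study$outcome_stats, "results/data/outcome_gwas.tsv")

cat("Simulated locus:", cfg$n_variants, "variants,",
    length(cfg$causal_indices), "causal (indices",
    paste(cfg$causal_indices, collapse = ", "), ")\n")
cat("Planted causal effect alpha =", cfg$alpha_true, "\n")
cat("Reference panel:", nrow(panel), "individuals; empirical MAF range",
    paste(round(range(colMeans(panel) / 2), 3), collapse = "-"), "\n")
cat("Strongest exposure association: F =",
    round(max((study$exposure_stats$beta / study$exposure_stats$se)^2), 1),
    "\n")
cat("Wrote panel and summary statistics under results/data/\n")
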