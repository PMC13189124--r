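#!/usr/bin/env Rscript
# Run the full demonstration analysis: a 6-protein x 4-trait simulated study
# taken through instrument selection, LD-aware GLS IVW/MR-Egger with Rucker
# selection, colocalization, replication in an independent simulated pQTL
# source, prioritization and the knowledge graph. Artifacts are written to
# results/pipeline/.

suppressPackageStartupMessages(library(pqtlmr))

cfg <- pipeline_config(seed = 1, n_proteins = 6, n_traits = 4,
                       output_dir = "results/pipeline")
report <- run_pipeline(cfg, overwrite = TRUE)

cat("Protein-trait pairs analyzed:", report$counts$n_pairs, "\n")
cat("Valid estimates:", report$counts$n_estimates_ok,
    "| starved loci:", report$counts$n_insufficient, "\n")
cat("Multiplicity threshold:",
    signif(report$parameters$multiplicity_threshold, 4),
    "(", report$parameters$n_tests, "tests )\n")
cat("Significant associations:", report$counts$n_significant, "\n")
cat("Replicated (nominal):", report$counts$n_replicated_nominal,
    "| colocalized:", report$counts$n_colocalized, "\n")
cat("Top-tier (MR + replication + coloc):", report$counts$n_top_tier, "\n")
cat("Graph communities:", report$counts$n_communities, "\n")
cat("Artifacts in", report$output_dir, "\n")
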