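# Configuration-driven orchestration: simulate -> instruments -> MR ->
# colocalization -> replication -> prioritization -> knowledge graph ->
# evidence integration -> artifacts on disk.

#' Pipeline configuration
#'
#' A single object holding every stage parameter with the pipeline's default
#' thresholds (200-kbp window, MAF 1%, F 15, clump r^2 0.40, >= 5 variants,
#' coloc window 500 kbp and PP.H4 call 0.8, 75% concordance, tissue-trait
#' edge score > 8, enrichment p < 0.05). The whole configuration is echoed
#' verbatim into the run report.
#'
#' @param seed Master seed; every stage derives its stream from it.
#' @param n_proteins,n_traits Grid dimensions of the simulated study.
#' @param n_disease How many traits are diseases (the rest are biomarkers).
#' @param n_ref,n_exposure,n_outcome,n_variants,ld_decay Simulator settings
#'   passed to [simulation_config()].
#' @param alpha_matrix Optional `n_proteins x n_traits` matrix of true
#'   causal effects; default plants an effect of 0.3 for protein-trait pairs
#'   on the diagonal pattern `trait = protein mod n_traits`.
#' @param mr MR stage settings, an [mr_config()].
#' @param coloc Colocalization settings, a [coloc_config()].
#' @param multiplicity_threshold Optional override of the Bonferroni
#'   threshold (e.g. a published constant); default computed from counts.
#' @param concordance_cutoff,concordance_min_assoc 75% rule settings.
#' @param tissue_trait_cut,enrichment_p,broad_max Graph-layer settings.
#' @param output_dir Artifact directory for [run_pipeline()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, n_proteins = 6L, n_traits = 4L,
                            n_disease = 2L, n_ref = 2000L,
                            n_exposure = 6000L, n_outcome = 6000L,
                            n_variants = 24L, ld_decay = 0.5,
                            alpha_matrix = NULL,
                            mr = mr_config(), coloc = coloc_config(),
                            multiplicity_threshold = NULL,
                            concordance_cutoff = 0.75,
                            concordance_min_assoc = 4,
                            tissue_trait_cut = 8, enrichment_p = 0.05,
                            broad_max = 300,
                            output_dir = tempfile("pqtlmr_run_")) {
  proteins <- sprintf("PROT%02d", seq_len(n_proteins))
  traits <- sprintf("TRAIT%02d", seq_len(n_traits))
  if (is.null(alpha_matrix)) {
    alpha_matrix <- matrix(0, n_proteins, n_traits,
                           dimnames = list(proteins, traits))
    for (i in seq_len(n_proteins)) {
      alpha_matrix[i, (i - 1L) %% n_traits + 1L] <- 0.3
    }
  }
  stopifnot(nrow(alpha_matrix) == n_proteins, ncol(alpha_matrix) == n_traits)
  dimnames(alpha_matrix) <- list(proteins, traits)
  structure(list(
    seed = as.integer(seed), proteins = proteins, traits = traits,
    n_disease = as.integer(n_disease), n_ref = as.integer(n_ref),
    n_exposure = as.integer(n_exposure), n_outcome = as.integer(n_outcome),
    n_variants = as.integer(n_variants), ld_decay = ld_decay,
    alpha_matrix = alpha_matrix, mr = mr, coloc = coloc,
    multiplicity_threshold = multiplicity_threshold,
    concordance_cutoff = concordance_cutoff,
    concordance_min_assoc = concordance_min_assoc,
    tissue_trait_cut = tissue_trait_cut, enrichment_p = enrichment_p,
    broad_max = broad_max, output_dir = output_dir
  ), class = "pipeline_config")
}

protein_locus <- function(cfg_sim, gene_id) {
  pos <- variant_positions(cfg_sim)
  # gene body spans the central third of the simulated variant grid
  span <- range(pos)
  third <- diff(span) / 3
  gene_locus(gene_id, cfg_sim$chrom,
             floor(span[1] + third), ceiling(span[2] - third))
}

# Four causal cis variants spread across the locus: enough LD-sharing
# neighbours pass the F filter that a typical locus retains >= 5 clumped
# instruments, as in the source pQTL studies where every analyzed protein
# had a usable instrument set.
simulate_protein_study <- function(config, i, stream) {
  p <- config$n_variants
  causal <- unique(pmin(p, ceiling(p * c(0.125, 0.375, 0.625, 0.875))))
  simulation_config(
    seed = derive_seed(config$seed, stream, i),
    n_ref = config$n_ref, n_exposure = config$n_exposure,
    n_outcome = config$n_outcome, n_variants = p,
    ld_decay = config$ld_decay,
    causal_indices = causal,
    causal_betas = rep(c(0.4, 0.35, 0.3, 0.35), length.out = length(causal))
  )
}

#' Run the full analysis pipeline on simulated data
#'
#' Simulates a reference panel, a discovery and a replication pQTL GWAS per
#' protein, and per-trait outcome GWAS with the configured true effects;
#' then runs instrument selection and MR for every protein-trait pair,
#' colocalization on each region, replication assessment, direction and
#' concordance profiling, positive-control checks, the knowledge graph with
#' Louvain communities and pathway enrichment, and evidence integration.
#' All tabular artifacts, graph exports and a JSON run report are written
#' to `config$output_dir`. Identical configuration and seed give
#' byte-identical artifacts.
#'
#' @param config A [pipeline_config()].
#' @param overwrite Allow writing into an existing non-empty directory.
#' @return A `run_report` list (also serialized to `report.json`).
#' @export
run_pipeline <- function(config, overwrite = FALSE) {
  out <- config$output_dir
  if (dir.exists(out) && length(dir(out)) && !overwrite) {
    stop("output directory exists and is not empty: ", out)
  }
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  proteins <- config$proteins
  traits <- config$traits
  n_disease <- config$n_disease

  mult <- bonferroni_threshold(length(proteins), length(traits),
                               threshold = config$multiplicity_threshold)

  # --- simulate + MR + coloc per protein-trait pair -----------------------
  estimates <- list()
  repl_estimates <- list()
  colocs <- list()
  for (i in seq_along(proteins)) {
    base <- simulate_protein_study(config, i, "discovery")
    repl_base <- simulate_protein_study(config, i, "replication")
    panel <- simulate_reference_panel(base)
    repl_panel <- simulate_reference_panel(repl_base)
    locus <- protein_locus(base, proteins[i])
    for (j in seq_along(traits)) {
      cfg_ij <- base
      cfg_ij$alpha_true <- config$alpha_matrix[i, j]
      study <- simulate_gwas_pair(cfg_ij, panel)
      est <- run_protein_trait_mr(study$exposure_stats, study$outcome_stats,
                                  locus, panel, config = config$mr,
                                  protein = proteins[i], trait = traits[j])
      estimates[[length(estimates) + 1L]] <- est
      colocs[[length(colocs) + 1L]] <- coloc_region(
        study$exposure_stats, study$outcome_stats, locus,
        config = config$coloc, outcome_type = "quantitative",
        protein = proteins[i], trait = traits[j]
      )
      repl_cfg <- repl_base
      repl_cfg$alpha_true <- config$alpha_matrix[i, j]
      repl_study <- simulate_gwas_pair(repl_cfg, repl_panel)
      repl_estimates[[length(repl_estimates) + 1L]] <- run_protein_trait_mr(
        repl_study$exposure_stats, repl_study$outcome_stats,
        locus, repl_panel, config = config$mr,
        protein = proteins[i], trait = traits[j]
      )
    }
  }
  est_df <- mr_results_table(estimates)
  repl_df <- mr_results_table(repl_estimates)
  coloc_df <- coloc_results_table(colocs)
  audit_df <- do.call(rbind, lapply(estimates, function(e) {
    if (!nrow(e$excluded)) return(NULL)
    cbind(protein = e$protein, trait = e$trait, e$excluded)
  }))
  if (is.null(audit_df)) {
    audit_df <- data.frame(protein = character(), trait = character(),
                           variant_id = character(), stage = character(),
                           reason = character())
  }

  # --- annotations, prioritization ---------------------------------------
  tissues <- sprintf("TISSUE%02d", 1:5)
  pathways <- sprintf("PW%02d", 1:8)
  ann <- simulate_annotations(derive_seed(config$seed, "annotations"),
                              proteins, traits, tissues, pathways,
                              n_disease = n_disease)

  sig <- est_df[est_df$status == "ok" & est_df$pval < mult$threshold, ,
                drop = FALSE]
  if (nrow(sig)) {
    sig$direction <- vapply(seq_len(nrow(sig)), function(r) {
      classify_direction(sig$beta[r], sig$trait[r], ann)
    }, character(1))
  } else {
    sig$direction <- character(0)
  }
  concordance <- do.call(rbind, lapply(unique(sig$protein), function(pr) {
    concordance_profile(sig$direction[sig$protein == pr], protein = pr,
                        cutoff = config$concordance_cutoff,
                        min_assoc = config$concordance_min_assoc)
  }))
  if (is.null(concordance)) {
    concordance <- data.frame(protein = character(), n_significant = integer(),
                              n_harmful = integer(), n_beneficial = integer(),
                              classification = character())
  }
  pleio <- pleiotropy_summary(sig)
  repl_ok <- repl_df[repl_df$status == "ok", , drop = FALSE]
  replication <- assess_replication(
    sig, repl_ok,
    n_proteins_available = max(1L, length(unique(repl_ok$protein)))
  )
  controls <- positive_control_concordance(est_df, ann, mult$threshold)
  drug_classes <- data.frame(
    protein = proteins,
    class = vapply(proteins, druggability_classify, character(1),
                   annotations = ann),
    stringsAsFactors = FALSE
  )

  # --- knowledge graph -----------------------------------------------------
  graph <- build_graph(est_df, ann, mult$threshold, coloc = coloc_df,
                       tissue_trait_cut = config$tissue_trait_cut)
  partition <- if (igraph::ecount(igraph::simplify(graph)) > 0) {
    louvain_communities(graph, seed = derive_seed(config$seed, "louvain"))
  } else {
    NULL
  }
  enrichment <- if (!is.null(partition)) {
    pathway_enrichment(partition, ann$pathways, proteins,
                       p_threshold = config$enrichment_p,
                       broad_max = config$broad_max)
  } else {
    NULL
  }

  evidence <- integrate_evidence(est_df, replication$records, coloc_df,
                                 mult$threshold)

  # --- artifacts -----------------------------------------------------------
  wt <- function(df, name) {
    utils::write.table(df, file.path(out, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(est_df, "mr_estimates.tsv")
  wt(repl_df, "mr_replication_estimates.tsv")
  wt(audit_df, "variant_audit.tsv")
  wt(coloc_df, "colocalization.tsv")
  wt(replication$records, "replication.tsv")
  wt(concordance, "concordance.tsv")
  wt(pleio$counts, "pleiotropy_counts.tsv")
  wt(controls$verdicts, "positive_controls.tsv")
  wt(drug_classes, "druggability.tsv")
  wt(evidence, "evidence_tiers.tsv")
  if (!is.null(partition)) {
    wt(data.frame(node = names(partition$membership),
                  community = unname(partition$membership)),
       "communities.tsv")
    wt(enrichment, "pathway_enrichment.tsv")
  }
  export_graph(graph, graphml_path = file.path(out, "graph.graphml"),
               json_path = file.path(out, "graph.json"))

  report <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("pqtlmr")),
    parameters = list(
      n_proteins = length(proteins), n_traits = length(traits),
      n_disease = n_disease, n_ref = config$n_ref,
      n_exposure = config$n_exposure, n_outcome = config$n_outcome,
      n_variants = config$n_variants, ld_decay = config$ld_decay,
      multiplicity_threshold = mult$threshold, n_tests = mult$n_tests,
      window_bp = config$mr$window_bp, maf_min = config$mr$maf_min,
      f_min = config$mr$f_min, r2_max = config$mr$r2_max,
      min_variants = config$mr$min_variants,
      coloc_window_bp = config$coloc$window_bp,
      pp4_call = config$coloc$pp4_call,
      concordance_cutoff = config$concordance_cutoff,
      tissue_trait_cut = config$tissue_trait_cut,
      enrichment_p = config$enrichment_p
    ),
    counts = list(
      n_pairs = nrow(est_df),
      n_estimates_ok = sum(est_df$status == "ok"),
      n_insufficient = sum(est_df$status == "insufficient_variants"),
      n_significant = nrow(sig),
      n_variants_dropped = nrow(audit_df),
      n_replication_assessed = replication$summary$n_assessed,
      n_replicated_nominal = replication$summary$n_nominal,
      n_replicated_conservative = replication$summary$n_conservative,
      n_colocalized = sum(coloc_df$colocalized %in% TRUE),
      n_communities = if (is.null(partition)) 0L else
        length(unique(partition$membership)),
      n_top_tier = sum(evidence$top_tier)
    )
  )
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(c(report, list(output_dir = out)), class = "run_report")
}

#' Integrate MR, replication and colocalization evidence
#'
#' Per protein-trait pair, records whether the pair is
#' multiplicity-significant in MR, nominally replicated with a concordant
#' direction, and colocalized (PP.H4 at or above the call threshold); the
#' top tier (`consistent support`) requires all three.
#'
#' @param estimates MR results table.
#' @param replication_records Records from [assess_replication()] (may have
#'   zero rows).
#' @param coloc Colocalization results table.
#' @param multiplicity_threshold MR significance threshold.
#' @return Data frame: `protein`, `trait`, `mr_significant`, `replicated`,
#'   `colocalized`, `top_tier`.
#' @export
integrate_evidence <- function(estimates, replication_records, coloc,
                               multiplicity_threshold) {
  key <- function(p, t) paste(p, t, sep = "\r")
  out <- data.frame(
    protein = estimates$protein, trait = estimates$trait,
    mr_significant = estimates$status == "ok" &
      is.finite(estimates$pval) & estimates$pval < multiplicity_threshold,
    stringsAsFactors = FALSE
  )
  ridx <- match(key(out$protein, out$trait),
                key(replication_records$protein, replication_records$trait))
  out$replicated <- !is.na(ridx) &
    replication_records$nominal_replicated[ridx] %in% TRUE
  cidx <- match(key(out$protein, out$trait), key(coloc$protein, coloc$trait))
  out$colocalized <- !is.na(cidx) & coloc$colocalized[cidx] %in% TRUE
  out$top_tier <- out$mr_significant & out$replicated & out$colocalized
  out
}
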