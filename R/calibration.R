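# Simulation studies of the pipeline's operating characteristics: type-I
# error and coverage of the GLS IVW estimator run through the full
# instrument-selection pipeline, MR-Egger intercept calibration, Rucker
# selection rates, colocalization discovery rates, and community recovery.
# These functions back both the test suite and the analysis drivers.

default_locus <- function(cfg) {
  pos <- variant_positions(cfg)
  span <- range(pos)
  third <- diff(span) / 3
  gene_locus("GENE", cfg$chrom, floor(span[1] + third),
             ceiling(span[2] - third))
}

calibration_config <- function(seed, rep, alpha_true = 0,
                               n_exposure = 3000L, n_outcome = 3000L,
                               n_ref = 1500L, n_variants = 20L,
                               ld_decay = 0.5,
                               pleiotropy_offset = 0) {
  causal <- unique(pmin(n_variants,
                        ceiling(n_variants * c(0.125, 0.375, 0.625, 0.875))))
  simulation_config(
    seed = derive_seed(seed, "rep", rep),
    n_ref = n_ref, n_exposure = n_exposure, n_outcome = n_outcome,
    n_variants = n_variants, ld_decay = ld_decay,
    causal_indices = causal,
    causal_betas = rep(c(0.4, 0.35, 0.3, 0.35), length.out = length(causal)),
    alpha_true = alpha_true,
    pleiotropy_betas = rep(pleiotropy_offset, n_variants)
  )
}

#' Null rejection rate and coverage of the full MR pipeline
#'
#' Replicates the end-to-end analysis — simulate a reference panel and a
#' two-sample GWAS pair, select and filter instruments, fit the GLS IVW
#' estimator — and summarizes the IVW p-values and 95% confidence intervals
#' against the known true effect.
#'
#' @param n_reps Number of replicates.
#' @param seed Master seed.
#' @param alpha_true True causal effect (0 gives the null calibration).
#' @param n_exposure,n_outcome,n_ref,n_variants,ld_decay Study dimensions.
#' @return List: `rejection_rate` (share of valid replicates with IVW
#'   p < 0.05), `coverage` (share whose 95% CI covers `alpha_true`),
#'   `mean_beta`, `n_valid`, `n_reps`, and the per-replicate `pvals`/`betas`.
#' @export
mr_calibration <- function(n_reps = 500, seed = 1L, alpha_true = 0,
                           n_exposure = 3000L, n_outcome = 3000L,
                           n_ref = 5000L, n_variants = 20L, ld_decay = 0.5) {
  pvals <- betas <- ses <- rep(NA_real_, n_reps)
  config <- mr_config()
  for (r in seq_len(n_reps)) {
    cfg <- calibration_config(seed, r, alpha_true = alpha_true,
                              n_exposure = n_exposure, n_outcome = n_outcome,
                              n_ref = n_ref, n_variants = n_variants,
                              ld_decay = ld_decay)
    panel <- simulate_reference_panel(cfg)
    study <- simulate_gwas_pair(cfg, panel)
    prep <- prepare_mr_input(study$exposure_stats, study$outcome_stats,
                             default_locus(cfg), panel, config)
    if (prep$status != "ok") next
    fit <- gls_fit(prep$input, with_intercept = FALSE)
    pvals[r] <- fit$pval
    betas[r] <- fit$beta
    ses[r] <- fit$se
  }
  valid <- is.finite(pvals)
  covered <- abs(betas[valid] - alpha_true) <= 1.96 * ses[valid]
  list(
    rejection_rate = mean(pvals[valid] < 0.05),
    coverage = mean(covered),
    mean_beta = mean(betas[valid]),
    n_valid = sum(valid), n_reps = n_reps,
    pvals = pvals, betas = betas, ses = ses
  )
}

# Simulate, harmonize and build an unfiltered mr_input (no clumping or
# diagnostic filters) -- used where calibration targets the estimator itself.
simulate_fit_input <- function(cfg) {
  panel <- simulate_reference_panel(cfg)
  study <- simulate_gwas_pair(cfg, panel)
  pair <- harmonize(study$exposure_stats, study$outcome_stats)
  pair$ld <- estimate_ld(panel, pair$variants)
  mr_input(pair)
}

#' MR-Egger intercept calibration under constant directional pleiotropy
#'
#' Simulates loci where every variant carries the same direct
#' variant-to-outcome effect (`pleiotropy_offset`) on top of a causal
#' protein effect, with independent variants and all-positive exposure
#' effects so the Egger intercept is identified, and fits MR-Egger per
#' replicate.
#'
#' @param n_reps Number of replicates.
#' @param seed Master seed.
#' @param pleiotropy_offset Planted constant direct effect.
#' @param alpha_true True causal effect.
#' @param n_variants Variants per locus (all causal).
#' @param n_exposure,n_outcome,n_ref Study dimensions.
#' @return List: `mean_intercept`, `sd_intercept`, `mc_se`, `bias`,
#'   `intercepts`, `n_reps`.
#' @export
egger_intercept_calibration <- function(n_reps = 200, seed = 1L,
                                        pleiotropy_offset = 0.05,
                                        alpha_true = 0.3, n_variants = 8L,
                                        n_exposure = 10000L,
                                        n_outcome = 3000L, n_ref = 1500L) {
  intercepts <- rep(NA_real_, n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- simulation_config(
      seed = derive_seed(seed, "egger", r),
      n_ref = n_ref, n_exposure = n_exposure, n_outcome = n_outcome,
      n_variants = n_variants, ld_decay = 0,
      causal_indices = seq_len(n_variants),
      causal_betas = seq(0.15, 0.6, length.out = n_variants),
      alpha_true = alpha_true,
      pleiotropy_betas = rep(pleiotropy_offset, n_variants)
    )
    fit <- gls_fit(simulate_fit_input(cfg), with_intercept = TRUE)
    intercepts[r] <- fit$intercept
  }
  m <- mean(intercepts)
  s <- stats::sd(intercepts)
  list(mean_intercept = m, sd_intercept = s, mc_se = s / sqrt(n_reps),
       bias = m - pleiotropy_offset, intercepts = intercepts,
       n_reps = n_reps)
}

#' Rucker model-selection rates
#'
#' Simulates replicates with a given constant pleiotropy offset, fits IVW
#' and MR-Egger, and reports how often each model is selected.
#'
#' @inheritParams egger_intercept_calibration
#' @param ld_decay AR(1) LD of the simulated loci.
#' @return List: `ivw_rate`, `egger_rate`, `n_reps`.
#' @export
rucker_selection_rate <- function(n_reps = 500, seed = 1L,
                                  pleiotropy_offset = 0,
                                  alpha_true = 0.3, n_variants = 8L,
                                  n_exposure = 3000L, n_outcome = 3000L,
                                  n_ref = 1500L, ld_decay = 0) {
  picks <- character(n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- simulation_config(
      seed = derive_seed(seed, "rucker", r),
      n_ref = n_ref, n_exposure = n_exposure, n_outcome = n_outcome,
      n_variants = n_variants, ld_decay = ld_decay,
      causal_indices = seq_len(n_variants),
      causal_betas = seq(0.15, 0.6, length.out = n_variants),
      alpha_true = alpha_true,
      pleiotropy_betas = rep(pleiotropy_offset, n_variants)
    )
    input <- simulate_fit_input(cfg)
    picks[r] <- rucker_select(gls_fit(input, with_intercept = FALSE),
                              gls_fit(input, with_intercept = TRUE))
  }
  list(ivw_rate = mean(picks == "IVW"),
       egger_rate = mean(picks == "MR-Egger"),
       n_reps = n_reps)
}

#' Colocalization discovery rate with a shared causal variant
#'
#' Simulates loci where one variant drives both the protein and the outcome
#' (through the protein) at strong signal, runs region colocalization, and
#' reports how often PP.H4 reaches the call threshold.
#'
#' @param n_reps Number of replicates.
#' @param seed Master seed.
#' @param alpha_true Protein-to-outcome effect (sets the outcome signal).
#' @param causal_beta Exposure effect of the causal variant.
#' @param n_variants Variants in the region.
#' @param n_exposure,n_outcome Cohort sizes.
#' @param config A [coloc_config()].
#' @return List: `h4_rate` (share with PP.H4 >= `pp4_call`), `pp_h4`,
#'   `n_reps`.
#' @export
coloc_shared_causal_rate <- function(n_reps = 100, seed = 1L,
                                     alpha_true = 0.8, causal_beta = 0.45,
                                     n_variants = 20L,
                                     n_exposure = 3000L, n_outcome = 3000L,
                                     config = coloc_config()) {
  pp4 <- rep(NA_real_, n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- simulation_config(
      seed = derive_seed(seed, "coloc", r),
      n_ref = 100L, n_exposure = n_exposure, n_outcome = n_outcome,
      n_variants = n_variants, ld_decay = 0.5,
      causal_indices = ceiling(n_variants / 2),
      causal_betas = causal_beta, alpha_true = alpha_true
    )
    panel <- simulate_reference_panel(cfg)
    study <- simulate_gwas_pair(cfg, panel)
    cp <- coloc_region(study$exposure_stats, study$outcome_stats,
                       default_locus(cfg), config = config)
    pp4[r] <- cp$pp[["H4"]]
  }
  list(h4_rate = mean(pp4 >= config$pp4_call), pp_h4 = pp4, n_reps = n_reps)
}

#' Colocalization with distinct causal variants
#'
#' Exposure and outcome are driven by different, weakly linked variants at
#' opposite ends of the region; reports how often H3 (two distinct causal
#' variants) is the modal hypothesis.
#'
#' @inheritParams coloc_shared_causal_rate
#' @return List: `h3_modal_rate`, `n_reps`.
#' @export
coloc_distinct_causal_rate <- function(n_reps = 50, seed = 1L,
                                       n_variants = 20L,
                                       n_exposure = 3000L, n_outcome = 3000L,
                                       config = coloc_config()) {
  modal <- rep(NA_character_, n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- simulation_config(
      seed = derive_seed(seed, "coloc_h3", r),
      n_ref = 100L, n_exposure = n_exposure, n_outcome = n_outcome,
      n_variants = n_variants, ld_decay = 0.5,
      causal_indices = 2L, causal_betas = 0.45, alpha_true = 0
    )
    cfg$pleiotropy_betas[n_variants - 1L] <- 0.45
    panel <- simulate_reference_panel(cfg)
    study <- simulate_gwas_pair(cfg, panel)
    cp <- coloc_region(study$exposure_stats, study$outcome_stats,
                       default_locus(cfg), config = config)
    modal[r] <- names(which.max(cp$pp))
  }
  list(h3_modal_rate = mean(modal == "H3"), modal = modal, n_reps = n_reps)
}

#' Planted two-block community recovery rate
#'
#' Generates graphs with two dense blocks (within-block edge probability
#' `p_within`) joined by a single cross edge, runs Louvain, and reports how
#' often the planted blocks are recovered exactly (up to label permutation).
#'
#' @param n_runs Number of seeded runs.
#' @param seed Master seed.
#' @param block_size Nodes per block.
#' @param p_within Within-block edge probability.
#' @return List: `recovery_rate`, `n_runs`.
#' @export
block_recovery_rate <- function(n_runs = 100, seed = 1L, block_size = 6L,
                                p_within = 0.9) {
  hits <- logical(n_runs)
  nodes <- c(paste0("a", seq_len(block_size)), paste0("b", seq_len(block_size)))
  planted <- rep(1:2, each = block_size)
  for (r in seq_len(n_runs)) {
    edges <- with_seed(derive_seed(seed, "block", r), {
      el <- NULL
      for (blk in list(seq_len(block_size), block_size + seq_len(block_size))) {
        cmb <- utils::combn(blk, 2)
        # keep each within-block edge with probability p_within, but ensure
        # the block stays connected via a spanning path
        keep <- stats::runif(ncol(cmb)) < p_within
        path <- cbind(blk[-length(blk)], blk[-1])
        el <- rbind(el, t(cmb[, keep, drop = FALSE]), path)
      }
      rbind(el, c(1L, block_size + 1L))
    })
    g <- igraph::graph_from_edgelist(unique(edges), directed = FALSE)
    igraph::V(g)$name <- nodes[as.integer(igraph::V(g))]
    part <- louvain_communities(g, seed = derive_seed(seed, "louvain", r))
    memb <- part$membership[nodes]
    hits[r] <- length(unique(memb)) == 2 &&
      all(tapply(memb, planted, function(x) length(unique(x)) == 1))
  }
  list(recovery_rate = mean(hits), n_runs = n_runs)
}
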