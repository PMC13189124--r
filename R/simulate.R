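# Seeded simulator: reference panels, pQTL/outcome GWAS summary statistics
# with known ground truth, and annotation fixtures. The generative model is a
# two-sample design: the exposure (protein) and outcome cohorts are disjoint
# and the reference panel is a third, independent sample used only for LD.

#' Simulation configuration for a single protein locus
#'
#' Describes the genetic architecture of one cis locus and the two GWAS
#' cohorts measured on it. Haplotypes are drawn from a latent Gaussian with
#' AR(1) correlation `ld_decay^|i-j|`, thresholded at the allele-frequency
#' quantile, so pairwise LD is controllable and dosages are valid 0/1/2.
#'
#' Structural model (quantitative traits, SD units):
#' \deqn{X = G\beta + \kappa\, G b_{rev} + e_x, \quad
#'       Y = \alpha (G\beta + e_x) + G b_{rev} + G b_{pleio} + e_y}
#' Variants in `reverse_indices` act on the outcome first and reach the
#' exposure only through the outcome's heritable component, attenuated by
#' \eqn{\kappa < 1} — exactly the pattern Steiger filtering is designed to
#' catch. Binary outcomes use a liability threshold on the same linear
#' predictor.
#'
#' @param seed Master integer seed; every random draw derives from it.
#' @param n_ref Reference-panel individuals (LD estimation only).
#' @param n_exposure,n_outcome GWAS cohort sizes.
#' @param n_variants Number of cis variants at the locus.
#' @param ld_decay AR(1) latent correlation in `[0, 1)`.
#' @param maf_range Length-2 numeric in `(0, 0.5]`; per-variant MAFs are drawn
#'   uniformly within it.
#' @param causal_indices 1-based variant indices affecting the exposure.
#' @param causal_betas Per-causal effect sizes (protein SDs per allele).
#' @param alpha_true Causal protein-to-outcome effect.
#' @param pleiotropy_betas Per-variant direct variant-to-outcome effects
#'   (length `n_variants`; default all zero).
#' @param reverse_indices 1-based indices of variants acting outcome-first.
#' @param reverse_betas Effects of the reverse variants on the outcome.
#' @param reverse_kappa Feedback of the outcome's own component onto the
#'   exposure (default 0.5); makes reverse variants Steiger-detectable.
#' @param outcome_type `"quantitative"` or `"binary"`.
#' @param case_fraction Case fraction for binary outcomes, in `(0, 1)`.
#' @param noise_x_sd,noise_y_sd Residual SDs of exposure and outcome.
#' @param chrom Chromosome label for emitted records.
#' @param pos_start,pos_step Base-pair position of the first variant and the
#'   spacing between adjacent variants.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_ref = 5000L,
                              n_exposure = 10000L,
                              n_outcome = 10000L,
                              n_variants = 20L,
                              ld_decay = 0.5,
                              maf_range = c(0.05, 0.5),
                              causal_indices = NULL,
                              causal_betas = NULL,
                              alpha_true = 0,
                              pleiotropy_betas = NULL,
                              reverse_indices = integer(0),
                              reverse_betas = numeric(0),
                              reverse_kappa = 0.5,
                              outcome_type = c("quantitative", "binary"),
                              case_fraction = 0.1,
                              noise_x_sd = 1,
                              noise_y_sd = 1,
                              chrom = "1",
                              pos_start = 1000000L,
                              pos_step = 5000L) {
  outcome_type <- match.arg(outcome_type)
  if (is.null(causal_indices)) {
    # default architecture: three causal cis variants spread over the locus
    causal_indices <- unique(pmax(1L, ceiling(n_variants * c(0.15, 0.5, 0.85))))
  }
  if (is.null(causal_betas)) {
    causal_betas <- rep(c(0.4, 0.3, 0.35), length.out = length(causal_indices))
  }
  if (is.null(pleiotropy_betas)) pleiotropy_betas <- numeric(n_variants)
  cfg <- list(
    seed = as.integer(seed), n_ref = as.integer(n_ref),
    n_exposure = as.integer(n_exposure), n_outcome = as.integer(n_outcome),
    n_variants = as.integer(n_variants), ld_decay = ld_decay,
    maf_range = maf_range, causal_indices = as.integer(causal_indices),
    causal_betas = causal_betas, alpha_true = alpha_true,
    pleiotropy_betas = pleiotropy_betas,
    reverse_indices = as.integer(reverse_indices),
    reverse_betas = reverse_betas, reverse_kappa = reverse_kappa,
    outcome_type = outcome_type, case_fraction = case_fraction,
    noise_x_sd = noise_x_sd, noise_y_sd = noise_y_sd,
    chrom = as.character(chrom), pos_start = as.integer(pos_start),
    pos_step = as.integer(pos_step)
  )
  validate_simulation_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

validate_simulation_config <- function(cfg) {
  num_ok <- function(x) is.numeric(x) && all(is.finite(x))
  if (!num_ok(cfg$seed)) stop("seed must be a finite number")
  if (cfg$n_ref < 2L) stop("n_ref must be >= 2")
  if (cfg$n_variants < 1L) stop("n_variants must be >= 1")
  if (cfg$n_exposure < 3L || cfg$n_outcome < 3L) stop("cohort sizes must be >= 3")
  if (!num_ok(cfg$ld_decay) || cfg$ld_decay < 0 || cfg$ld_decay >= 1) {
    stop("ld_decay must lie in [0, 1)")
  }
  if (length(cfg$maf_range) != 2L || !num_ok(cfg$maf_range) ||
      any(cfg$maf_range <= 0) || any(cfg$maf_range > 0.5) ||
      cfg$maf_range[1] > cfg$maf_range[2]) {
    stop("maf_range must be an increasing pair in (0, 0.5]")
  }
  if (length(cfg$causal_indices) != length(cfg$causal_betas)) {
    stop("causal_indices and causal_betas lengths differ")
  }
  if (length(cfg$causal_indices) &&
      (any(cfg$causal_indices < 1L) || any(cfg$causal_indices > cfg$n_variants))) {
    stop("causal_indices out of range [1, n_variants]")
  }
  if (length(cfg$pleiotropy_betas) != cfg$n_variants) {
    stop("pleiotropy_betas must have length n_variants")
  }
  if (length(cfg$reverse_indices) != length(cfg$reverse_betas)) {
    stop("reverse_indices and reverse_betas lengths differ")
  }
  if (length(cfg$reverse_indices) &&
      (any(cfg$reverse_indices < 1L) || any(cfg$reverse_indices > cfg$n_variants))) {
    stop("reverse_indices out of range")
  }
  if (!num_ok(cfg$alpha_true) || !num_ok(cfg$noise_x_sd) || !num_ok(cfg$noise_y_sd)) {
    stop("effect and noise parameters must be finite")
  }
  if (cfg$noise_x_sd < 0 || cfg$noise_y_sd < 0) stop("noise SDs must be >= 0")
  if (cfg$outcome_type == "binary" &&
      (cfg$case_fraction <= 0 || cfg$case_fraction >= 1)) {
    stop("case_fraction must lie in (0, 1) for binary outcomes")
  }
  invisible(cfg)
}

variant_ids <- function(cfg) sprintf("v%04d", seq_len(cfg$n_variants))

variant_positions <- function(cfg) {
  cfg$pos_start + (seq_len(cfg$n_variants) - 1L) * cfg$pos_step
}

# Non-palindromic allele pairs cycled across the locus so harmonization is
# unambiguous by default; palindromes are constructed explicitly in tests.
variant_alleles <- function(cfg) {
  pairs <- matrix(c("A", "G", "C", "T", "G", "A", "T", "C"), ncol = 2, byrow = TRUE)
  idx <- (seq_len(cfg$n_variants) - 1L) %% nrow(pairs) + 1L
  list(effect = pairs[idx, 1], other = pairs[idx, 2])
}

#' Per-variant target minor allele frequencies of a configuration
#'
#' Deterministic given the seed; shared by the reference panel and both GWAS
#' cohorts so all three samples come from one population.
#'
#' @param cfg A [simulation_config()].
#' @return Numeric vector of MAFs, length `n_variants`.
#' @export
variant_mafs <- function(cfg) {
  with_seed(
    derive_seed(cfg$seed, "maf"),
    stats::runif(cfg$n_variants, cfg$maf_range[1], cfg$maf_range[2])
  )
}

# Draw n individuals' dosages: two latent-Gaussian AR(1) haplotypes each,
# thresholded at the upper maf-quantile.
draw_dosages <- function(n, cfg, mafs, stream_seed) {
  p <- cfg$n_variants
  rho <- cfg$ld_decay
  thr <- stats::qnorm(1 - mafs)
  with_seed(stream_seed, {
    G <- matrix(0L, n, p)
    for (hap in 1:2) {
      Z <- matrix(stats::rnorm(n * p), n, p)
      if (p > 1 && rho > 0) {
        for (j in 2:p) Z[, j] <- rho * Z[, j - 1] + sqrt(1 - rho^2) * Z[, j]
      }
      G <- G + (Z > matrix(thr, n, p, byrow = TRUE))
    }
    storage.mode(G) <- "integer"
    G
  })
}

#' Simulate a reference genotype panel
#'
#' Draws `n_ref` individuals at the configured locus. Each individual is the
#' sum of two haplotypes; each haplotype is a latent AR(1) Gaussian vector
#' thresholded at `qnorm(1 - MAF)`, so adjacent-variant LD is governed by
#' `ld_decay` and dosages are valid 0/1/2 counts of the effect allele.
#'
#' @param cfg A [simulation_config()].
#' @return Integer matrix (`n_ref` rows, `n_variants` columns) with variant
#'   ids as column names and the target MAFs in `attr(, "mafs")`.
#' @export
#' @examples
#' cfg <- simulation_config(seed = 7, n_ref = 200, n_variants = 5)
#' panel <- simulate_reference_panel(cfg)
#' dim(panel)
simulate_reference_panel <- function(cfg) {
  validate_simulation_config(cfg)
  mafs <- variant_mafs(cfg)
  G <- draw_dosages(cfg$n_ref, cfg, mafs, derive_seed(cfg$seed, "panel"))
  colnames(G) <- variant_ids(cfg)
  attr(G, "mafs") <- mafs
  G
}

sumstat_frame <- function(cfg, beta, se, n, eaf) {
  al <- variant_alleles(cfg)
  z <- beta / se
  data.frame(
    variant_id = variant_ids(cfg),
    chrom = cfg$chrom,
    pos = variant_positions(cfg),
    effect_allele = al$effect,
    other_allele = al$other,
    eaf = eaf,
    beta = beta,
    se = se,
    pval = 2 * stats::pnorm(-abs(z)),
    n = n,
    stringsAsFactors = FALSE
  )
}

# Marginal per-variant OLS of y on each dosage column, vectorized.
marginal_gwas <- function(G, y) {
  n <- nrow(G)
  gc <- scale(G, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  ssx <- colSums(gc^2)
  if (any(ssx == 0)) stop("monomorphic variant in simulated cohort; increase n or MAF")
  beta <- as.vector(crossprod(gc, yc)) / ssx
  ssy <- sum(yc^2)
  s2 <- pmax(ssy - beta^2 * ssx, 0) / (n - 2)
  list(beta = beta, se = sqrt(s2 / ssx))
}

marginal_logistic_gwas <- function(G, y) {
  p <- ncol(G)
  beta <- se <- numeric(p)
  for (j in seq_len(p)) {
    fit <- stats::glm.fit(cbind(1, G[, j]), y, family = stats::binomial())
    sm <- chol2inv(chol(crossprod(sqrt(fit$weights) * cbind(1, G[, j]))))
    beta[j] <- fit$coefficients[2]
    se[j] <- sqrt(sm[2, 2])
  }
  list(beta = beta, se = se)
}

#' Simulate a two-sample exposure/outcome GWAS pair
#'
#' Draws disjoint exposure and outcome cohorts from the same population as
#' the reference panel, generates the protein and outcome phenotypes under the
#' configured structural model, and summarizes each cohort by per-variant
#' marginal regressions (OLS for quantitative traits, logistic fits reporting
#' log-odds for binary outcomes).
#'
#' @param cfg A [simulation_config()].
#' @param panel Reference panel from [simulate_reference_panel()]; used only
#'   to check consistency (LD estimation happens downstream).
#' @return A `simulated_study` list with elements `panel`, `exposure_stats`,
#'   `outcome_stats` (summary-statistic data frames) and `truth` (the
#'   generating configuration).
#' @export
simulate_gwas_pair <- function(cfg, panel) {
  validate_simulation_config(cfg)
  if (ncol(panel) != cfg$n_variants ||
      !identical(colnames(panel), variant_ids(cfg))) {
    stop("panel is not consistent with the configuration")
  }
  mafs <- variant_mafs(cfg)

  beta_vec <- numeric(cfg$n_variants)
  beta_vec[cfg$causal_indices] <- cfg$causal_betas
  rev_vec <- numeric(cfg$n_variants)
  rev_vec[cfg$reverse_indices] <- cfg$reverse_betas

  make_phenos <- function(G, seed_label) {
    n <- nrow(G)
    with_seed(derive_seed(cfg$seed, seed_label, "noise"), {
      e_x <- stats::rnorm(n, 0, cfg$noise_x_sd)
      e_y <- stats::rnorm(n, 0, cfg$noise_y_sd)
      x_exo <- as.vector(G %*% beta_vec) + e_x
      y_rev <- as.vector(G %*% rev_vec)
      y_lin <- cfg$alpha_true * x_exo + y_rev + e_y +
        as.vector(G %*% cfg$pleiotropy_betas)
      # reverse variants reach the exposure only through the outcome's
      # heritable component, attenuated by reverse_kappa
      x <- x_exo + cfg$reverse_kappa * y_rev
      list(x = x, y = y_lin)
    })
  }

  Ge <- draw_dosages(cfg$n_exposure, cfg, mafs, derive_seed(cfg$seed, "cohort_exposure"))
  Go <- draw_dosages(cfg$n_outcome, cfg, mafs, derive_seed(cfg$seed, "cohort_outcome"))
  ph_e <- make_phenos(Ge, "exposure")
  ph_o <- make_phenos(Go, "outcome")

  gx <- marginal_gwas(Ge, ph_e$x)
  if (cfg$outcome_type == "binary") {
    thr <- stats::quantile(ph_o$y, 1 - cfg$case_fraction)
    cases <- as.integer(ph_o$y > thr)
    gy <- marginal_logistic_gwas(Go, cases)
  } else {
    gy <- marginal_gwas(Go, ph_o$y)
  }

  study <- list(
    panel = panel,
    exposure_stats = sumstat_frame(cfg, gx$beta, gx$se, cfg$n_exposure,
                                   colMeans(Ge) / 2),
    outcome_stats = sumstat_frame(cfg, gy$beta, gy$se, cfg$n_outcome,
                                  colMeans(Go) / 2),
    truth = cfg
  )
  class(study) <- "simulated_study"
  study
}

#' Simulate annotation fixtures
#'
#' Builds the annotation tables consumed by the prioritization and graph
#' layers: druggability classes, beneficial-direction labels, a disease-group
#' map, pathway membership (with optional planted enriched communities),
#' tissue expression (with optional planted overexpression), tissue-trait
#' literature co-occurrence counts, trial records with mechanism labels, and
#' protein interactors.
#'
#' @param seed Integer seed.
#' @param proteins,traits,tissues,pathways Non-empty unique character vectors.
#' @param n_disease Number of `traits` treated as diseases (the first
#'   `n_disease`); the rest are biomarkers.
#' @param planted_pathways Optional named list `pathway -> protein vector`
#'   forcing those memberships (planted enrichment for tests).
#' @param planted_overexpression Optional data frame with columns `protein`,
#'   `tissue`; those cells get a ten-fold expression boost.
#' @return An `annotation_bundle` list of data frames/matrices.
#' @export
simulate_annotations <- function(seed, proteins, traits, tissues, pathways,
                                 n_disease = ceiling(length(traits) / 2),
                                 planted_pathways = NULL,
                                 planted_overexpression = NULL) {
  for (nm in list(proteins, traits, tissues, pathways)) {
    if (!length(nm)) stop("name lists must be non-empty")
    if (anyDuplicated(nm)) stop("duplicate identifiers in annotation inputs")
  }
  n_disease <- min(n_disease, length(traits))
  groups13 <- c(
    "autoimmune", "cardiac", "metabolic", "cancer", "neurological",
    "respiratory", "renal", "hepatic", "vascular", "infectious",
    "musculoskeletal", "ophthalmic", "hematological"
  )
  with_seed(derive_seed(seed, "annotations"), {
    druggability <- data.frame(
      protein = proteins,
      class = sample(c("drugged", "druggable", "neither"), length(proteins),
                     replace = TRUE, prob = c(0.5, 0.3, 0.2)),
      stringsAsFactors = FALSE
    )
    trait_type <- rep(c("disease", "biomarker"),
                      c(n_disease, length(traits) - n_disease))
    # Diseases: risk increase is always harmful. Biomarkers carry a label for
    # whether a raising effect is harmful or beneficial.
    beneficial_direction <- data.frame(
      trait = traits,
      type = trait_type,
      increase_is = ifelse(trait_type == "disease", "harmful",
                           sample(c("harmful", "beneficial"),
                                  length(traits), replace = TRUE)),
      stringsAsFactors = FALSE
    )
    disease_group <- data.frame(
      trait = traits,
      group = sample(groups13, length(traits), replace = TRUE),
      stringsAsFactors = FALSE
    )
    memb <- do.call(rbind, lapply(proteins, function(pr) {
      k <- sample(seq_len(min(3, length(pathways))), 1)
      data.frame(protein = pr, pathway = sample(pathways, k),
                 stringsAsFactors = FALSE)
    }))
    if (!is.null(planted_pathways)) {
      extra <- do.call(rbind, lapply(names(planted_pathways), function(pw) {
        data.frame(protein = planted_pathways[[pw]], pathway = pw,
                   stringsAsFactors = FALSE)
      }))
      memb <- unique(rbind(memb, extra))
    }
    expr <- matrix(stats::rlnorm(length(proteins) * length(tissues), 2, 0.3),
                   length(proteins), length(tissues),
                   dimnames = list(proteins, tissues))
    if (!is.null(planted_overexpression)) {
      for (i in seq_len(nrow(planted_overexpression))) {
        expr[planted_overexpression$protein[i],
             planted_overexpression$tissue[i]] <-
          expr[planted_overexpression$protein[i],
               planted_overexpression$tissue[i]] * 10
      }
    }
    n_total <- 100000L
    tt <- expand.grid(tissue = tissues, trait = traits,
                      stringsAsFactors = FALSE)
    tt$n_tissue <- sample(200:2000, nrow(tt), replace = TRUE)
    tt$n_trait <- sample(200:2000, nrow(tt), replace = TRUE)
    tt$n_both <- stats::rbinom(nrow(tt), size = pmin(tt$n_tissue, tt$n_trait),
                               prob = tt$n_trait / n_total)
    tt$n_total <- n_total
    n_trials <- max(3L, length(proteins))
    trials <- data.frame(
      protein = sample(proteins, n_trials, replace = TRUE),
      trait = sample(traits[seq_len(n_disease)], n_trials, replace = TRUE),
      phase = sample(1:4, n_trials, replace = TRUE),
      mechanism = sample(c("inhibitor", "agonist"), n_trials, replace = TRUE),
      stringsAsFactors = FALSE
    )
    interactors <- do.call(rbind, lapply(proteins, function(pr) {
      partners <- setdiff(proteins, pr)
      k <- min(length(partners), sample(0:2, 1))
      if (k == 0) return(NULL)
      data.frame(protein = pr, interactor = sample(partners, k),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(interactors)) {
      interactors <- data.frame(protein = character(), interactor = character(),
                                stringsAsFactors = FALSE)
    }
    bundle <- list(
      druggability = druggability,
      beneficial_direction = beneficial_direction,
      disease_group = disease_group,
      pathways = memb,
      tissue_expression = expr,
      tissue_trait_counts = tt,
      trials = trials,
      interactors = interactors
    )
    class(bundle) <- "annotation_bundle"
    bundle
  })
}
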