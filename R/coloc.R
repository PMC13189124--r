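# Approximate-Bayes-factor colocalization: per-variant Wakefield log-ABFs
# for each trait, combined over the five hypotheses (H0 no association,
# H1/H2 one trait only, H3 two distinct causal variants, H4 one shared
# causal variant) in log space.

#' Colocalization configuration
#'
#' @param window_bp Flanking window around the gene body (default 500000 bp).
#' @param prior_p1,prior_p2 Per-variant priors of association with trait 1 /
#'   trait 2 only (default 1e-4 each).
#' @param prior_p12 Per-variant prior of association with both (default 1e-5,
#'   must not exceed `min(p1, p2)`).
#' @param sd_prior_quant Effect-size prior SD for quantitative traits (0.15).
#' @param sd_prior_binary Log-odds prior SD for binary traits (0.2).
#' @param pp4_call Posterior probability of H4 at or above which a region is
#'   called colocalized (default 0.8, inclusive).
#' @return A `coloc_config` list.
#' @export
coloc_config <- function(window_bp = 500000, prior_p1 = 1e-4, prior_p2 = 1e-4,
                         prior_p12 = 1e-5, sd_prior_quant = 0.15,
                         sd_prior_binary = 0.2, pp4_call = 0.8) {
  for (p in c(prior_p1, prior_p2, prior_p12)) {
    if (p <= 0 || p >= 1) stop("priors must lie in (0, 1)")
  }
  if (prior_p12 > min(prior_p1, prior_p2)) {
    stop("prior_p12 must not exceed min(prior_p1, prior_p2)")
  }
  if (pp4_call <= 0 || pp4_call >= 1) stop("pp4_call must lie in (0, 1)")
  structure(list(window_bp = window_bp, prior_p1 = prior_p1,
                 prior_p2 = prior_p2, prior_p12 = prior_p12,
                 sd_prior_quant = sd_prior_quant,
                 sd_prior_binary = sd_prior_binary, pp4_call = pp4_call),
            class = "coloc_config")
}

#' Wakefield log approximate Bayes factor
#'
#' For a variant with estimate `beta`, standard error `se` and effect-size
#' prior SD `sd_prior`: with `z = beta/se`, `V = se^2`, `W = sd_prior^2` and
#' shrinkage `r = W / (W + V)`, the log-ABF is `0.5 * (log(1 - r) + r * z^2)`.
#'
#' @param beta,se Effect estimate and positive standard error (vectorized).
#' @param sd_prior Prior SD of the true effect.
#' @return Log approximate Bayes factor(s).
#' @export
#' @examples
#' wakefield_labf(0.5, 0.05, 0.15)
wakefield_labf <- function(beta, se, sd_prior) {
  if (any(se <= 0)) stop("se must be positive")
  z <- beta / se
  r <- sd_prior^2 / (sd_prior^2 + se^2)
  0.5 * (log1p(-r) + r * z^2)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Posterior hypothesis probabilities from per-variant log-ABFs
#'
#' Under a single causal variant per trait, sums the per-variant evidence for
#' each hypothesis (all in log space) with the configured priors:
#' `h0 = 1`, `h1 = p1*S1`, `h2 = p2*S2`, `h3 = p1*p2*(S1*S2 - S12)`,
#' `h4 = p12*S12`, where `S1 = sum(exp(labf1))`, `S2 = sum(exp(labf2))` and
#' `S12 = sum(exp(labf1 + labf2))`, then normalizes.
#'
#' @param labf1,labf2 Equal-length log-ABF vectors over the same variants.
#' @param config A [coloc_config()].
#' @param protein,trait Labels carried into the result.
#' @return A `coloc_posterior` list: `pp` (named H0..H4, sums to 1),
#'   `n_variants`, `colocalized` (`pp["H4"] >= pp4_call`, inclusive).
#' @export
coloc_posteriors <- function(labf1, labf2, config = coloc_config(),
                             protein = NA_character_, trait = NA_character_) {
  if (length(labf1) != length(labf2)) stop("log-ABF vectors differ in length")
  if (!length(labf1)) stop("no variants supplied")
  lS1 <- logsumexp(labf1)
  lS2 <- logsumexp(labf2)
  lS12 <- logsumexp(labf1 + labf2)
  # S1*S2 - S12 = sum over ordered pairs with distinct variants
  l_prod <- lS1 + lS2
  if (lS12 > l_prod + 1e-9) stop("inconsistent evidence sums (S12 > S1*S2)")
  l_h3_sum <- if (lS12 >= l_prod) -Inf else l_prod + log1p(-exp(lS12 - l_prod))
  lw <- c(
    H0 = 0,
    H1 = log(config$prior_p1) + lS1,
    H2 = log(config$prior_p2) + lS2,
    H3 = log(config$prior_p1) + log(config$prior_p2) + l_h3_sum,
    H4 = log(config$prior_p12) + lS12
  )
  pp <- exp(lw - logsumexp(lw))
  pp <- pp / sum(pp)
  structure(list(
    protein = protein, trait = trait, pp = pp,
    n_variants = length(labf1),
    colocalized = unname(pp["H4"] >= config$pp4_call),
    status = "ok"
  ), class = "coloc_posterior")
}

#' Colocalization over a gene region
#'
#' Intersects exposure and outcome variants inside the closed window
#' `[start - window_bp, end + window_bp]` around the gene body and runs
#' ABF colocalization on every overlapping variant — deliberately with no
#' MAF or p-value filtering, since any variant in the region could be the
#' causal one. The per-trait effect-size prior SD follows the trait type.
#'
#' @param exposure,outcome Summary-statistic data frames.
#' @param locus A [gene_locus()].
#' @param config A [coloc_config()].
#' @param outcome_type `"quantitative"` or `"binary"` (selects the outcome
#'   prior SD).
#' @param protein,trait Labels carried into the result.
#' @return A `coloc_posterior`; when no variants overlap, a stub with
#'   `status = "no_overlap"` and `NA` probabilities.
#' @export
coloc_region <- function(exposure, outcome, locus, config = coloc_config(),
                         outcome_type = c("quantitative", "binary"),
                         protein = locus$gene_id, trait = "outcome") {
  outcome_type <- match.arg(outcome_type)
  lo <- locus$start - config$window_bp
  hi <- locus$end + config$window_bp
  ex <- exposure[exposure$chrom == locus$chrom &
                   exposure$pos >= lo & exposure$pos <= hi, , drop = FALSE]
  shared <- intersect(ex$variant_id, outcome$variant_id)
  if (!length(shared)) {
    return(structure(list(
      protein = protein, trait = trait,
      pp = stats::setNames(rep(NA_real_, 5), paste0("H", 0:4)),
      n_variants = 0L, colocalized = NA, status = "no_overlap"
    ), class = "coloc_posterior"))
  }
  ex <- ex[match(shared, ex$variant_id), , drop = FALSE]
  ou <- outcome[match(shared, outcome$variant_id), , drop = FALSE]
  sd_out <- if (outcome_type == "binary") config$sd_prior_binary else
    config$sd_prior_quant
  labf1 <- wakefield_labf(ex$beta, ex$se, config$sd_prior_quant)
  labf2 <- wakefield_labf(ou$beta, ou$se, sd_out)
  coloc_posteriors(labf1, labf2, config, protein = protein, trait = trait)
}

#' Collect colocalization results into a table
#'
#' @param posteriors List of `coloc_posterior` objects.
#' @return Data frame with `pp_h0`..`pp_h4` columns.
#' @export
coloc_results_table <- function(posteriors) {
  do.call(rbind, lapply(posteriors, function(cp) {
    data.frame(protein = cp$protein, trait = cp$trait,
               n_variants = cp$n_variants,
               pp_h0 = cp$pp[["H0"]], pp_h1 = cp$pp[["H1"]],
               pp_h2 = cp$pp[["H2"]], pp_h3 = cp$pp[["H3"]],
               pp_h4 = cp$pp[["H4"]], colocalized = cp$colocalized,
               status = cp$status, stringsAsFactors = FALSE)
  }))
}
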