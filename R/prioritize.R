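# Post-MR layers: direction classification against beneficial-direction
# labels, 75% concordance profiling, pleiotropy summaries, replication
# assessment, positive-control concordance, druggability classes.

#' Classify an MR effect as harmful or beneficial
#'
#' Diseases: a risk-increasing effect (`beta > 0` on the log-odds scale) is
#' harmful, risk-decreasing is beneficial. Biomarkers: the sign of the effect
#' is composed with the trait's beneficial-direction label (e.g. lowering a
#' biomarker whose increase is harmful is beneficial).
#'
#' @param beta MR effect of a protein increase on the trait (non-zero).
#' @param trait Trait name, present in `annotations$beneficial_direction`.
#' @param annotations An `annotation_bundle` (see [simulate_annotations()]).
#' @return `"harmful"` or `"beneficial"`.
#' @export
classify_direction <- function(beta, trait, annotations) {
  if (is.na(beta) || beta == 0) stop("undirected: beta is zero or missing")
  bd <- annotations$beneficial_direction
  row <- bd[bd$trait == trait, , drop = FALSE]
  if (nrow(row) != 1) stop("missing beneficial-direction annotation for ", trait)
  if (row$type == "disease") {
    if (beta > 0) "harmful" else "beneficial"
  } else {
    raising_is <- row$increase_is
    if (beta > 0) raising_is else
      if (raising_is == "harmful") "beneficial" else "harmful"
  }
}

#' Directional concordance profile per protein
#'
#' Among a protein's multiplicity-significant associations, counts harmful
#' and beneficial directions and classifies the protein as
#' harmful-consistent or beneficial-consistent when at least `cutoff` of the
#' associations share the direction (inclusive), `mixed` otherwise, and
#' `insufficient` below `min_assoc` associations.
#'
#' @param directions Character vector of `"harmful"`/`"beneficial"` labels
#'   for one protein's significant associations.
#' @param protein Protein label.
#' @param cutoff Concordance proportion (default 0.75, inclusive).
#' @param min_assoc Minimum association count (default 4).
#' @return A one-row data frame: `protein`, `n_significant`, `n_harmful`,
#'   `n_beneficial`, `classification`.
#' @export
concordance_profile <- function(directions, protein = NA_character_,
                                cutoff = 0.75, min_assoc = 4) {
  stopifnot(all(directions %in% c("harmful", "beneficial")))
  n <- length(directions)
  nh <- sum(directions == "harmful")
  nb <- n - nh
  classification <- if (n < min_assoc) {
    "insufficient"
  } else if (nh / n >= cutoff) {
    "harmful-consistent"
  } else if (nb / n >= cutoff) {
    "beneficial-consistent"
  } else {
    "mixed"
  }
  data.frame(protein = protein, n_significant = n, n_harmful = nh,
             n_beneficial = nb, classification = classification,
             stringsAsFactors = FALSE)
}

#' Per-protein pleiotropy counts with quartile summary
#'
#' Counts distinct traits per protein among significant associations and
#' summarizes the counts by median and quartiles (linear interpolation
#' between order statistics, `stats::quantile` type 7).
#'
#' @param significant Data frame of significant associations with columns
#'   `protein` and `trait`.
#' @return List with `counts` (data frame `protein`, `n_traits`) and
#'   `summary` (`median`, `q1`, `q3`, `n_proteins`).
#' @export
pleiotropy_summary <- function(significant) {
  if (!nrow(significant)) {
    return(list(counts = data.frame(protein = character(),
                                    n_traits = integer()),
                summary = list(median = NA_real_, q1 = NA_real_,
                               q3 = NA_real_, n_proteins = 0L)))
  }
  uniq <- unique(significant[, c("protein", "trait")])
  tab <- table(uniq$protein)
  counts <- data.frame(protein = names(tab), n_traits = as.integer(tab),
                       stringsAsFactors = FALSE)
  qs <- stats::quantile(counts$n_traits, c(0.25, 0.5, 0.75), type = 7)
  list(counts = counts,
       summary = list(median = unname(qs[2]), q1 = unname(qs[1]),
                      q3 = unname(qs[3]), n_proteins = nrow(counts)))
}

#' Assess replication of discovery associations
#'
#' Matches discovery and replication estimates on (protein, trait). An
#' association replicates nominally when the replication effect has the same
#' sign and p < 0.05, and conservatively when the p-value additionally beats
#' the Bonferroni threshold `0.05 / n_proteins_available`. Percentages are
#' reported with nearest-integer rounding.
#'
#' @param discovery,replication Data frames with columns `protein`, `trait`,
#'   `beta`, `pval`.
#' @param n_proteins_available Number of proteins with replication data
#'   (denominator of the conservative threshold).
#' @return List with `records` (per-pair flags), `unmatched` (audit of
#'   discovery pairs without replication data), and `summary` (`n_assessed`,
#'   `n_nominal`, `pct_nominal`, `n_conservative`, `pct_conservative`,
#'   `conservative_threshold`).
#' @export
assess_replication <- function(discovery, replication, n_proteins_available) {
  if (n_proteins_available < 1) stop("n_proteins_available must be >= 1")
  thr <- 0.05 / n_proteins_available
  key <- function(df) paste(df$protein, df$trait, sep = "\r")
  idx <- match(key(discovery), key(replication))
  matched <- !is.na(idx)
  unmatched <- discovery[!matched, c("protein", "trait"), drop = FALSE]
  if (nrow(unmatched)) unmatched$reason <- "no_replication_data"
  d <- discovery[matched, , drop = FALSE]
  r <- replication[idx[matched], , drop = FALSE]
  same_sign <- sign(d$beta) == sign(r$beta) & sign(d$beta) != 0
  records <- data.frame(
    protein = d$protein, trait = d$trait,
    discovery_beta = d$beta, discovery_p = d$pval,
    replication_beta = r$beta, replication_p = r$pval,
    nominal_replicated = same_sign & r$pval < 0.05,
    conservative_replicated = same_sign & r$pval < thr,
    stringsAsFactors = FALSE
  )
  n <- nrow(records)
  n_nom <- sum(records$nominal_replicated)
  n_con <- sum(records$conservative_replicated)
  list(
    records = records,
    unmatched = unmatched,
    summary = list(
      n_assessed = n,
      n_nominal = n_nom,
      pct_nominal = if (n) round(100 * n_nom / n) else NA_integer_,
      n_conservative = n_con,
      pct_conservative = if (n) round(100 * n_con / n) else NA_integer_,
      conservative_threshold = thr
    )
  )
}

# Trials attributable to a protein directly or through its interactors.
linked_trials <- function(protein, annotations) {
  partners <- annotations$interactors$interactor[
    annotations$interactors$protein == protein]
  tr <- annotations$trials
  tr[tr$protein %in% c(protein, partners), , drop = FALSE]
}

#' Positive-control concordance between MR estimates and trial mechanisms
#'
#' Positive controls are protein-trait pairs with phase >= 3 trials for the
#' same trait targeting the protein or one of its interactors. A pair is
#' identified when its MR p-value reaches at least nominal significance, and
#' concordant when a risk-increasing MR effect meets an inhibitor mechanism
#' or a protective effect meets an agonist. Pairs with an unknown mechanism
#' are skipped with an audit entry.
#'
#' @param estimates Data frame with `protein`, `trait`, `beta`, `pval`.
#' @param annotations An `annotation_bundle` with `trials` and `interactors`.
#' @param multiplicity_threshold Threshold for the top significance tier.
#' @param min_phase Minimum trial phase (default 3).
#' @return List with `verdicts` (per-pair tier and concordance), `skipped`,
#'   and `summary` (`n_controls`, `n_identified`, `pct_identified`,
#'   `n_concordant`, `pct_concordant` — percentages of identified pairs,
#'   nearest-integer rounding).
#' @export
positive_control_concordance <- function(estimates, annotations,
                                         multiplicity_threshold,
                                         min_phase = 3) {
  tr <- annotations$trials
  tr <- tr[tr$phase >= min_phase, , drop = FALSE]
  skipped <- tr[!tr$mechanism %in% c("inhibitor", "agonist"), , drop = FALSE]
  if (nrow(skipped)) skipped$reason <- "unknown_mechanism"
  tr <- tr[tr$mechanism %in% c("inhibitor", "agonist"), , drop = FALSE]

  verdicts <- NULL
  for (prot in unique(estimates$protein)) {
    lt <- linked_trials(prot, annotations)
    lt <- lt[lt$phase >= min_phase &
               lt$mechanism %in% c("inhibitor", "agonist"), , drop = FALSE]
    if (!nrow(lt)) next
    for (trait in unique(lt$trait)) {
      est <- estimates[estimates$protein == prot & estimates$trait == trait, ,
                       drop = FALSE]
      if (!nrow(est)) next
      est <- est[1, ]
      mech <- unique(lt$mechanism[lt$trait == trait])
      # a pair trialed with both mechanisms is ambiguous; use the majority,
      # ties resolved as inhibitor (the more common development mode)
      mech <- if (length(mech) == 1) mech else {
        tabm <- sort(table(lt$mechanism[lt$trait == trait]), decreasing = TRUE)
        if (length(tabm) > 1 && tabm[1] == tabm[2]) "inhibitor" else names(tabm)[1]
      }
      tier <- if (!is.na(est$pval) && est$pval < multiplicity_threshold) {
        "multiplicity"
      } else if (!is.na(est$pval) && est$pval < 0.05) {
        "nominal"
      } else {
        "none"
      }
      concordant <- if (is.na(est$beta) || est$beta == 0) NA else {
        (est$beta > 0 && mech == "inhibitor") ||
          (est$beta < 0 && mech == "agonist")
      }
      verdicts <- rbind(verdicts, data.frame(
        protein = prot, trait = trait, mechanism = mech, tier = tier,
        beta = est$beta, pval = est$pval, concordant = concordant,
        stringsAsFactors = FALSE
      ))
    }
  }
  if (is.null(verdicts)) {
    verdicts <- data.frame(protein = character(), trait = character(),
                           mechanism = character(), tier = character(),
                           beta = numeric(), pval = numeric(),
                           concordant = logical(), stringsAsFactors = FALSE)
  }
  identified <- verdicts[verdicts$tier != "none", , drop = FALSE]
  n_controls <- nrow(verdicts)
  n_ident <- nrow(identified)
  n_conc <- sum(identified$concordant, na.rm = TRUE)
  list(
    verdicts = verdicts,
    skipped = skipped,
    summary = list(
      n_controls = n_controls,
      n_identified = n_ident,
      pct_identified = if (n_controls) round(100 * n_ident / n_controls)
        else NA_integer_,
      n_concordant = n_conc,
      pct_concordant = if (n_ident) round(100 * n_conc / n_ident)
        else NA_integer_
    )
  )
}

#' Summary percentages from identified/concordant counts
#'
#' Nearest-integer percentage of `numerator / denominator`; the convention
#' used for every printed percentage in this package.
#'
#' @param numerator,denominator Non-negative counts, `denominator > 0`.
#' @return Integer percentage.
#' @export
#' @examples
#' percent_of(22, 33)
percent_of <- function(numerator, denominator) {
  if (denominator <= 0) stop("denominator must be positive")
  as.integer(round(100 * numerator / denominator))
}

#' Druggability classification of a protein
#'
#' `drugged` when the protein (or any of its interactors) has been targeted
#' at any human trial phase; otherwise `druggable` when listed in the
#' druggable set; otherwise `neither`. Unknown proteins return `neither`
#' with a warning.
#'
#' @param protein Protein identifier.
#' @param annotations An `annotation_bundle`.
#' @return `"drugged"`, `"druggable"` or `"neither"`.
#' @export
druggability_classify <- function(protein, annotations) {
  known <- annotations$druggability$protein
  if (!protein %in% known) {
    warning("unknown protein: ", protein)
    return("neither")
  }
  if (nrow(linked_trials(protein, annotations))) return("drugged")
  cls <- annotations$druggability$class[known == protein][1]
  if (cls == "drugged") "drugged" else if (cls == "druggable") "druggable"
    else "neither"
}
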