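# Cis-instrument selection: window/MAF/F filters, allele harmonization,
# reference-panel LD, and greedy LD clumping.

#' Define a gene locus
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome label.
#' @param start,end 1-based inclusive gene-body coordinates.
#' @return A `gene_locus` list.
#' @export
gene_locus <- function(gene_id, chrom, start, end) {
  if (start > end) stop("locus start must be <= end")
  structure(list(gene_id = as.character(gene_id), chrom = as.character(chrom),
                 start = as.numeric(start), end = as.numeric(end)),
            class = "gene_locus")
}

add_audit <- function(audit, ids, stage, reason) {
  if (!length(ids)) return(audit)
  rbind(audit, data.frame(variant_id = ids, stage = stage, reason = reason,
                          stringsAsFactors = FALSE))
}

empty_audit <- function() {
  data.frame(variant_id = character(), stage = character(),
             reason = character(), stringsAsFactors = FALSE)
}

#' Select cis variants around a gene locus
#'
#' Keeps variants inside the closed window `[start - window_bp, end +
#' window_bp]` with minor allele frequency `min(eaf, 1 - eaf) >= maf_min` and
#' single-variant F statistic `(beta/se)^2 >= f_min`. The window flanks the
#' gene body on both sides.
#'
#' @param records Summary-statistic data frame.
#' @param locus A [gene_locus()] on the records' chromosome.
#' @param window_bp Flank size in base pairs (default 200000).
#' @param maf_min Minimum minor allele frequency (default 0.01).
#' @param f_min Minimum instrument F statistic (default 15).
#' @return Retained records, with dropped variants in the `audit` attribute
#'   (`outside_window`, `low_maf`, `weak_instrument`, `wrong_chromosome`).
#' @export
select_cis_variants <- function(records, locus, window_bp = 200000,
                                maf_min = 0.01, f_min = 15) {
  audit <- empty_audit()
  lo <- locus$start - window_bp
  hi <- locus$end + window_bp

  off_chrom <- records$chrom != locus$chrom
  audit <- add_audit(audit, records$variant_id[off_chrom], "cis_selection",
                     "wrong_chromosome")
  records <- records[!off_chrom, , drop = FALSE]

  outside <- records$pos < lo | records$pos > hi
  audit <- add_audit(audit, records$variant_id[outside], "cis_selection",
                     "outside_window")
  records <- records[!outside, , drop = FALSE]

  maf <- pmin(records$eaf, 1 - records$eaf)
  low <- maf < maf_min
  audit <- add_audit(audit, records$variant_id[low], "cis_selection", "low_maf")
  records <- records[!low, , drop = FALSE]

  f_stat <- (records$beta / records$se)^2
  weak <- f_stat < f_min
  audit <- add_audit(audit, records$variant_id[weak], "cis_selection",
                     "weak_instrument")
  records <- records[!weak, , drop = FALSE]

  rownames(records) <- NULL
  attr(records, "audit") <- audit
  records
}

complement_allele <- function(a) {
  chartr("ACGT", "TGCA", a)
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "G" & a2 == "C") | (a1 == "C" & a2 == "G")
}

#' Harmonize exposure and outcome summary statistics
#'
#' Intersects variants by id and puts both studies on the exposure's
#' effect-allele orientation: outcome records with swapped effect/other
#' alleles have their beta negated and EAF complemented; strand flips are
#' resolved by complementing alleles first. Palindromic variants (A/T or G/C),
#' whose strand cannot be resolved, are excluded when their exposure MAF is
#' at or above `palindrome_maf` (ambiguous near 0.5). Irreconcilable allele
#' sets are dropped with reason `allele_mismatch`.
#'
#' @param exposure,outcome Summary-statistic data frames.
#' @param palindrome_maf Lower edge of the ambiguity band (default 0.42);
#'   palindromic variants with MAF in `[palindrome_maf, 0.5]` are removed.
#' @return A `harmonized_pair`: aligned `exposure`/`outcome` record frames,
#'   vectors `variants`, `beta_x`, `se_x`, `beta_y`, `se_y`, `n_x`, `n_y`,
#'   `ld` (`NULL` until [estimate_ld()]), and an `audit` data frame.
#' @export
harmonize <- function(exposure, outcome, palindrome_maf = 0.42) {
  audit <- empty_audit()
  shared <- intersect(exposure$variant_id, outcome$variant_id)
  audit <- add_audit(audit,
                     setdiff(c(exposure$variant_id, outcome$variant_id), shared),
                     "harmonize", "not_in_both_studies")
  ex <- exposure[match(shared, exposure$variant_id), , drop = FALSE]
  ou <- outcome[match(shared, outcome$variant_id), , drop = FALSE]

  keep <- rep(TRUE, length(shared))
  for (i in seq_along(shared)) {
    ea_x <- ex$effect_allele[i]; oa_x <- ex$other_allele[i]
    ea_y <- ou$effect_allele[i]; oa_y <- ou$other_allele[i]

    if (is_palindromic(ea_x, oa_x)) {
      maf <- min(ex$eaf[i], 1 - ex$eaf[i])
      if (maf >= palindrome_maf) {
        keep[i] <- FALSE
        audit <- add_audit(audit, shared[i], "harmonize", "palindromic_ambiguous")
        next
      }
    }
    aligned <- FALSE
    for (flip_strand in c(FALSE, TRUE)) {
      a1 <- if (flip_strand) complement_allele(ea_y) else ea_y
      a2 <- if (flip_strand) complement_allele(oa_y) else oa_y
      if (a1 == ea_x && a2 == oa_x) {
        aligned <- TRUE
        break
      }
      if (a1 == oa_x && a2 == ea_x) {
        ou$beta[i] <- -ou$beta[i]
        ou$eaf[i] <- 1 - ou$eaf[i]
        ou$effect_allele[i] <- ea_x
        ou$other_allele[i] <- oa_x
        aligned <- TRUE
        break
      }
    }
    if (aligned && ou$effect_allele[i] != ea_x) {
      # strand-complemented but same orientation: relabel to exposure strand
      ou$effect_allele[i] <- ea_x
      ou$other_allele[i] <- oa_x
    }
    if (!aligned) {
      keep[i] <- FALSE
      audit <- add_audit(audit, shared[i], "harmonize", "allele_mismatch")
    }
  }
  ex <- ex[keep, , drop = FALSE]
  ou <- ou[keep, , drop = FALSE]
  rownames(ex) <- rownames(ou) <- NULL
  structure(list(
    variants = ex$variant_id,
    exposure = ex, outcome = ou,
    beta_x = ex$beta, se_x = ex$se,
    beta_y = ou$beta, se_y = ou$se,
    n_x = ex$n, n_y = ou$n,
    ld = NULL, audit = audit
  ), class = "harmonized_pair")
}

#' Estimate an LD correlation matrix from a dosage panel
#'
#' Pearson correlation of dosages across reference individuals, diagonal
#' forced to exactly 1. Variants with (near-)zero dosage variance cannot be
#' placed in LD and raise an error.
#'
#' @param panel Dosage matrix with variant-id column names.
#' @param variants Variant ids to include, in output order.
#' @return Symmetric correlation matrix with `variants` as dimnames.
#' @export
estimate_ld <- function(panel, variants) {
  if (nrow(panel) < 2) stop("panel must contain at least 2 individuals")
  missing_v <- setdiff(variants, colnames(panel))
  if (length(missing_v)) {
    stop("variants absent from panel: ", paste(missing_v, collapse = ", "))
  }
  G <- panel[, variants, drop = FALSE]
  v <- apply(G, 2, stats::var)
  if (any(v < 1e-12)) {
    stop("zero_variance: monomorphic variant(s): ",
         paste(variants[v < 1e-12], collapse = ", "))
  }
  rho <- stats::cor(G)
  diag(rho) <- 1
  rho <- (rho + t(rho)) / 2
  dimnames(rho) <- list(variants, variants)
  rho
}

#' Greedy LD clumping of summary statistics
#'
#' Repeatedly keeps the most significant remaining variant and drops every
#' remaining variant with squared correlation above `r2_max` against it, so
#' the retained set is pairwise `r^2 <= r2_max`. Ties on p-value are broken
#' by position, then variant id, making the result invariant to input order.
#'
#' @param records Summary-statistic data frame.
#' @param ld LD correlation matrix covering the records (by variant id).
#' @param r2_max Maximum pairwise squared correlation (default 0.40).
#' @return Retained records with dropped variants audited as
#'   `clumped_r2_with:<index variant>`.
#' @export
ld_clump <- function(records, ld, r2_max = 0.40) {
  audit <- empty_audit()
  if (nrow(records) <= 1) {
    attr(records, "audit") <- audit
    return(records)
  }
  missing_v <- setdiff(records$variant_id, rownames(ld))
  if (length(missing_v)) {
    stop("LD matrix lacks variants: ", paste(missing_v, collapse = ", "))
  }
  ord <- order(records$pval, records$pos, records$variant_id)
  remaining <- records$variant_id[ord]
  kept <- character(0)
  while (length(remaining)) {
    lead <- remaining[1]
    kept <- c(kept, lead)
    remaining <- remaining[-1]
    if (!length(remaining)) break
    r2 <- ld[lead, remaining]^2
    drop <- remaining[r2 > r2_max]
    audit <- add_audit(audit, drop, "clump", paste0("clumped_r2_with:", lead))
    remaining <- setdiff(remaining, drop)
  }
  out <- records[records$variant_id %in% kept, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "audit") <- audit
  out
}

#' Subset a harmonized pair to a variant set
#'
#' Keeps the pair's vectors, record frames and LD matrix aligned.
#'
#' @param pair A `harmonized_pair`.
#' @param variants Variant ids to keep (order preserved from the pair).
#' @param reason Audit reason recorded for the dropped variants.
#' @param stage Audit stage label.
#' @return The reduced `harmonized_pair`.
#' @export
subset_pair <- function(pair, variants, reason = "subset", stage = "subset") {
  keep <- pair$variants %in% variants
  dropped <- pair$variants[!keep]
  pair$audit <- add_audit(pair$audit, dropped, stage, reason)
  pair$variants <- pair$variants[keep]
  pair$exposure <- pair$exposure[keep, , drop = FALSE]
  pair$outcome <- pair$outcome[keep, , drop = FALSE]
  for (f in c("beta_x", "se_x", "beta_y", "se_y", "n_x", "n_y")) {
    pair[[f]] <- pair[[f]][keep]
  }
  if (!is.null(pair$ld)) {
    pair$ld <- pair$ld[keep, keep, drop = FALSE]
  }
  rownames(pair$exposure) <- rownames(pair$outcome) <- NULL
  pair
}
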