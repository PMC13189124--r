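# LD-aware generalized-least-squares IVW and MR-Egger with Rucker model
# selection, Steiger and leverage/outlier filtering, and multiplicity control.
#
# Model: beta_y = theta * beta_x (IVW) or beta_y = a + theta * beta_x (Egger),
# with residual covariance Sigma = D_sey %*% rho %*% D_sey capturing both the
# outcome sampling error and the LD correlation between instruments.

#' Stage parameters for a protein-trait MR analysis
#'
#' One place for every threshold the pipeline uses. Defaults: 200-kbp cis
#' window, MAF >= 1%, F >= 15, palindrome ambiguity band starting at MAF
#' 0.42, clumping at r^2 0.40, at least 5 variants for a valid estimate,
#' leverage cut at 3x the mean leverage, outlier chi-square cut at 11, and
#' the Rucker Q-difference tested against chi-square(1) at 0.05.
#'
#' @param window_bp,maf_min,f_min,palindrome_maf,r2_max,min_variants
#'   Instrument-selection thresholds (see [select_cis_variants()],
#'   [harmonize()], [ld_clump()]).
#' @param leverage_mult,outlier_chisq Leverage/outlier cuts
#'   (see [leverage_outlier_filter()]).
#' @param rucker_alpha Significance level for the Rucker Q difference.
#' @param ridge Diagonal jitter added to Sigma before factorization.
#' @return A list of class `mr_config`.
#' @export
mr_config <- function(window_bp = 200000, maf_min = 0.01, f_min = 15,
                      palindrome_maf = 0.42, r2_max = 0.40, min_variants = 5,
                      leverage_mult = 3, outlier_chisq = 11,
                      rucker_alpha = 0.05, ridge = 1e-8) {
  structure(list(window_bp = window_bp, maf_min = maf_min, f_min = f_min,
                 palindrome_maf = palindrome_maf, r2_max = r2_max,
                 min_variants = min_variants, leverage_mult = leverage_mult,
                 outlier_chisq = outlier_chisq, rucker_alpha = rucker_alpha,
                 ridge = ridge),
            class = "mr_config")
}

#' Assemble an MR input from a harmonized pair
#'
#' @param pair A `harmonized_pair` with a non-`NULL` LD matrix.
#' @return An `mr_input` list with `variants`, `beta_x`, `se_x`, `beta_y`,
#'   `se_y`, `n_x`, `n_y`, `ld`, `audit`.
#' @export
mr_input <- function(pair) {
  if (is.null(pair$ld)) stop("pair has no LD matrix; call estimate_ld first")
  if (length(pair$variants) < 1) stop("mr_input requires at least 1 variant")
  stopifnot(nrow(pair$ld) == length(pair$variants))
  structure(pair, class = "mr_input")
}

sigma_matrix <- function(input, ridge = 1e-8) {
  S <- diag(input$se_y, length(input$se_y)) %*% input$ld %*%
    diag(input$se_y, length(input$se_y))
  S + diag(ridge, nrow(S))
}

#' Generalized-least-squares MR fit
#'
#' Regresses outcome effects on exposure effects with residual covariance
#' `Sigma = D_se_y %*% rho %*% D_se_y`. For the intercept model (MR-Egger)
#' every variant is first oriented to a non-negative exposure effect by
#' jointly flipping `beta_x`, `beta_y` and the corresponding rows/columns of
#' the LD matrix — required for intercept identifiability; the slope-only
#' model is orientation-invariant and is fitted as supplied.
#'
#' Standard errors carry a multiplicative overdispersion factor
#' `phi = max(1, Q / (p - k))`; p-values use the normal approximation.
#'
#' @param input An [mr_input()].
#' @param with_intercept `TRUE` for MR-Egger, `FALSE` for IVW.
#' @param ridge Diagonal jitter added to `Sigma` (default 1e-8).
#' @return A `gls_fit` list: `beta`, `se`, `pval` (slope), `intercept`,
#'   `intercept_se`, `intercept_pval` (`NA` for IVW), `Q`, `df`, `phi`,
#'   `n_variants`, `coef`, `cov`.
#' @export
gls_fit <- function(input, with_intercept = FALSE, ridge = 1e-8) {
  p <- length(input$beta_x)
  k <- if (with_intercept) 2L else 1L
  if (p < k) stop("need at least ", k, " variants for this model")
  x <- input$beta_x
  y <- input$beta_y
  ld <- input$ld
  if (with_intercept) {
    s <- ifelse(x < 0, -1, 1)
    x <- s * x
    y <- s * y
    ld <- ld * tcrossprod(s)
  }
  Sigma <- diag(input$se_y, p) %*% ld %*% diag(input$se_y, p) +
    diag(ridge, p)
  L <- tryCatch(t(chol(Sigma)), error = function(e) {
    stop("ld_singular: residual covariance is not positive definite")
  })
  X <- if (with_intercept) cbind(intercept = 1, slope = x) else
    cbind(slope = x)
  # whiten: solve(L, .) gives the decorrelated system
  Xw <- forwardsolve(L, X)
  yw <- forwardsolve(L, y)
  XtX <- crossprod(Xw)
  if (!is.finite(rcond(XtX)) || rcond(XtX) < 1e-12) {
    stop("ld_singular: design is rank deficient")
  }
  XtXinv <- tryCatch(chol2inv(chol(XtX)), error = function(e) {
    stop("ld_singular: design is rank deficient")
  })
  theta <- as.vector(XtXinv %*% crossprod(Xw, yw))
  resid_w <- yw - Xw %*% theta
  Q <- sum(resid_w^2)
  df <- p - k
  phi <- if (df > 0) max(1, Q / df) else 1
  covm <- XtXinv * phi
  se <- sqrt(diag(covm))
  pv <- 2 * stats::pnorm(-abs(theta / se))
  slope_i <- k
  structure(list(
    beta = unname(theta[slope_i]), se = unname(se[slope_i]),
    pval = unname(pv[slope_i]),
    intercept = if (with_intercept) unname(theta[1]) else NA_real_,
    intercept_se = if (with_intercept) unname(se[1]) else NA_real_,
    intercept_pval = if (with_intercept) unname(pv[1]) else NA_real_,
    Q = Q, df = df, phi = phi, n_variants = p,
    coef = stats::setNames(theta, colnames(X)),
    cov = covm, with_intercept = with_intercept
  ), class = "gls_fit")
}

#' Rucker model selection between IVW and MR-Egger
#'
#' Selects MR-Egger when its heterogeneity improvement `Q_ivw - Q_egger`
#' exceeds the chi-square(1) critical value at `alpha` (3.841 at 0.05);
#' otherwise IVW. The models are nested, so a negative difference beyond
#' numerical tolerance is an error.
#'
#' @param fit_ivw,fit_egger [gls_fit()] results on the same variant set.
#' @param alpha Significance level for the Q difference (default 0.05).
#' @return `"IVW"` or `"MR-Egger"`.
#' @export
rucker_select <- function(fit_ivw, fit_egger, alpha = 0.05) {
  if (fit_ivw$n_variants != fit_egger$n_variants) {
    stop("fits are not on the same variant set")
  }
  dq <- fit_ivw$Q - fit_egger$Q
  if (dq < -1e-8) {
    stop("Q_ivw < Q_egger violates model nesting (difference ", dq, ")")
  }
  if (max(dq, 0) > stats::qchisq(1 - alpha, df = 1)) "MR-Egger" else "IVW"
}

#' Steiger directionality filter
#'
#' Per variant, compares the variance explained in exposure and outcome,
#' `r2 = z^2 / (z^2 + n)` with `z = beta/se`, and removes variants explaining
#' strictly more outcome than exposure variance (reverse-causation guard);
#' ties are kept.
#'
#' @param input An [mr_input()] with sample sizes on both sides.
#' @return The reduced `mr_input`; removals audited with reason `steiger`.
#' @export
steiger_filter <- function(input) {
  if (any(!is.finite(input$n_x)) || any(!is.finite(input$n_y))) {
    stop("Steiger filtering requires sample sizes for both studies")
  }
  zx2 <- (input$beta_x / input$se_x)^2
  zy2 <- (input$beta_y / input$se_y)^2
  r2x <- zx2 / (zx2 + input$n_x)
  r2y <- zy2 / (zy2 + input$n_y)
  keep <- !(r2y > r2x)
  out <- subset_pair(input, input$variants[keep],
                     reason = "steiger", stage = "steiger")
  class(out) <- class(input)
  out
}

#' Iterative leverage/outlier exclusion
#'
#' Fits both models, applies Rucker selection, and inspects the selected fit:
#' leverage `h_i` (diagonal of the GLS hat matrix) against
#' `leverage_mult * mean(h)` and the squared decorrelated residual `e_i^2`
#' (with `e = L^-1 (y - X theta)`, `Sigma = L L'`) against `outlier_chisq`.
#' The single worst violator (largest relative exceedance) is removed and the
#' model refitted, until no violator remains or removal would take the
#' variant count below `min_variants` (then the violation is logged and
#' removal stops).
#'
#' @param input An [mr_input()].
#' @param config An [mr_config()].
#' @return The reduced `mr_input`; removals audited as `high_leverage` /
#'   `outlier`, and a floor-rule stop as `violation_kept_min_variants`.
#' @export
leverage_outlier_filter <- function(input, config = mr_config()) {
  repeat {
    p <- length(input$variants)
    fits <- fit_both_models(input, config)
    fit <- if (fits$method == "MR-Egger") fits$egger else fits$ivw
    diag_stats <- gls_diagnostics(input, fit, ridge = config$ridge)
    h <- diag_stats$leverage
    e2 <- diag_stats$outlier
    lev_cut <- config$leverage_mult * mean(h)
    viol <- h > lev_cut | e2 > config$outlier_chisq
    if (!any(viol)) break
    if (p - 1 < config$min_variants) {
      input$audit <- add_audit(input$audit,
                               input$variants[which(viol)],
                               "leverage_outlier",
                               "violation_kept_min_variants")
      break
    }
    score <- pmax(h / lev_cut, e2 / config$outlier_chisq)
    score[!viol] <- -Inf
    worst <- which.max(score)
    reason <- if (e2[worst] > config$outlier_chisq) "outlier" else "high_leverage"
    keep_ids <- input$variants[-worst]
    cls <- class(input)
    input <- subset_pair(input, keep_ids, reason = reason,
                         stage = "leverage_outlier")
    class(input) <- cls
  }
  input
}

# Leverage and decorrelated squared residuals for a GLS fit, replaying the
# fit's orientation convention.
gls_diagnostics <- function(input, fit, ridge = 1e-8) {
  p <- length(input$beta_x)
  x <- input$beta_x
  y <- input$beta_y
  ld <- input$ld
  if (fit$with_intercept) {
    s <- ifelse(x < 0, -1, 1)
    x <- s * x
    y <- s * y
    ld <- ld * tcrossprod(s)
  }
  Sigma <- diag(input$se_y, p) %*% ld %*% diag(input$se_y, p) + diag(ridge, p)
  L <- t(chol(Sigma))
  X <- if (fit$with_intercept) cbind(1, x) else cbind(x)
  Xw <- forwardsolve(L, X)
  yw <- forwardsolve(L, y)
  XtXinv <- chol2inv(chol(crossprod(Xw)))
  # hat matrix of the whitened system; trace equals k
  Hw <- Xw %*% XtXinv %*% t(Xw)
  resid_w <- as.vector(yw - Xw %*% fit$coef)
  list(leverage = diag(Hw), outlier = resid_w^2)
}

fit_both_models <- function(input, config = mr_config()) {
  fit_ivw <- gls_fit(input, with_intercept = FALSE, ridge = config$ridge)
  fit_egger <- NULL
  method <- "IVW"
  if (length(input$variants) >= 3) {
    # Egger is unidentifiable when oriented instrument strengths are all
    # equal (intercept collinear with slope); fall back to IVW then.
    fit_egger <- tryCatch(
      gls_fit(input, with_intercept = TRUE, ridge = config$ridge),
      error = function(e) NULL
    )
    if (!is.null(fit_egger)) {
      method <- rucker_select(fit_ivw, fit_egger, alpha = config$rucker_alpha)
    }
  }
  list(ivw = fit_ivw, egger = fit_egger, method = method)
}

#' Bonferroni multiplicity policy
#'
#' Family-wise threshold `alpha_family / (n_proteins * n_traits)`, with an
#' optional fixed override (e.g. a published constant).
#'
#' @param n_proteins,n_traits Test-grid dimensions (both >= 1).
#' @param alpha_family Family-wise error rate (default 0.05).
#' @param threshold Optional override; when given, it is used verbatim.
#' @return List with `n_tests` and `threshold`.
#' @export
#' @examples
#' bonferroni_threshold(151, 64)
bonferroni_threshold <- function(n_proteins, n_traits, alpha_family = 0.05,
                                 threshold = NULL) {
  if (n_proteins < 1 || n_traits < 1) stop("protein and trait counts must be >= 1")
  n_tests <- n_proteins * n_traits
  list(
    n_tests = n_tests,
    threshold = if (is.null(threshold)) alpha_family / n_tests else threshold
  )
}

#' End-to-end cis-MR for one protein-trait pair
#'
#' Pipeline order: cis selection, harmonization, reference-panel LD, LD
#' clumping, Steiger filtering, initial fits, iterative leverage/outlier
#' exclusion, Rucker model selection. Analyses retaining fewer than
#' `min_variants` instruments at the fitting stage are reported with status
#' `insufficient_variants` and no estimate.
#'
#' @param exposure,outcome Summary-statistic data frames.
#' @param locus The protein's [gene_locus()].
#' @param panel Reference dosage panel for LD.
#' @param config An [mr_config()].
#' @param protein,trait Labels carried into the result.
#' @return An `mr_estimate` list: `protein`, `trait`, `method`, `beta`, `se`,
#'   `pval`, `intercept`, `intercept_se`, `q_ivw`, `q_egger`,
#'   `n_variants_used`, `excluded` (audit data frame), `status`.
#' @export
run_protein_trait_mr <- function(exposure, outcome, locus, panel,
                                 config = mr_config(),
                                 protein = locus$gene_id, trait = "outcome") {
  prep <- prepare_mr_input(exposure, outcome, locus, panel, config)

  insufficient <- function(pair) {
    structure(list(
      protein = protein, trait = trait, method = NA_character_,
      beta = NA_real_, se = NA_real_, pval = NA_real_,
      intercept = NA_real_, intercept_se = NA_real_,
      q_ivw = NA_real_, q_egger = NA_real_,
      n_variants_used = length(pair$variants),
      excluded = pair$audit, status = "insufficient_variants"
    ), class = "mr_estimate")
  }
  if (prep$status != "ok") return(insufficient(prep$input))
  input <- prep$input

  fits <- fit_both_models(input, config)
  sel <- if (fits$method == "MR-Egger") fits$egger else fits$ivw
  structure(list(
    protein = protein, trait = trait, method = fits$method,
    beta = sel$beta, se = sel$se, pval = sel$pval,
    intercept = sel$intercept, intercept_se = sel$intercept_se,
    q_ivw = fits$ivw$Q,
    q_egger = if (is.null(fits$egger)) NA_real_ else fits$egger$Q,
    n_variants_used = length(input$variants),
    excluded = input$audit, status = "ok"
  ), class = "mr_estimate")
}

#' Instrument selection and filtering for one protein-trait pair
#'
#' The selection half of [run_protein_trait_mr()]: cis selection,
#' harmonization, LD estimation, clumping, Steiger filtering and the
#' iterative leverage/outlier exclusion, without the final fits. Useful for
#' calibration studies that need the filtered instrument set itself.
#'
#' @inheritParams run_protein_trait_mr
#' @return List with `input` (the filtered [mr_input()], or the partial pair
#'   when starved) and `status` (`"ok"` or `"insufficient_variants"`).
#' @export
prepare_mr_input <- function(exposure, outcome, locus, panel,
                             config = mr_config()) {
  cis <- select_cis_variants(exposure, locus, window_bp = config$window_bp,
                             maf_min = config$maf_min, f_min = config$f_min)
  audit <- attr(cis, "audit")

  # variants dropped at cis selection are already audited; keep harmonize's
  # not_in_both_studies reason for genuinely one-sided variants only
  outcome_cis <- outcome[!outcome$variant_id %in% audit$variant_id, ,
                         drop = FALSE]
  pair <- harmonize(cis, outcome_cis, palindrome_maf = config$palindrome_maf)
  pair$audit <- rbind(audit, pair$audit)
  starved <- function(pair) list(input = pair, status = "insufficient_variants")
  if (length(pair$variants) < 1) return(starved(pair))

  in_panel <- intersect(pair$variants, colnames(panel))
  pair <- subset_pair(pair, in_panel, reason = "not_in_reference_panel",
                      stage = "ld")
  if (length(pair$variants) < 1) return(starved(pair))
  pair$ld <- estimate_ld(panel, pair$variants)

  clumped <- ld_clump(pair$exposure, pair$ld, r2_max = config$r2_max)
  clump_audit <- attr(clumped, "audit")
  pair <- subset_pair(pair, clumped$variant_id, reason = "clumped",
                      stage = "clump")
  # keep per-lead clump reasons rather than the generic 'clumped'
  pair$audit <- rbind(
    pair$audit[pair$audit$stage != "clump", , drop = FALSE],
    clump_audit
  )

  input <- mr_input(pair)
  input <- steiger_filter(input)
  if (length(input$variants) < config$min_variants) return(starved(input))

  input <- leverage_outlier_filter(input, config)
  if (length(input$variants) < config$min_variants) return(starved(input))
  list(input = input, status = "ok")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat("cis-MR estimate:", x$protein, "->", x$trait, "\n")
  if (x$status != "ok") {
    cat("  status:", x$status, "(", x$n_variants_used, "variants )\n")
    return(invisible(x))
  }
  cat(sprintf("  method %s  beta %.4f  se %.4f  p %.3g  (%d variants)\n",
              x$method, x$beta, x$se, x$pval, x$n_variants_used))
  if (!is.na(x$intercept)) {
    cat(sprintf("  Egger intercept %.4f (se %.4f)\n", x$intercept,
                x$intercept_se))
  }
  cat(sprintf("  Q_ivw %.3f  Q_egger %s\n", x$q_ivw,
              ifelse(is.na(x$q_egger), "NA", sprintf("%.3f", x$q_egger))))
  invisible(x)
}

#' Collect MR estimates into a results table
#'
#' @param estimates List of `mr_estimate` objects.
#' @return Data frame, one row per estimate.
#' @export
mr_results_table <- function(estimates) {
  do.call(rbind, lapply(estimates, function(e) {
    data.frame(protein = e$protein, trait = e$trait, method = e$method,
               beta = e$beta, se = e$se, pval = e$pval,
               intercept = e$intercept, intercept_se = e$intercept_se,
               q_ivw = e$q_ivw, q_egger = e$q_egger,
               n_variants_used = e$n_variants_used, status = e$status,
               stringsAsFactors = FALSE)
  }))
}
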