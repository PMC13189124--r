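# GLS estimators, Rucker selection, Steiger and leverage/outlier filters,
# multiplicity arithmetic, end-to-end estimate statuses.

test_that("single-instrument GLS reduces to the Wald ratio exactly", {
  input <- make_input(beta_x = 0.1, se_x = 0.01, beta_y = 0.05, se_y = 0.01)
  fit <- gls_fit(input, with_intercept = FALSE, ridge = 0)
  expect_equal(fit$beta, 0.5, tolerance = 1e-12)
  expect_equal(fit$se, 0.1, tolerance = 1e-12)
  expect_equal(fit$Q, 0, tolerance = 1e-12)
})

test_that("noise-free proportional effects give the exact slope and Q = 0", {
  x <- c(0.1, 0.2, 0.3, 0.15)
  input <- make_input(beta_x = x, se_x = 0.01, beta_y = 2 * x, se_y = 0.02)
  fit <- gls_fit(input, with_intercept = FALSE, ridge = 0)
  expect_equal(fit$beta, 2, tolerance = 1e-10)
  expect_equal(fit$Q, 0, tolerance = 1e-10)
})

test_that("GLS with identity LD equals the classical IVW closed form", {
  set.seed(71)
  for (rep in 1:5) {
    p <- sample(3:8, 1)
    x <- runif(p, 0.05, 0.5) * sample(c(-1, 1), p, TRUE)
    se_y <- runif(p, 0.01, 0.05)
    y <- 0.4 * x + rnorm(p, 0, se_y)
    input <- make_input(beta_x = x, se_x = 0.01, beta_y = y, se_y = se_y)
    fit <- gls_fit(input, with_intercept = FALSE, ridge = 0)
    oracle <- classical_ivw(x, y, se_y)
    expect_equal(fit$beta, oracle$beta, tolerance = 1e-10)
    expect_equal(fit$se, oracle$se, tolerance = 1e-10)
    expect_equal(fit$Q, oracle$q, tolerance = 1e-10)
  }
})

test_that("correlated-LD fits match the direct normal-equations oracle", {
  x <- c(0.12, -0.25, 0.31, 0.18, 0.22)
  y <- c(0.05, -0.11, 0.14, 0.09, 0.08)
  se_y <- c(0.011, 0.014, 0.012, 0.016, 0.013)
  ld <- ar1_matrix(5, 0.3)
  input <- make_input(beta_x = x, se_x = 0.01, beta_y = y, se_y = se_y,
                      ld = ld)
  for (intercept in c(FALSE, TRUE)) {
    fit <- gls_fit(input, with_intercept = intercept)
    oracle <- gls_oracle(x, y, se_y, ld, intercept = intercept)
    expect_equal(fit$coef[["slope"]], oracle$theta[length(oracle$theta)],
                 tolerance = 1e-10)
    expect_equal(fit$Q, oracle$Q, tolerance = 1e-10)
    expect_equal(unname(fit$se), oracle$se[length(oracle$se)],
                 tolerance = 1e-10)
    if (intercept) {
      expect_equal(fit$intercept, oracle$theta[1], tolerance = 1e-10)
    }
  }
})

test_that("estimates are invariant under joint allele re-orientation", {
  x <- c(0.12, -0.25, 0.31, 0.18, 0.22)
  y <- c(0.05, -0.11, 0.14, 0.09, 0.08)
  se_y <- rep(0.012, 5)
  ld <- ar1_matrix(5, 0.4)
  s <- c(1, -1, 1, -1, 1)
  flipped <- ld * tcrossprod(s)
  a <- make_input(beta_x = x, se_x = 0.01, beta_y = y, se_y = se_y, ld = ld)
  b <- make_input(beta_x = s * x, se_x = 0.01, beta_y = s * y, se_y = se_y,
                  ld = flipped)
  for (intercept in c(FALSE, TRUE)) {
    fa <- gls_fit(a, with_intercept = intercept)
    fb <- gls_fit(b, with_intercept = intercept)
    expect_equal(fa$beta, fb$beta, tolerance = 1e-10)
    expect_equal(fa$se, fb$se, tolerance = 1e-10)
    expect_equal(fa$Q, fb$Q, tolerance = 1e-10)
  }
})

test_that("Q_ivw >= Q_egger on any shared variant set", {
  set.seed(73)
  for (rep in 1:10) {
    p <- sample(3:9, 1)
    x <- runif(p, 0.05, 0.5)
    se_y <- runif(p, 0.01, 0.05)
    y <- 0.3 * x + 0.02 + rnorm(p, 0, se_y)
    ld <- ar1_matrix(p, runif(1, 0, 0.6))
    input <- make_input(beta_x = x, se_x = 0.01, beta_y = y, se_y = se_y,
                        ld = ld)
    q_ivw <- gls_fit(input, FALSE)$Q
    q_egger <- gls_fit(input, TRUE)$Q
    expect_gte(q_ivw, q_egger - 1e-8)
  }
})

test_that("Rucker selection follows the chi-square(1) rule", {
  f <- function(q, p) list(Q = q, n_variants = p)
  expect_equal(rucker_select(f(5, 6), f(5, 6)), "IVW")
  expect_equal(rucker_select(f(20, 6), f(10, 6)), "MR-Egger")
  expect_equal(rucker_select(f(13.85, 6), f(10, 6)), "MR-Egger")
  expect_equal(rucker_select(f(13.0, 6), f(10, 6)), "IVW") # 3.0 < 3.841
  expect_error(rucker_select(f(5, 6), f(9, 6)), "nesting")
  expect_error(rucker_select(f(5, 6), f(5, 7)), "variant set")
})

test_that("Steiger filtering removes outcome-first variants and keeps ties", {
  # variant 1: strong on exposure; variant 2: mirrored; variant 3: exact tie
  input <- make_input(
    beta_x = c(10 * 0.02, 1 * 0.02, 0.05),
    se_x = 0.02,
    beta_y = c(1 * 0.02, 10 * 0.02, 0.05),
    se_y = 0.02,
    n_x = 1000, n_y = 1000
  )
  input$n_x <- c(1000, 10000, 1000)
  input$n_y <- c(10000, 1000, 1000)
  out <- steiger_filter(input)
  expect_setequal(out$variants, c("rs1", "rs3"))
  expect_equal(out$audit$reason[out$audit$variant_id == "rs2"], "steiger")
  r2 <- function(z, n) z^2 / (z^2 + n)
  expect_gt(r2(10, 1000), r2(1, 10000))
})

test_that("balanced designs trigger no leverage removals", {
  input <- make_input(beta_x = rep(0.2, 6), se_x = 0.01,
                      beta_y = rep(0.1, 6), se_y = 0.02)
  out <- leverage_outlier_filter(input)
  expect_equal(length(out$variants), 6)
  expect_equal(nrow(out$audit), 0)
})

test_that("a planted five-sigma outlier is removed, floor rule permitting", {
  x <- rep(1, 6)
  y <- 0.5 * x
  y[3] <- y[3] + 5 * 0.1
  input <- make_input(beta_x = x, se_x = 0.01, beta_y = y, se_y = 0.1)
  out <- leverage_outlier_filter(input)
  expect_false("rs3" %in% out$variants)
  expect_equal(out$audit$reason[out$audit$variant_id == "rs3"], "outlier")

  # with exactly 5 variants the floor rule logs but does not remove
  x5 <- rep(1, 5)
  y5 <- 0.5 * x5
  y5[2] <- y5[2] + 5 * 0.1
  input5 <- make_input(beta_x = x5, se_x = 0.01, beta_y = y5, se_y = 0.1)
  out5 <- leverage_outlier_filter(input5)
  expect_equal(length(out5$variants), 5)
  expect_true("violation_kept_min_variants" %in% out5$audit$reason)
})

test_that("multiplicity thresholds follow the Bonferroni product", {
  pol <- bonferroni_threshold(151, 64)
  expect_identical(pol$n_tests, 151 * 64)
  expect_equal(pol$n_tests, 9664)
  expect_equal(pol$threshold, 0.05 / 9664)
  expect_equal(bonferroni_threshold(1, 1)$threshold, 0.05)
  expect_equal(bonferroni_threshold(151, 64, threshold = 5.16e-6)$threshold,
               5.16e-6)
  expect_error(bonferroni_threshold(0, 5), ">= 1")
})

test_that("fewer than five surviving variants yields insufficient_variants", {
  cfg <- simulation_config(seed = 47, n_ref = 500, n_exposure = 3000,
                           n_outcome = 3000, n_variants = 4, ld_decay = 0,
                           causal_indices = 1:2, causal_betas = c(0.4, 0.3))
  panel <- simulate_reference_panel(cfg)
  st <- simulate_gwas_pair(cfg, panel)
  est <- run_protein_trait_mr(st$exposure_stats, st$outcome_stats,
                              pqtlmr:::default_locus(cfg), panel)
  expect_equal(est$status, "insufficient_variants")
  expect_true(is.na(est$beta))
})

test_that("the full pipeline recovers a strong planted effect", {
  cfg <- pqtlmr:::calibration_config(57, 1, alpha_true = 0.3,
                                     n_exposure = 5000, n_outcome = 5000,
                                     n_ref = 2000)
  panel <- simulate_reference_panel(cfg)
  st <- simulate_gwas_pair(cfg, panel)
  est <- run_protein_trait_mr(st$exposure_stats, st$outcome_stats,
                              pqtlmr:::default_locus(cfg), panel)
  expect_equal(est$status, "ok")
  expect_gte(est$n_variants_used, 5)
  expect_lt(abs(est$beta - 0.3), 3 * est$se)
})

test_that("Rucker increasingly prefers Egger as pleiotropy grows", {
  rates <- sapply(c(0, 0.04, 0.12), function(offset) {
    rucker_selection_rate(n_reps = 60, seed = 61,
                          pleiotropy_offset = offset)$egger_rate
  })
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[3], rates[1])
})
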