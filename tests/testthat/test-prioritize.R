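# Direction classification, concordance, pleiotropy, replication,
# positive controls and druggability.

make_bundle <- function() {
  simulate_annotations(5, paste0("P", 1:6), paste0("T", 1:6),
                       c("liver", "blood"), paste0("PW", 1:3),
                       n_disease = 3)
}

test_that("direction classification composes sign with trait labels", {
  ann <- make_bundle()
  # T1..T3 diseases, T4..T6 biomarkers
  expect_equal(classify_direction(0.5, "T1", ann), "harmful")
  expect_equal(classify_direction(-0.5, "T1", ann), "beneficial")
  bio <- ann$beneficial_direction[ann$beneficial_direction$type == "biomarker", ]
  up_harm <- bio$trait[bio$increase_is == "harmful"]
  up_good <- bio$trait[bio$increase_is == "beneficial"]
  if (length(up_harm)) {
    expect_equal(classify_direction(-0.2, up_harm[1], ann), "beneficial")
    expect_equal(classify_direction(0.2, up_harm[1], ann), "harmful")
  }
  if (length(up_good)) {
    expect_equal(classify_direction(0.2, up_good[1], ann), "beneficial")
  }
  expect_error(classify_direction(0, "T1", ann), "undirected")
  expect_error(classify_direction(0.1, "NOPE", ann), "annotation")
})

test_that("the 75% concordance rule is inclusive and floored", {
  h <- "harmful"; b <- "beneficial"
  expect_equal(concordance_profile(rep(h, 4))$classification,
               "harmful-consistent")
  expect_equal(concordance_profile(c(h, h, h, b))$classification,
               "harmful-consistent") # 3/4 = 75% exactly
  expect_equal(concordance_profile(c(h, h, b, b))$classification, "mixed")
  expect_equal(concordance_profile(c(h, h, h))$classification, "insufficient")
  expect_equal(concordance_profile(c(b, b, b, h))$classification,
               "beneficial-consistent")
  prof <- concordance_profile(c(h, b, b, b, b), protein = "P1")
  expect_equal(prof$n_harmful + prof$n_beneficial, prof$n_significant)
})

test_that("balanced direction profiles never pass the 75% rule", {
  for (n in c(4, 6, 8)) {
    dirs <- rep(c("harmful", "beneficial"), n / 2)
    expect_equal(concordance_profile(dirs)$classification, "mixed")
  }
})

test_that("flipping every effect sign swaps the consistency classes", {
  set.seed(29)
  dirs <- sample(c("harmful", "beneficial"), 40, replace = TRUE)
  flip <- ifelse(dirs == "harmful", "beneficial", "harmful")
  cls <- concordance_profile(dirs)$classification
  cls_f <- concordance_profile(flip)$classification
  swap <- c("harmful-consistent" = "beneficial-consistent",
            "beneficial-consistent" = "harmful-consistent",
            "mixed" = "mixed", "insufficient" = "insufficient")
  expect_equal(cls_f, unname(swap[cls]))
})

test_that("pleiotropy counts and quartiles match order-statistic oracles", {
  sig <- data.frame(
    protein = rep(paste0("P", 1:5), c(2, 4, 8, 13, 20)),
    trait = paste0("T", unlist(lapply(c(2, 4, 8, 13, 20), seq_len)))
  )
  ps <- pleiotropy_summary(sig)
  expect_equal(ps$summary$median, 8)
  one <- pleiotropy_summary(data.frame(protein = "P9", trait = "T1"))
  expect_equal(one$summary$median, 1)
  expect_equal(one$summary$q1, one$summary$q3)

  set.seed(37)
  counts <- sample(1:30, 12, replace = TRUE)
  sig2 <- data.frame(protein = rep(paste0("Q", 1:12), counts),
                     trait = paste0("T", unlist(lapply(counts, seq_len))))
  ps2 <- pleiotropy_summary(sig2)
  # oracle: type-7 linear interpolation computed by hand from sorted counts
  s <- sort(counts)
  interp <- function(p) {
    hidx <- (length(s) - 1) * p + 1
    lo <- floor(hidx); hi <- ceiling(hidx)
    s[lo] + (hidx - lo) * (s[hi] - s[lo])
  }
  expect_equal(ps2$summary$q1, interp(0.25))
  expect_equal(ps2$summary$median, interp(0.5))
  expect_equal(ps2$summary$q3, interp(0.75))
})

test_that("replication requires sign concordance and the right threshold", {
  disc <- data.frame(protein = c("P1", "P1", "P2", "P3"),
                     trait = c("T1", "T2", "T1", "T1"),
                     beta = c(0.5, -0.3, 0.2, 0.4),
                     pval = c(1e-8, 1e-7, 1e-9, 1e-8))
  repl <- data.frame(protein = c("P1", "P1", "P2"),
                     trait = c("T1", "T2", "T1"),
                     beta = c(0.4, -0.2, -0.3),
                     pval = c(0.04, 1e-6, 1e-10))
  res <- assess_replication(disc, repl, n_proteins_available = 73)
  expect_equal(res$summary$conservative_threshold, 0.05 / 73)
  expect_equal(res$summary$conservative_threshold, 6.85e-4, tolerance = 1e-3)
  rec <- res$records
  expect_true(rec$nominal_replicated[1])        # same sign, p = 0.04
  expect_false(rec$conservative_replicated[1])  # 0.04 > 6.85e-4
  expect_true(rec$conservative_replicated[2])
  expect_false(rec$nominal_replicated[3])       # opposite sign, tiny p
  expect_equal(res$unmatched$protein, "P3")
  # summary percentages recompute from their own counts
  expect_equal(res$summary$pct_nominal,
               round(100 * res$summary$n_nominal / res$summary$n_assessed))
})

test_that("positive-control verdicts follow mechanism concordance", {
  ann <- make_bundle()
  ann$trials <- data.frame(
    protein = c("P1", "P2", "P3", "P4"),
    trait = c("T1", "T1", "T2", "T2"),
    phase = c(3, 4, 3, 2),
    mechanism = c("inhibitor", "inhibitor", "agonist", "inhibitor"),
    stringsAsFactors = FALSE
  )
  ann$interactors <- data.frame(protein = character(),
                                interactor = character())
  est <- data.frame(protein = c("P1", "P2", "P3", "P4"),
                    trait = c("T1", "T1", "T2", "T2"),
                    beta = c(0.5, -0.5, -0.4, 0.3),
                    pval = c(1e-8, 1e-8, 0.01, 1e-8))
  res <- positive_control_concordance(est, ann, 1e-6)
  v <- res$verdicts
  expect_true(v$concordant[v$protein == "P1"])   # risk up + inhibitor
  expect_false(v$concordant[v$protein == "P2"])  # protective + inhibitor
  expect_true(v$concordant[v$protein == "P3"])   # protective + agonist
  expect_false("P4" %in% v$protein)              # phase 2 trial only
  expect_equal(v$tier[v$protein == "P1"], "multiplicity")
  expect_equal(v$tier[v$protein == "P3"], "nominal")
  expect_equal(res$summary$pct_concordant,
               round(100 * res$summary$n_concordant /
                       res$summary$n_identified))
})

test_that("interactor-linked trials are attributed to the protein", {
  ann <- make_bundle()
  ann$trials <- data.frame(protein = "P2", trait = "T1", phase = 3,
                           mechanism = "inhibitor", stringsAsFactors = FALSE)
  ann$interactors <- data.frame(protein = "P1", interactor = "P2",
                                stringsAsFactors = FALSE)
  est <- data.frame(protein = "P1", trait = "T1", beta = 0.4, pval = 1e-8)
  res <- positive_control_concordance(est, ann, 1e-6)
  expect_true("P1" %in% res$verdicts$protein)
  expect_true(res$verdicts$concordant[res$verdicts$protein == "P1"])
  expect_equal(druggability_classify("P1", ann), "drugged")
})

test_that("druggability classes rank drugged over druggable over neither", {
  ann <- make_bundle()
  ann$trials <- data.frame(protein = "P1", trait = "T1", phase = 1,
                           mechanism = "inhibitor", stringsAsFactors = FALSE)
  ann$interactors <- data.frame(protein = character(),
                                interactor = character())
  ann$druggability$class <- c("neither", "druggable", "neither",
                              "drugged", "druggable", "neither")
  expect_equal(druggability_classify("P1", ann), "drugged") # phase-1 trial
  expect_equal(druggability_classify("P2", ann), "druggable")
  expect_equal(druggability_classify("P3", ann), "neither")
  expect_warning(cls <- druggability_classify("XX", ann), "unknown")
  expect_equal(cls, "neither")
})

test_that("printed percentage convention is nearest-integer", {
  expect_equal(percent_of(411, 567), 72L)
  expect_equal(percent_of(326, 567), 57L)
  expect_equal(percent_of(33, 55), 60L)
  expect_equal(percent_of(22, 33), 67L)
  expect_error(percent_of(1, 0), "positive")
})
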