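# Knowledge graph: co-occurrence scores, overexpression, construction,
# Louvain communities and pathway enrichment.

test_that("tissue-trait score is an exact hypergeometric tail on -log10", {
  expect_equal(tissue_trait_score(0, 100, 100, 10000), 0)
  # under-enriched counts score zero
  expect_equal(tissue_trait_score(1, 100, 100, 10000), 0)
  s <- tissue_trait_score(50, 100, 100, 10000)
  # oracle: direct sum of hypergeometric point masses over the tail
  tail_p <- sum(dhyper(50:100, 100, 9900, 100))
  expect_equal(s, -log10(tail_p), tolerance = 1e-9)
  expect_gt(s, 8)
  expect_error(tissue_trait_score(60, 50, 100, 10000), "inconsistent")
})

test_that("tissue-trait edges require a score strictly above 8", {
  ann <- simulate_annotations(7, c("P1", "P2"), c("T1", "T2"),
                              c("liver", "blood"), c("PW1", "PW2"))
  est <- data.frame(protein = "P1", trait = "T1", beta = 1, pval = 1e-9,
                    status = "ok", stringsAsFactors = FALSE)
  scores <- data.frame(tissue = c("liver", "blood"), trait = c("T1", "T2"),
                       score = c(8.0, 8.1), stringsAsFactors = FALSE)
  g <- build_graph(est, ann, 1e-6, tissue_trait_scores = scores)
  el <- igraph::as_data_frame(g)
  tt <- el[el$type == "tissue_trait", ]
  expect_equal(nrow(tt), 1)
  expect_setequal(unlist(tt[, c("from", "to")]), c("blood", "T2"))
})

test_that("overexpression thresholding matches brute-force row statistics", {
  expr <- matrix(5, 3, 5, dimnames = list(paste0("P", 1:3),
                                          paste0("Ti", 1:5)))
  expect_equal(nrow(overexpression_edges(expr)), 0) # uniform, zero SD
  expr[2, 3] <- 50 # z = (50 - 14)/20.1 = 1.79 > 1.645
  oe <- overexpression_edges(expr)
  expect_equal(oe$protein, "P2")
  expect_equal(oe$tissue, "Ti3")

  set.seed(41)
  expr2 <- matrix(rlnorm(40, 2, 0.5), 5, 8,
                  dimnames = list(paste0("P", 1:5), paste0("Ti", 1:8)))
  oe2 <- overexpression_edges(expr2)
  manual <- NULL
  for (i in 1:5) for (j in 1:8) {
    z <- (expr2[i, j] - mean(expr2[i, ])) / sd(expr2[i, ])
    if (z > qnorm(0.95)) manual <- rbind(manual, c(i, j))
  }
  expect_equal(nrow(oe2), if (is.null(manual)) 0 else nrow(manual))
  expect_error(overexpression_edges(-expr), "non-negative")
})

test_that("graph construction matches hand enumeration on a fixture", {
  prots <- c("P1", "P2", "P3")
  traits <- c("T1", "T2")
  tissues <- paste0("Ti", 1:5)
  ann <- simulate_annotations(11, prots, traits, tissues, c("PW1", "PW2"),
                              n_disease = 1)
  # deterministic annotation content for exact enumeration
  ann$trials <- data.frame(protein = "P2", trait = "T1", phase = 3,
                           mechanism = "inhibitor", stringsAsFactors = FALSE)
  expr <- matrix(1, 3, 5, dimnames = list(prots, tissues))
  expr["P3", "Ti5"] <- 9 # z = (9 - 2.6)/3.58 = 1.79 > 1.645; other rows flat
  ann$tissue_expression <- expr
  thr <- 1e-6
  est <- data.frame(
    protein = c("P1", "P2", "P3"), trait = c("T1", "T2", "T1"),
    beta = c(0.5, -0.3, 0.2), pval = c(1e-8, thr, 0.2),
    status = c("ok", "ok", "ok"), stringsAsFactors = FALSE
  )
  scores <- data.frame(tissue = "Ti1", trait = "T2", score = 9)
  g <- build_graph(est, ann, thr, tissue_trait_scores = scores)
  expect_equal(igraph::vcount(g), 10) # 3 proteins + 2 traits + 5 tissues
  el <- igraph::as_data_frame(g)
  # P1-T1 is the only MR edge: P2's p equals the threshold (strict),
  # P3 is not significant
  mr <- el[el$type == "mr_association", ]
  expect_equal(nrow(mr), 1)
  expect_setequal(unlist(mr[, c("from", "to")]), c("P1", "T1"))
  expect_equal(nrow(el[el$type == "trial", ]), 1)
  expect_equal(nrow(el[el$type == "tissue_trait", ]), 1)
  oe <- el[el$type == "overexpression", ]
  expect_equal(nrow(oe), 1)
  expect_setequal(unlist(oe[, c("from", "to")]), c("P3", "Ti5"))

  ann_bad <- ann
  ann_bad$trials$trait <- "UNKNOWN_TRAIT"
  expect_error(build_graph(est, ann_bad, thr, tissue_trait_scores = scores),
               "dangling")
})

test_that("no significant estimates means no MR edges", {
  ann <- simulate_annotations(13, c("P1", "P2"), c("T1", "T2"),
                              c("liver"), c("PW1"))
  est <- data.frame(protein = "P1", trait = "T1", beta = 1, pval = 0.5,
                    status = "ok", stringsAsFactors = FALSE)
  g <- build_graph(est, ann, 1e-6,
                   tissue_trait_scores = data.frame(tissue = character(),
                                                    trait = character(),
                                                    score = numeric()))
  el <- igraph::as_data_frame(g)
  expect_equal(sum(el$type == "mr_association"), 0)
})

test_that("Louvain separates two bridged cliques", {
  make_clique_pair <- function() {
    edges <- NULL
    for (blk in list(1:4, 5:8)) edges <- rbind(edges, t(combn(blk, 2)))
    edges <- rbind(edges, c(1, 5))
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    igraph::V(g)$name <- paste0("n", 1:8)
    g
  }
  g <- make_clique_pair()
  part <- louvain_communities(g, seed = 3)
  memb <- part$membership[paste0("n", 1:8)]
  expect_equal(length(unique(memb)), 2)
  expect_equal(length(unique(memb[1:4])), 1)
  expect_equal(length(unique(memb[5:8])), 1)
  # brute force over all 4140 partitions of the 8 nodes
  expect_gte(part$modularity, brute_force_modularity(g) - 1e-9)
})

test_that("a 7-node fixture reaches the brute-force modularity optimum", {
  edges <- rbind(c(1, 2), c(2, 3), c(1, 3), c(3, 4), c(4, 5), c(5, 6),
                 c(4, 6), c(6, 7))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::V(g)$name <- paste0("v", 1:7)
  part <- louvain_communities(g, seed = 5)
  expect_gte(part$modularity, brute_force_modularity(g) - 1e-9)
})

test_that("reported modularity equals an independent recomputation", {
  set.seed(47)
  g <- igraph::sample_gnp(15, 0.3)
  igraph::V(g)$name <- paste0("n", 1:15)
  part <- louvain_communities(g, seed = 7)
  expect_equal(part$modularity, modularity_value(g, part$membership),
               tolerance = 1e-12)
  singletons <- setNames(seq_len(15), igraph::V(g)$name)
  expect_gte(part$modularity, modularity_value(g, singletons))
})

test_that("community labels are invariant to node permutation", {
  edges <- rbind(t(combn(1:4, 2)), t(combn(5:8, 2)), c(1, 5))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::V(g)$name <- paste0("n", 1:8)
  perm <- igraph::permute(g, c(3, 1, 4, 2, 7, 5, 8, 6))
  p1 <- louvain_communities(g, seed = 11)$membership
  p2 <- louvain_communities(perm, seed = 11)$membership
  # same grouping of the same named nodes, up to label renaming
  key1 <- split(names(p1), p1)
  key2 <- split(names(p2), p2)
  norm <- function(k) sort(vapply(k, function(v) paste(sort(v),
                                                       collapse = ","), ""))
  expect_equal(unname(norm(key1)), unname(norm(key2)))
  expect_error(louvain_communities(igraph::make_empty_graph(3)), "no_edges")
})

test_that("planted two-block graphs are recovered across seeded runs", {
  res <- block_recovery_rate(n_runs = 40, seed = 19)
  expect_gte(res$recovery_rate, 0.95)
})

test_that("enrichment Wald statistics match hand computation", {
  memb <- setNames(c(1, 1, 1, 1, 1, 2, 2, 2, 2, 2), paste0("P", 1:10))
  # community 1: 5 proteins, 3 in PW1; outside: 5 proteins, 1 in PW1
  pw <- data.frame(protein = c("P1", "P2", "P3", "P6"),
                   pathway = "PW1", stringsAsFactors = FALSE)
  res <- pathway_enrichment(memb, pw, paste0("P", 1:10))
  row <- res[res$community == 1 & res$pathway == "PW1", ]
  p_in <- 3 / 5; p_out <- 1 / 5
  z_manual <- (p_in - p_out) /
    sqrt(p_in * (1 - p_in) / 5 + p_out * (1 - p_out) / 5)
  expect_equal(row$z, z_manual, tolerance = 1e-12)
  expect_equal(row$pval, 2 * pnorm(-abs(z_manual)), tolerance = 1e-12)
  # anti-symmetry: community 2's z for PW1 is the negation
  row2 <- res[res$community == 2 & res$pathway == "PW1", ]
  expect_equal(row2$z, -z_manual, tolerance = 1e-12)
})

test_that("spec'd example a=3 n_in=5 b=10 n_out=100 matches the formula", {
  memb <- setNames(rep(c(1, 2), c(5, 100)), paste0("P", 1:105))
  in_pw <- c(paste0("P", 1:3), paste0("P", 6:15))
  pw <- data.frame(protein = in_pw, pathway = "PW1", stringsAsFactors = FALSE)
  res <- pathway_enrichment(memb, pw, paste0("P", 1:105))
  row <- res[res$community == 1 & res$pathway == "PW1", ]
  expect_equal(row$a, 3); expect_equal(row$b, 10)
  z_manual <- (0.6 - 0.1) / sqrt(0.6 * 0.4 / 5 + 0.1 * 0.9 / 100)
  expect_equal(row$z, z_manual, tolerance = 1e-12)
})

test_that("selection requires two community proteins and skips broad sets", {
  memb <- setNames(c(1, 1, 1, 2, 2, 2), paste0("P", 1:6))
  pw <- data.frame(
    protein = c("P1", "P1", "P2", "P3", "P4"),
    pathway = c("PW_small", "PW_big", "PW_big", "PW_big", "PW_other"),
    stringsAsFactors = FALSE
  )
  res <- pathway_enrichment(memb, pw, paste0("P", 1:6))
  small <- res[res$community == 1 & res$pathway == "PW_small", ]
  expect_false(small$eligible) # only one community protein in it
  # equal in/out proportions are never selected
  memb2 <- setNames(c(1, 1, 2, 2), paste0("P", 1:4))
  pw2 <- data.frame(protein = c("P1", "P3"), pathway = "PWx")
  res2 <- pathway_enrichment(memb2, pw2, paste0("P", 1:4))
  expect_equal(res2$z[1], 0)
  expect_false(any(res2$selected))
  # denylisted top pathway falls through to the second-ranked
  memb3 <- setNames(c(1, 1, 1, 2, 2, 2), paste0("P", 1:6))
  pw3 <- data.frame(
    protein = c("P1", "P2", "P3", "P1", "P2"),
    pathway = c("broad", "broad", "broad", "specific", "specific"),
    stringsAsFactors = FALSE
  )
  res3 <- pathway_enrichment(memb3, pw3, paste0("P", 1:6),
                             broad_denylist = "broad")
  expect_false(res3$selected[res3$community == 1 & res3$pathway == "broad"])
  expect_true(res3$selected[res3$community == 1 & res3$pathway == "specific"])
})
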