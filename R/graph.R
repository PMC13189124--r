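# Knowledge graph: typed protein/trait/tissue nodes, MR/trial/overexpression/
# tissue-trait edges, Louvain communities, proportion-difference pathway
# enrichment, and file export.

#' Tissue-trait literature co-occurrence score
#'
#' Operationalizes the literature co-occurrence score as the negative log10
#' one-sided hypergeometric tail probability of observing at least `n_both`
#' abstracts mentioning both keywords, given `n_tissue` and `n_trait`
#' mentions among `n_total` abstracts. When the observed co-occurrence does
#' not exceed its expectation the score is 0, so the score is always >= 0.
#' Downstream, tissue-trait edges are created for scores strictly above 8.
#'
#' @param n_both Co-occurrence count.
#' @param n_tissue,n_trait Marginal keyword counts.
#' @param n_total Total number of abstracts.
#' @return Non-negative score (vectorized over the inputs).
#' @export
#' @examples
#' tissue_trait_score(50, 100, 100, 10000)
tissue_trait_score <- function(n_both, n_tissue, n_trait, n_total) {
  ok <- n_both <= pmin(n_tissue, n_trait) & pmax(n_tissue, n_trait) <= n_total &
    n_both >= 0 & n_tissue >= 0 & n_trait >= 0
  if (any(!ok)) stop("inconsistent counts: need n_both <= min(n_tissue, n_trait) <= n_total")
  expected <- as.numeric(n_tissue) * as.numeric(n_trait) / n_total
  log_tail <- stats::phyper(n_both - 1, n_tissue, n_total - n_tissue, n_trait,
                            lower.tail = FALSE, log.p = TRUE)
  score <- -log_tail / log(10)
  ifelse(n_both <= expected, 0, score)
}

#' Protein-tissue overexpression edges
#'
#' Flags, per protein, the tissues whose expression exceeds the protein's
#' cross-tissue mean by more than `z_crit` standard deviations (one-sided;
#' default 1.645, i.e. 0.05). Proteins with zero cross-tissue SD yield no
#' edges.
#'
#' @param expression Non-negative matrix, proteins in rows, tissues in
#'   columns, with dimnames.
#' @param z_crit One-sided critical value (default `qnorm(0.95)`).
#' @return Data frame `protein`, `tissue`, `expression`, `z`.
#' @export
overexpression_edges <- function(expression, z_crit = stats::qnorm(0.95)) {
  if (any(expression < 0)) stop("expression values must be non-negative")
  if (is.null(rownames(expression)) || is.null(colnames(expression))) {
    stop("expression matrix needs protein and tissue dimnames")
  }
  out <- NULL
  for (i in seq_len(nrow(expression))) {
    x <- expression[i, ]
    s <- stats::sd(x)
    if (!is.finite(s) || s <= 0) next
    z <- (x - mean(x)) / s
    hit <- z > z_crit
    if (any(hit)) {
      out <- rbind(out, data.frame(
        protein = rownames(expression)[i],
        tissue = colnames(expression)[hit],
        expression = unname(x[hit]), z = unname(z[hit]),
        stringsAsFactors = FALSE
      ))
    }
  }
  if (is.null(out)) {
    out <- data.frame(protein = character(), tissue = character(),
                      expression = numeric(), z = numeric(),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Build the protein/trait/tissue knowledge graph
#'
#' Nodes are typed proteins, traits and tissues. Edges: `mr_association`
#' for estimates with p strictly below the multiplicity threshold (signed,
#' optionally flagged with colocalization support), `trial` from trial
#' records (drug target to indicated trait, including interactor-linked
#' trials), `tissue_trait` for co-occurrence scores strictly above
#' `tissue_trait_cut`, and `overexpression` from the expression matrix.
#'
#' @param estimates MR results data frame (`protein`, `trait`, `beta`,
#'   `pval`, `status`).
#' @param annotations An `annotation_bundle`.
#' @param multiplicity_threshold Significance threshold for MR edges.
#' @param coloc Optional colocalization table (`protein`, `trait`,
#'   `colocalized`); matched pairs annotate MR edges.
#' @param tissue_trait_scores Optional precomputed data frame `tissue`,
#'   `trait`, `score`; when `NULL`, scores are computed from
#'   `annotations$tissue_trait_counts` via [tissue_trait_score()].
#' @param tissue_trait_cut Score threshold, strict (default 8).
#' @param z_crit Overexpression cut (default `qnorm(0.95)`).
#' @return An undirected `igraph` with vertex attributes `name`, `type` and
#'   edge attributes `type`, `sign`, `colocalized`, `provenance`.
#' @export
build_graph <- function(estimates, annotations, multiplicity_threshold,
                        coloc = NULL, tissue_trait_scores = NULL,
                        tissue_trait_cut = 8, z_crit = stats::qnorm(0.95)) {
  proteins <- unique(c(estimates$protein, annotations$druggability$protein))
  traits <- unique(c(estimates$trait,
                     annotations$beneficial_direction$trait))
  tissues <- unique(colnames(annotations$tissue_expression))

  dangling <- character(0)
  tr <- annotations$trials
  bad_tr <- !(tr$protein %in% proteins) | !(tr$trait %in% traits)
  if (any(bad_tr)) {
    dangling <- c(dangling, paste0("trial:", tr$protein[bad_tr], "->",
                                   tr$trait[bad_tr]))
  }
  if (length(dangling)) {
    stop("dangling references: ", paste(dangling, collapse = ", "))
  }

  edges <- data.frame(from = character(), to = character(), type = character(),
                      sign = numeric(), colocalized = logical(),
                      provenance = character(), stringsAsFactors = FALSE)
  ok <- estimates$status == "ok" & is.finite(estimates$pval) &
    estimates$pval < multiplicity_threshold
  sig <- estimates[ok, , drop = FALSE]
  if (nrow(sig)) {
    cflag <- rep(FALSE, nrow(sig))
    if (!is.null(coloc) && nrow(coloc)) {
      key <- function(p, t) paste(p, t, sep = "\r")
      idx <- match(key(sig$protein, sig$trait), key(coloc$protein, coloc$trait))
      cflag <- !is.na(idx) & coloc$colocalized[idx] %in% TRUE
    }
    edges <- rbind(edges, data.frame(
      from = sig$protein, to = sig$trait, type = "mr_association",
      sign = sign(sig$beta), colocalized = cflag, provenance = "mr",
      stringsAsFactors = FALSE
    ))
  }
  if (nrow(tr)) {
    edges <- rbind(edges, data.frame(
      from = tr$protein, to = tr$trait, type = "trial", sign = NA_real_,
      colocalized = NA, provenance = "trials", stringsAsFactors = FALSE
    ))
  }
  if (is.null(tissue_trait_scores)) {
    cc <- annotations$tissue_trait_counts
    tissue_trait_scores <- data.frame(
      tissue = cc$tissue, trait = cc$trait,
      score = tissue_trait_score(cc$n_both, cc$n_tissue, cc$n_trait,
                                 cc$n_total),
      stringsAsFactors = FALSE
    )
  }
  tts <- tissue_trait_scores[tissue_trait_scores$score > tissue_trait_cut, ,
                             drop = FALSE]
  if (nrow(tts)) {
    edges <- rbind(edges, data.frame(
      from = tts$tissue, to = tts$trait, type = "tissue_trait",
      sign = NA_real_, colocalized = NA, provenance = "literature",
      stringsAsFactors = FALSE
    ))
  }
  oe <- overexpression_edges(annotations$tissue_expression, z_crit = z_crit)
  if (nrow(oe)) {
    edges <- rbind(edges, data.frame(
      from = oe$protein, to = oe$tissue, type = "overexpression",
      sign = NA_real_, colocalized = NA, provenance = "expression",
      stringsAsFactors = FALSE
    ))
  }
  edges <- edges[edges$from != edges$to, , drop = FALSE]

  nodes <- data.frame(
    name = c(proteins, traits, tissues),
    type = rep(c("protein", "trait", "tissue"),
               c(length(proteins), length(traits), length(tissues))),
    stringsAsFactors = FALSE
  )
  bad_ends <- setdiff(unique(c(edges$from, edges$to)), nodes$name)
  if (length(bad_ends)) {
    stop("dangling references: ", paste(bad_ends, collapse = ", "))
  }
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
}

#' Modularity of a partition, recomputed from first principles
#'
#' `Q = (1/2m) * sum_ij (A_ij - k_i k_j / 2m) * [c_i == c_j]` on the
#' simplified, unweighted graph.
#'
#' @param graph An igraph object.
#' @param membership Named (or vertex-ordered) community labels.
#' @return Modularity value.
#' @export
modularity_value <- function(graph, membership) {
  g <- igraph::simplify(graph, remove.multiple = TRUE, remove.loops = TRUE)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  if (!is.null(names(membership))) {
    membership <- membership[rownames(A)]
  }
  k <- rowSums(A)
  m2 <- sum(k)
  if (m2 == 0) return(NA_real_)
  same <- outer(membership, membership, "==")
  sum((A - outer(k, k) / m2) * same) / m2
}

#' Louvain community detection
#'
#' Runs the standard two-phase Louvain algorithm on the simplified,
#' unweighted, undirected graph (resolution 1). The result is deterministic
#' under a fixed seed; modularity is recomputed independently of the
#' clustering routine.
#'
#' @param graph An igraph object with at least one edge.
#' @param seed Integer seed.
#' @return A `community_partition` list: `membership` (named integer vector)
#'   and `modularity`.
#' @export
louvain_communities <- function(graph, seed = 1L) {
  g <- igraph::simplify(graph, remove.multiple = TRUE, remove.loops = TRUE)
  if (igraph::ecount(g) == 0) stop("no_edges: graph has no edges")
  cl <- with_seed(seed, igraph::cluster_louvain(g, weights = NA))
  memb <- stats::setNames(as.integer(igraph::membership(cl)),
                          igraph::V(g)$name)
  structure(list(membership = memb,
                 modularity = modularity_value(g, memb)),
            class = "community_partition")
}

#' Proportion-difference pathway enrichment per community
#'
#' For each community and pathway, compares the proportion of the
#' community's proteins in the pathway against the proportion among proteins
#' outside the community with a two-proportion Wald statistic
#' `z = (p_in - p_out) / sqrt(p_in(1-p_in)/n_in + p_out(1-p_out)/n_out)`
#' (two-sided normal p). When the variance term is exactly zero (both
#' proportions degenerate), 0.5 is added to all four cells. Pathways are
#' eligible when `p < p_threshold` and at least `min_in_pathway` community
#' proteins are members; ranking is by proportion difference. The top-ranked
#' eligible pathway is selected per community, unless it is flagged broad
#' (denylist or more members than `broad_max`), in which case the
#' second-ranked is selected if available.
#'
#' @param partition A `community_partition` (or named membership vector).
#' @param pathway_membership Data frame `protein`, `pathway`.
#' @param proteins Character vector of all protein nodes (defines in/out
#'   totals; community members outside it are ignored).
#' @param p_threshold Eligibility p-value cut (default 0.05).
#' @param min_in_pathway Minimum community proteins in the pathway (default 2).
#' @param broad_denylist Pathway ids considered too broad to be informative.
#' @param broad_max Pathway-size ceiling above which a pathway counts as
#'   broad (default 300).
#' @return Data frame with one row per (community, pathway):
#'   `community`, `pathway`, `a`, `n_in`, `b`, `n_out`, `prop_diff`, `z`,
#'   `pval`, `eligible`, `selected`; attribute `skipped` lists communities
#'   without protein members.
#' @export
pathway_enrichment <- function(partition, pathway_membership, proteins,
                               p_threshold = 0.05, min_in_pathway = 2,
                               broad_denylist = character(0),
                               broad_max = 300) {
  memb <- if (inherits(partition, "community_partition")) {
    partition$membership
  } else {
    partition
  }
  memb <- memb[names(memb) %in% proteins]
  res <- NULL
  skipped <- integer(0)
  pathways <- unique(pathway_membership$pathway)
  pathway_sets <- split(pathway_membership$protein, pathway_membership$pathway)
  for (com in sort(unique(memb))) {
    inside <- names(memb)[memb == com]
    outside <- setdiff(proteins, inside)
    n_in <- length(inside)
    n_out <- length(outside)
    if (n_in == 0) {
      skipped <- c(skipped, com)
      next
    }
    rows <- lapply(pathways, function(pw) {
      members <- pathway_sets[[pw]]
      a <- sum(inside %in% members)
      b <- sum(outside %in% members)
      p_in <- a / n_in
      p_out <- if (n_out > 0) b / n_out else 0
      v <- p_in * (1 - p_in) / n_in +
        (if (n_out > 0) p_out * (1 - p_out) / n_out else 0)
      if (v == 0) {
        a_c <- a + 0.5; b_c <- b + 0.5
        n_in_c <- n_in + 1; n_out_c <- n_out + 1
        p_in_c <- a_c / n_in_c; p_out_c <- b_c / n_out_c
        v <- p_in_c * (1 - p_in_c) / n_in_c + p_out_c * (1 - p_out_c) / n_out_c
        z <- (p_in_c - p_out_c) / sqrt(v)
      } else {
        z <- (p_in - p_out) / sqrt(v)
      }
      data.frame(community = com, pathway = pw, a = a, n_in = n_in, b = b,
                 n_out = n_out, prop_diff = p_in - p_out, z = z,
                 pval = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    tab$eligible <- tab$pval < p_threshold & tab$a >= min_in_pathway
    tab$selected <- FALSE
    elig <- which(tab$eligible)
    if (length(elig)) {
      ord <- elig[order(-tab$prop_diff[elig], tab$pathway[elig])]
      sizes <- vapply(tab$pathway[ord],
                      function(pw) length(unique(pathway_sets[[pw]])),
                      integer(1))
      broad <- tab$pathway[ord] %in% broad_denylist | sizes > broad_max
      pick <- if (!broad[1]) ord[1] else if (length(ord) > 1) ord[2] else NA
      if (!is.na(pick)) tab$selected[pick] <- TRUE
    }
    res <- rbind(res, tab)
  }
  if (is.null(res)) {
    res <- data.frame(community = integer(), pathway = character(),
                      a = integer(), n_in = integer(), b = integer(),
                      n_out = integer(), prop_diff = numeric(), z = numeric(),
                      pval = numeric(), eligible = logical(),
                      selected = logical(), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}

#' Export a knowledge graph to GraphML and node-link JSON
#'
#' @param graph An igraph knowledge graph.
#' @param graphml_path,json_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
export_graph <- function(graph, graphml_path = NULL, json_path = NULL) {
  written <- character(0)
  if (!is.null(graphml_path)) {
    igraph::write_graph(graph, graphml_path, format = "graphml")
    written <- c(written, graphml_path)
  }
  if (!is.null(json_path)) {
    nodes <- data.frame(id = igraph::V(graph)$name,
                        type = igraph::V(graph)$type,
                        stringsAsFactors = FALSE)
    el <- igraph::as_data_frame(graph, what = "edges")
    jsonlite::write_json(list(nodes = nodes, links = el), json_path,
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    written <- c(written, json_path)
  }
  invisible(written)
}
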