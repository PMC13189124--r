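# Fixture builders and independent oracles shared across the test files.

# Summary-statistic rows built field-by-field; defaults give a valid record.
make_records <- function(n = 3, variant_id = sprintf("rs%d", seq_len(n)),
                         chrom = "1", pos = seq_len(n) * 1000,
                         effect_allele = rep_len(c("A", "C", "G"), n),
                         other_allele = rep_len(c("G", "T", "A"), n),
                         eaf = rep(0.3, n), beta = rep(0.1, n),
                         se = rep(0.02, n), pval = NULL, n_col = rep(5000, n)) {
  if (is.null(pval)) pval <- 2 * pnorm(-abs(beta / se))
  data.frame(variant_id = variant_id, chrom = chrom, pos = pos,
             effect_allele = effect_allele, other_allele = other_allele,
             eaf = eaf, beta = beta, se = se, pval = pval, n = n_col,
             stringsAsFactors = FALSE)
}

# Hand-built mr_input with explicit LD, bypassing harmonization.
make_input <- function(beta_x, se_x, beta_y, se_y, ld = NULL,
                       n_x = 10000, n_y = 10000) {
  p <- length(beta_x)
  if (is.null(ld)) ld <- diag(p)
  ids <- sprintf("rs%d", seq_len(p))
  dimnames(ld) <- list(ids, ids)
  structure(list(
    variants = ids,
    exposure = make_records(p, beta = beta_x, se = se_x, n_col = rep(n_x, p)),
    outcome = make_records(p, beta = beta_y, se = se_y, n_col = rep(n_y, p)),
    beta_x = beta_x, se_x = rep_len(se_x, p),
    beta_y = beta_y, se_y = rep_len(se_y, p),
    n_x = rep(n_x, p), n_y = rep(n_y, p),
    ld = ld, audit = pqtlmr:::empty_audit()
  ), class = c("mr_input", "harmonized_pair"))
}

ar1_matrix <- function(p, rho) rho^abs(outer(seq_len(p), seq_len(p), "-"))

# Independent GLS oracle: direct normal-equations solve via explicit matrix
# inverse (solve), a different numerical path from the chol/forwardsolve
# implementation. Mirrors the documented 1e-8 diagonal regularization.
gls_oracle <- function(x, y, se_y, ld, intercept = FALSE, ridge = 1e-8) {
  p <- length(x)
  if (intercept) {
    s <- ifelse(x < 0, -1, 1)
    x <- s * x; y <- s * y; ld <- ld * tcrossprod(s)
  }
  Sigma <- diag(se_y, p) %*% ld %*% diag(se_y, p) + diag(ridge, p)
  Si <- solve(Sigma)
  X <- if (intercept) cbind(1, x) else cbind(x)
  A <- solve(t(X) %*% Si %*% X)
  theta <- A %*% t(X) %*% Si %*% y
  r <- y - X %*% theta
  Q <- as.numeric(t(r) %*% Si %*% r)
  k <- ncol(X)
  phi <- if (p > k) max(1, Q / (p - k)) else 1
  list(theta = as.vector(theta), se = unname(sqrt(diag(A) * phi)), Q = Q)
}

# Classical inverse-variance-weighted estimate (independent closed form).
classical_ivw <- function(beta_x, beta_y, se_y) {
  w <- beta_x^2 / se_y^2
  ratio <- beta_y / beta_x
  beta <- sum(w * ratio) / sum(w)
  se <- sqrt(1 / sum(w))
  q <- sum(w * (ratio - beta)^2)
  phi <- max(1, q / (length(beta_x) - 1))
  list(beta = beta, se = se * sqrt(phi), q = q)
}

# All set partitions of seq_len(n) (for brute-force modularity search).
set_partitions <- function(n) {
  if (n == 1) return(list(list(1L)))
  smaller <- set_partitions(n - 1)
  out <- list()
  for (p in smaller) {
    for (i in seq_along(p)) {
      q <- p
      q[[i]] <- c(q[[i]], n)
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(n))
  }
  out
}

partition_to_membership <- function(partition, n) {
  memb <- integer(n)
  for (i in seq_along(partition)) memb[partition[[i]]] <- i
  memb
}

# Brute-force maximum modularity over every partition of a small graph.
brute_force_modularity <- function(graph) {
  n <- igraph::vcount(graph)
  best <- -Inf
  for (p in set_partitions(n)) {
    memb <- stats::setNames(partition_to_membership(p, n),
                            igraph::V(graph)$name)
    q <- modularity_value(graph, memb)
    if (q > best) best <- q
  }
  best
}
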