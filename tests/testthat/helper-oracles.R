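# Independent brute-force oracles, written as literal step-by-step walks so
# they share no code with the package implementations they check.

# running-sum enrichment score: explicit loop over every ranked position
oracle_es <- function(scores, hit, w) {
  n <- length(scores)
  nh <- sum(hit)
  nr <- sum(abs(scores[hit])^w)
  rs <- numeric(n)
  cur <- 0
  for (i in seq_len(n)) {
    if (hit[i]) {
      cur <- cur + (if (nr > 0) abs(scores[i])^w / nr else 1 / nh)
    } else {
      cur <- cur - 1 / (n - nh)
    }
    rs[i] <- cur
  }
  # earliest extremum wins ties beyond 1e-12 (shared tie policy)
  best <- 0
  for (i in seq_len(n)) {
    if (abs(rs[i]) > abs(best) + 1e-12) best <- rs[i]
  }
  best
}

# ssGSEA score: explicit cumulative walk over the expression-sorted genes
oracle_ssgsea <- function(expr, members, alpha) {
  ord <- order(-expr, names(expr), method = "radix")
  ids <- names(expr)[ord]
  n <- length(expr)
  in_set <- ids %in% members
  rank_vals <- (n:1)^alpha
  denom_in <- sum(rank_vals[in_set])
  denom_out <- n - sum(in_set)
  p_in <- 0
  p_out <- 0
  total <- 0
  for (i in seq_len(n)) {
    if (in_set[i]) p_in <- p_in + rank_vals[i] / denom_in
    else p_out <- p_out + 1 / denom_out
    total <- total + (p_in - p_out)
  }
  total
}

# Pearson r straight from the covariance formula
oracle_pearson_r <- function(x, y) {
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) / (n - 1) /
    (stats::sd(x) * stats::sd(y))
}

# small cohort shared by several suites
small_cohort <- function(seed = 11, ...) {
  generate_cohort(cohort_config(n_samples = 100L, n_genes = 600L,
                                n_mirnas = 6L, n_immune_sets = 8L,
                                genes_per_set = 6L, seed = seed, ...))
}
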