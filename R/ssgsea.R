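#' Single-sample GSEA score for one sample and one gene set
#'
#' Genes are ranked by expression, descending (ties broken by gene ID). With
#' rank values `r_i = N - i + 1` along the walk, the score is
#' `sum_i [P_in(i) - P_out(i)]` where `P_in` is the cumulative sum of
#' `r^alpha` over in-set genes normalised to 1 and `P_out` is the cumulative
#' fraction of out-of-set genes. Because only ranks enter, the score is
#' invariant to any strictly monotone transform of the expression vector —
#' the defining property of ssGSEA.
#'
#' @param sample_expr Named numeric vector of gene expression for one
#'   sample.
#' @param members Character vector of set member gene IDs; at least 2 must
#'   be present in `sample_expr` and the set must not cover all genes.
#' @param alpha Rank weighting exponent (default 0.25, the canonical ssGSEA
#'   choice).
#' @return Scalar enrichment score.
#' @export
ssgsea_sample_score <- function(sample_expr, members, alpha = 0.25) {
  gene_ids <- names(sample_expr)
  if (is.null(gene_ids)) stop("sample_expr must be named by gene ID",
                              call. = FALSE)
  n <- length(sample_expr)
  hit_orig <- gene_ids %in% members
  nh <- sum(hit_orig)
  if (nh < 2L) {
    stop("degenerate gene set: fewer than 2 members present", call. = FALSE)
  }
  if (nh == n) {
    stop("degenerate gene set: covers all genes", call. = FALSE)
  }
  ord <- order(-sample_expr, gene_ids, method = "radix")
  hit <- hit_orig[ord]
  rank_w <- (n - seq_len(n) + 1)^alpha
  p_in <- cumsum(ifelse(hit, rank_w, 0)) / sum(rank_w[hit])
  p_out <- cumsum(!hit) / (n - nh)
  sum(p_in - p_out)
}

#' ssGSEA scores for a whole collection over a whole cohort
#'
#' One score per (signature, sample). Signatures with fewer than 2 members
#' in the gene universe (or covering it entirely) are dropped and reported
#' in the `dropped` attribute. With `normalize = TRUE` the whole matrix is
#' rescaled linearly by its global range into \[0, 1\], preserving
#' between-signature comparability.
#'
#' @param genes Gene [expression_matrix()].
#' @param collection A [gene_set_collection()] of signatures.
#' @param alpha Rank weighting exponent (default 0.25).
#' @param normalize Rescale the score matrix into \[0, 1\] (default FALSE).
#' @return Object of class `"signature_score_matrix"`: list with `scores`
#'   (signatures x samples matrix), `normalized`, and attribute `dropped`.
#' @export
score_matrix <- function(genes, collection, alpha = 0.25, normalize = FALSE) {
  stopifnot(inherits(collection, "gene_set_collection"))
  G <- unclass(genes)
  gene_ids <- rownames(G)
  n <- nrow(G)
  hit_masks <- lapply(collection, function(m) gene_ids %in% m)
  nh <- vapply(hit_masks, sum, integer(1L))
  ok <- nh >= 2L & nh < n
  dropped <- data.frame(set_id = names(collection)[!ok],
                        n_members_present = nh[!ok],
                        stringsAsFactors = FALSE)
  if (!any(ok)) stop("all signatures are degenerate on this gene universe",
                     call. = FALSE)
  hit_masks <- hit_masks[ok]
  nh <- nh[ok]

  rank_w <- (n - seq_len(n) + 1)^alpha
  scores <- matrix(NA_real_, nrow = sum(ok), ncol = ncol(G),
                   dimnames = list(names(hit_masks), colnames(G)))
  for (s in seq_len(ncol(G))) {
    ord <- order(-G[, s], gene_ids, method = "radix")
    for (j in seq_along(hit_masks)) {
      hit <- hit_masks[[j]][ord]
      w_hit <- rank_w * hit
      p_in <- cumsum(w_hit) / sum(w_hit)
      p_out <- cumsum(!hit) / (n - nh[j])
      scores[j, s] <- sum(p_in - p_out)
    }
  }
  if (normalize) {
    rng <- range(scores)
    if (diff(rng) > 0) scores <- (scores - rng[1L]) / diff(rng)
  }
  structure(list(scores = scores, normalized = normalize),
            dropped = dropped, class = "signature_score_matrix")
}

#' @export
print.signature_score_matrix <- function(x, ...) {
  cat(sprintf("signature_score_matrix: %d signature(s) x %d sample(s)%s\n",
              nrow(x$scores), ncol(x$scores),
              if (x$normalized) " (range-normalised to [0, 1])" else ""))
  invisible(x)
}
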