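#' Correlate miRNA expression with per-sample signature scores
#'
#' Spearman rank correlation of every miRNA against every immune-signature
#' ssGSEA score over the shared samples (ID intersection). Because Spearman
#' depends only on ranks, the result is identical whether the signature
#' scores were range-normalised or not.
#'
#' @param mirnas miRNA [expression_matrix()].
#' @param scores A `"signature_score_matrix"` from [score_matrix()].
#' @return Object of class `"signature_correlation_matrix"`: list with
#'   `rho` and `p` (miRNAs x signatures matrices) and `n_samples_used`.
#' @export
correlate_signatures <- function(mirnas, scores) {
  stopifnot(inherits(scores, "signature_score_matrix"))
  S <- scores$scores
  shared <- intersect(colnames(mirnas), colnames(S))
  if (length(shared) < 3L) {
    stop("need at least 3 shared samples, found ", length(shared),
         call. = FALSE)
  }
  M <- unclass(mirnas)[, shared, drop = FALSE]
  S <- S[, shared, drop = FALSE]
  n <- length(shared)
  rank_rows <- function(x) t(apply(x, 1L, rank, ties.method = "average"))
  rho <- stats::cor(t(rank_rows(M)), t(rank_rows(S)))
  rho[] <- pmax(-1, pmin(1, rho)) # clamp in place, keeping dim and names
  p <- matrix(vapply(rho, cor_t_pvalue, numeric(1L), n = n),
              nrow = nrow(rho), dimnames = dimnames(rho))
  structure(list(rho = rho, p = p, n_samples_used = n),
            class = "signature_correlation_matrix")
}

#' @export
print.signature_correlation_matrix <- function(x, ...) {
  cat(sprintf(
    "signature_correlation_matrix: %d miRNA(s) x %d signature(s), n = %d\n",
    nrow(x$rho), ncol(x$rho), x$n_samples_used))
  invisible(x)
}

#' Directionality summary of one miRNA's signature correlations
#'
#' The screen's readout for a candidate immune-regulator miRNA: how
#' consistently positive its correlations with the immune signatures are.
#'
#' @param scm A `"signature_correlation_matrix"`.
#' @param mirna_id miRNA identifier present in the matrix.
#' @param alpha Significance level for the positive-significant count
#'   (default 0.05).
#' @return List with `fraction_positive`, `mean_rho`,
#'   `n_significant_positive` and `n_signatures`.
#' @export
directionality_summary <- function(scm, mirna_id, alpha = 0.05) {
  stopifnot(inherits(scm, "signature_correlation_matrix"))
  if (!mirna_id %in% rownames(scm$rho)) {
    stop("unknown miRNA: ", mirna_id, call. = FALSE)
  }
  rho <- scm$rho[mirna_id, ]
  p <- scm$p[mirna_id, ]
  list(fraction_positive = mean(rho > 0),
       mean_rho = mean(rho),
       n_significant_positive = sum(rho > 0 & p < alpha),
       n_signatures = length(rho))
}
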