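#' Pearson correlation with t-based p-value
#'
#' Computes `r = cov(x, y) / (sd(x) * sd(y))` and a two-sided p-value from
#' the t-transformation `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2`
#' degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @return List with `r`, `p` and `n`.
#' @export
cor_pearson <- function(x, y) {
  check_cor_input(x, y)
  n <- length(x)
  r <- stats::cov(x, y) / (stats::sd(x) * stats::sd(y))
  r <- max(-1, min(1, r))
  list(r = r, p = cor_t_pvalue(r, n), n = n)
}

#' Spearman rank correlation with t-based p-value
#'
#' `rho` is the Pearson correlation of the average-ranked vectors (ties get
#' mid-ranks); the p-value uses the same t-transformation as
#' [cor_pearson()].
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant; ties
#'   allowed.
#' @return List with `rho`, `p` and `n`.
#' @export
cor_spearman <- function(x, y) {
  check_cor_input(x, y)
  res <- cor_pearson(rank(x, ties.method = "average"),
                     rank(y, ties.method = "average"))
  list(rho = res$r, p = res$p, n = res$n)
}

check_cor_input <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length",
                                   call. = FALSE)
  if (length(x) < 3L) stop("correlation requires at least 3 observations",
                           call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values in correlation input",
                                 call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  invisible(TRUE)
}

# two-sided p from the t transform; |r| = 1 gives p = 0
cor_t_pvalue <- function(r, n) {
  if (abs(r) >= 1) return(0)
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(t_stat), df = n - 2)
}

#' Rank all genes by signed correlation with one miRNA
#'
#' Aligns the miRNA and gene matrices on their shared samples (ID
#' intersection, not position), computes the Pearson correlation of every
#' gene with the chosen miRNA, and returns genes sorted by signed
#' correlation, descending, with ties broken by gene ID so the ordering is
#' fully deterministic. Genes with constant expression over the shared
#' samples have no defined correlation; they are excluded and reported in
#' the `dropped_constant` attribute rather than silently lost.
#'
#' @param mirna_id miRNA identifier present in `mirnas`.
#' @param mirnas miRNA [expression_matrix()].
#' @param genes Gene [expression_matrix()].
#' @return A `"ranked_gene_list"`: `data.frame(gene_id, score)` sorted by
#'   score descending, with attributes `mirna_id`, `n_samples_used` and
#'   `dropped_constant`.
#' @export
rank_genes_for_mirna <- function(mirna_id, mirnas, genes) {
  if (!mirna_id %in% rownames(mirnas)) {
    stop("unknown miRNA: ", mirna_id, call. = FALSE)
  }
  shared <- intersect(colnames(mirnas), colnames(genes))
  if (length(shared) < 3L) {
    stop("need at least 3 shared samples, found ", length(shared),
         call. = FALSE)
  }
  x <- as.numeric(mirnas[mirna_id, shared])
  if (stats::sd(x) == 0) {
    stop("miRNA '", mirna_id, "' is constant over shared samples",
         call. = FALSE)
  }
  G <- unclass(genes)[, shared, drop = FALSE]
  ss <- rowSums((G - rowMeans(G))^2)
  constant <- ss == 0
  G <- G[!constant, , drop = FALSE]
  # vectorised Pearson: centred cross-products over row-wise norms
  xc <- x - mean(x)
  r <- as.numeric(G %*% xc) / (sqrt(ss[!constant]) * sqrt(sum(xc^2)))
  r <- pmax(-1, pmin(1, r))
  ord <- order(-r, rownames(G), method = "radix")
  out <- data.frame(gene_id = rownames(G)[ord], score = r[ord],
                    stringsAsFactors = FALSE)
  structure(out, mirna_id = mirna_id, n_samples_used = length(shared),
            dropped_constant = rownames(genes)[constant],
            class = c("ranked_gene_list", "data.frame"))
}
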