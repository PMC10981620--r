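#' Parameters for pre-ranked GSEA
#'
#' Defaults reproduce the screen's enrichment settings: weighted running sum
#' (`weight_exponent = 1`), 500 gene-label permutations, and a minimum set
#' size of 3.
#'
#' @param weight_exponent Non-negative exponent applied to |score| in the
#'   running-sum hit increments; 0 gives the classic unweighted
#'   Kolmogorov-Smirnov statistic.
#' @param n_permutations Number of gene-label permutations for the null.
#' @param min_set_size Sets with fewer used members are excluded.
#' @param max_set_size Optional upper bound on used set size (`NULL` = none).
#' @param seed Integer RNG seed; permutation nulls are deterministic given
#'   the seed.
#' @return List of class `"gsea_params"`.
#' @export
gsea_params <- function(weight_exponent = 1, n_permutations = 500L,
                        min_set_size = 3L, max_set_size = NULL, seed = 1L) {
  if (weight_exponent < 0) stop("weight_exponent must be >= 0", call. = FALSE)
  if (n_permutations < 1L) stop("n_permutations must be >= 1", call. = FALSE)
  if (min_set_size < 1L) stop("min_set_size must be >= 1", call. = FALSE)
  structure(list(weight_exponent = as.numeric(weight_exponent),
                 n_permutations = as.integer(n_permutations),
                 min_set_size = as.integer(min_set_size),
                 max_set_size = if (!is.null(max_set_size))
                   as.integer(max_set_size),
                 seed = as.integer(seed)),
            class = "gsea_params")
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranked gene list from top to bottom. At a set member ("hit")
#' the running sum increases by `|score|^w / sum(|score|^w over hits)`; at a
#' non-member it decreases by `1 / (N - N_hits)`. The enrichment score is
#' the running-sum value of maximal absolute deviation from zero (signed;
#' the earliest position wins exact ties). The leading edge is the set
#' members at or before the extremum for positive scores, and at or after
#' it for negative scores.
#'
#' If every hit has |score| = 0 (possible only with `w > 0` and zero-score
#' hits), hit increments fall back to the unweighted `1 / N_hits` so the
#' score remains defined.
#'
#' @param ranked A `"ranked_gene_list"` from [rank_genes_for_mirna()] (or
#'   any `data.frame` with `gene_id` and `score` sorted by score
#'   descending).
#' @param members Character vector of set member gene IDs.
#' @param w Weight exponent (default 1).
#' @return List with `es`, the full `running_sum` vector, and
#'   `leading_edge`; `NULL` if the set does not intersect the ranked list
#'   (skip signal).
#' @export
enrichment_score <- function(ranked, members, w = 1) {
  genes <- ranked$gene_id
  n <- length(genes)
  hit <- genes %in% members
  nh <- sum(hit)
  if (nh == 0L) return(NULL)
  if (nh == n) {
    stop("degenerate gene set: covers the entire ranked list", call. = FALSE)
  }
  sw <- abs(ranked$score)^w
  nr <- sum(sw[hit])
  inc <- if (nr > 0) sw / nr else rep(1 / nh, n)
  steps <- ifelse(hit, inc, -1 / (n - nh))
  rs <- cumsum(steps)
  # earliest extremum within 1e-12 of the maximum, so exact |rs| ties
  # (possible with w = 0) are broken by position, not by rounding noise
  i_max <- which(abs(rs) > max(abs(rs)) - 1e-12)[1L]
  es <- rs[i_max]
  leading <- if (es >= 0) genes[hit & seq_len(n) <= i_max]
             else genes[hit & seq_len(n) >= i_max]
  stopifnot(es >= -1 - 1e-12, es <= 1 + 1e-12)
  list(es = max(-1, min(1, es)), running_sum = rs, leading_edge = leading)
}

#' Permutation null distribution of the enrichment score
#'
#' Draws `n_permutations` uniformly random gene subsets of the given size
#' from the ranked list (gene-label permutation, the natural null for a
#' pre-ranked analysis) and returns their enrichment scores. The null is a
#' function of the ranked scores and the set size only, so identical-size
#' sets can share one null sample. Deterministic for a given
#' `params$seed`: the draw is seeded with `params$seed + set_size`.
#'
#' @param ranked Ranked gene list (sorted by score descending).
#' @param set_size Subset size, in `[min_set_size, N - 1]`.
#' @param params A [gsea_params()].
#' @return Numeric vector of `n_permutations` null enrichment scores.
#' @export
permutation_null <- function(ranked, set_size, params = gsea_params()) {
  n <- nrow(ranked)
  if (set_size < params$min_set_size || set_size >= n) {
    stop("set_size must lie in [min_set_size, N - 1]", call. = FALSE)
  }
  sw <- abs(ranked$score)^params$weight_exponent
  set.seed(params$seed + set_size)
  gsea_null_es(sw, as.integer(set_size), params$n_permutations)
}

# canonical sign-sided nominal p with add-one on both counts
gsea_nominal_p <- function(es, null_es) {
  if (es >= 0) {
    side <- null_es[null_es >= 0]
    (1 + sum(side >= es)) / (1 + length(side))
  } else {
    side <- null_es[null_es < 0]
    (1 + sum(side <= es)) / (1 + length(side))
  }
}

# ES -> NES given the same-sign null means; NA when the side is empty
gsea_nes <- function(es, mean_pos, mean_neg) {
  if (es >= 0) {
    if (is.na(mean_pos) || mean_pos == 0) NA_real_ else es / mean_pos
  } else {
    if (is.na(mean_neg) || mean_neg == 0) NA_real_ else es / mean_neg
  }
}

#' Run pre-ranked GSEA over a gene-set collection
#'
#' For every set: intersects with the ranked universe, computes the weighted
#' enrichment score, a sign-sided nominal permutation p-value with add-one
#' correction, the normalised enrichment score (ES divided by the mean
#' |null ES| of matching sign for that set size), and the canonical
#' NES-based FDR in which observed NES are compared against the pooled,
#' per-size-normalised permutation NES. Sets whose used size falls outside
#' `[min_set_size, max_set_size]` (or that are empty/degenerate on this
#' universe) are excluded and listed in the `excluded` attribute.
#'
#' Permutation nulls are cached per set size: under gene-label permutation
#' every set of the same size shares the same null, which keeps the
#' screen's hot loop (hundreds of terms, hundreds of permutations) cheap.
#'
#' @param ranked Ranked gene list.
#' @param collection A [gene_set_collection()].
#' @param params A [gsea_params()].
#' @return `data.frame` with columns `set_id`, `es`, `nes`, `p_nominal`,
#'   `fdr`, `set_size_used`, `leading_edge` (comma-joined), sorted by `fdr`
#'   ascending with ties by |nes| descending then `set_id`; attribute
#'   `excluded` reports skipped sets and reasons.
#' @export
run_collection <- function(ranked, collection, params = gsea_params()) {
  stopifnot(inherits(collection, "gene_set_collection"))
  n <- nrow(ranked)
  universe <- ranked$gene_id
  # one hash build for the whole collection: member -> ranked position
  all_members <- unlist(collection, use.names = FALSE)
  pos_all <- match(all_members, universe)
  pos_by_set <- split(pos_all, rep(seq_along(collection),
                                   lengths(collection)))
  pos_by_set <- lapply(pos_by_set, function(p) sort(p[!is.na(p)]))
  names(pos_by_set) <- names(collection)
  sizes <- lengths(pos_by_set)
  max_ok <- if (is.null(params$max_set_size)) n - 1L else
    min(params$max_set_size, n - 1L)
  keep <- sizes >= params$min_set_size & sizes <= max_ok
  excluded <- data.frame(set_id = names(collection)[!keep],
                         set_size_used = sizes[!keep],
                         reason = ifelse(sizes[!keep] < params$min_set_size,
                                         "below min_set_size",
                                         "above max size or degenerate"),
                         stringsAsFactors = FALSE)
  ids <- names(collection)[keep]
  if (!length(ids)) {
    out <- data.frame(set_id = character(), es = numeric(), nes = numeric(),
                      p_nominal = numeric(), fdr = numeric(),
                      set_size_used = integer(), leading_edge = character(),
                      stringsAsFactors = FALSE)
    attr(out, "excluded") <- excluded
    return(out)
  }

  sw <- abs(ranked$score)^params$weight_exponent
  es_list <- lapply(ids, function(id) {
    gsea_es_extremum(sw, pos_by_set[[id]])
  })
  es <- vapply(es_list, `[[`, numeric(1L), "es")
  le <- vapply(seq_along(ids), function(i) {
    pos <- pos_by_set[[ids[i]]]
    ext <- es_list[[i]]$extremum
    lead <- if (es[i] >= 0) pos[pos <= ext] else pos[pos >= ext]
    paste(universe[lead], collapse = ",")
  }, character(1L))
  size_used <- sizes[ids]

  # one cached null per distinct size (sorted for seed determinism)
  distinct_sizes <- sort(unique(size_used))
  nulls <- lapply(distinct_sizes, function(k) {
    permutation_null(ranked, k, params)
  })
  names(nulls) <- as.character(distinct_sizes)

  mean_pos <- vapply(nulls, function(z) {
    p <- z[z >= 0]; if (length(p)) mean(p) else NA_real_
  }, numeric(1L))
  mean_neg <- vapply(nulls, function(z) {
    q <- z[z < 0]; if (length(q)) mean(abs(q)) else NA_real_
  }, numeric(1L))

  key <- as.character(size_used)
  p_nom <- vapply(seq_along(ids), function(i) {
    gsea_nominal_p(es[i], nulls[[key[i]]])
  }, numeric(1L))
  nes <- vapply(seq_along(ids), function(i) {
    gsea_nes(es[i], mean_pos[[key[i]]], mean_neg[[key[i]]])
  }, numeric(1L))

  # pooled null NES: every permutation ES normalised by its size's
  # same-sign null mean
  null_nes <- unlist(lapply(as.character(distinct_sizes), function(k) {
    z <- nulls[[k]]
    out <- numeric(length(z))
    pos <- z >= 0
    out[pos] <- if (!is.na(mean_pos[[k]]) && mean_pos[[k]] > 0)
      z[pos] / mean_pos[[k]] else NA_real_
    out[!pos] <- if (!is.na(mean_neg[[k]]) && mean_neg[[k]] > 0)
      z[!pos] / mean_neg[[k]] else NA_real_
    out
  }), use.names = FALSE)
  null_nes <- null_nes[!is.na(null_nes)]
  fdr <- gsea_fdr(nes, null_nes)

  out <- data.frame(set_id = ids, es = es, nes = nes, p_nominal = p_nom,
                    fdr = fdr, set_size_used = as.integer(size_used),
                    leading_edge = le, stringsAsFactors = FALSE)
  ord <- order(out$fdr, -abs(out$nes), out$set_id, method = "radix",
               na.last = TRUE)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

# canonical GSEA FDR: for NES* >= 0,
#   q = [#{null NES >= NES*} / #{null NES >= 0}] /
#       [#{obs NES >= NES*} / #{obs NES >= 0}], capped at 1
# (mirrored for the negative side)
gsea_fdr <- function(nes, null_nes) {
  n_pos_null <- sum(null_nes >= 0)
  n_neg_null <- sum(null_nes < 0)
  n_pos_obs <- sum(nes >= 0, na.rm = TRUE)
  n_neg_obs <- sum(nes < 0, na.rm = TRUE)
  vapply(nes, function(s) {
    if (is.na(s)) return(NA_real_)
    if (s >= 0) {
      if (n_pos_null == 0L || n_pos_obs == 0L) return(NA_real_)
      num <- sum(null_nes >= s) / n_pos_null
      den <- sum(nes >= s, na.rm = TRUE) / n_pos_obs
    } else {
      if (n_neg_null == 0L || n_neg_obs == 0L) return(NA_real_)
      num <- sum(null_nes <= s) / n_neg_null
      den <- sum(nes <= s, na.rm = TRUE) / n_neg_obs
    }
    min(1, num / den)
  }, numeric(1L))
}
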