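#' Default immunological keyword vocabulary
#'
#' Lowercase substrings used to pull immune-related terms out of a GO
#' annotation table. Shipped as an ordinary character vector so the whole
#' downstream screen can be re-parameterised by editing it.
#'
#' @return Character vector of lowercase keywords.
#' @export
default_keywords <- function() {
  c("immune", "immun", "inflamm", "leukocyte", "lymphocyte", "t cell",
    "b cell", "cytokine", "chemokine", "interferon", "interleukin",
    "antigen", "mhc", "natural killer", "macrophage", "dendritic",
    "phagocyt", "complement", "toll-like", "myeloid")
}

#' Default immune functional categories
#'
#' Seven themes used to break the immune GO space down for the bubble
#' summary. A term may match several categories (GO is not partitioned by
#' theme); terms matching none fall into a residual `"other immune"` bin.
#'
#' @return Named list mapping category name to keyword vector.
#' @export
default_category_map <- function() {
  list(
    "immune response regulation" = c("regulation of immune",
                                     "immune response",
                                     "immune system"),
    "inflammatory response" = c("inflamm"),
    "lymphocyte activation & differentiation" =
      c("lymphocyte", "t cell", "b cell", "natural killer"),
    "myeloid/dendritic cell activation" =
      c("myeloid", "dendritic", "macrophage", "phagocyt"),
    "antigen processing & presentation" = c("antigen", "mhc"),
    "cytokine production & signalling" =
      c("cytokine", "chemokine", "interferon", "interleukin"),
    "leukocyte migration" = c("leukocyte migration", "chemotaxis",
                              "leukocyte")
  )
}

#' Keyword configuration for the immune GO filter
#'
#' @param keywords Lowercase keyword vocabulary (default
#'   [default_keywords()]).
#' @param category_map Named list of category keyword vectors (default
#'   [default_category_map()], 7 categories).
#' @param match_fields Which GO-table fields to scan: subset of
#'   `c("name", "description")`.
#' @return List of class `"keyword_config"`.
#' @export
keyword_config <- function(keywords = default_keywords(),
                           category_map = default_category_map(),
                           match_fields = c("name", "description")) {
  if (!length(keywords)) stop("keywords must be non-empty", call. = FALSE)
  match_fields <- match.arg(match_fields, c("name", "description"),
                            several.ok = TRUE)
  if (is.null(names(category_map)) || anyDuplicated(names(category_map))) {
    stop("category_map must have unique names", call. = FALSE)
  }
  structure(list(keywords = tolower(keywords),
                 category_map = lapply(category_map, tolower),
                 match_fields = match_fields),
            class = "keyword_config")
}

#' Read a keyword configuration from YAML
#'
#' Loads the editable vocabulary file (see
#' `system.file("extdata", "immune_keywords.yaml", package = "mirimmune")`
#' for the shipped default, which reproduces [default_keywords()] and
#' [default_category_map()]).
#'
#' @param path Path to a YAML file with top-level fields `keywords`,
#'   `categories` and optionally `match_fields`.
#' @return A [keyword_config()].
#' @export
read_keyword_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  if (is.null(y$keywords) || is.null(y$categories)) {
    stop("keyword YAML needs `keywords` and `categories` fields",
         call. = FALSE)
  }
  keyword_config(keywords = unlist(y$keywords),
                 category_map = lapply(y$categories, unlist),
                 match_fields = if (!is.null(y$match_fields))
                   unlist(y$match_fields) else c("name", "description"))
}

# lowercase concatenation of the configured match fields per term
match_text <- function(table, cfg) {
  txt <- rep("", nrow(table))
  for (f in cfg$match_fields) txt <- paste(txt, tolower(table[[f]]))
  txt
}

matched_keywords <- function(text, keywords) {
  lapply(text, function(t) {
    keywords[vapply(keywords, grepl, logical(1L), x = t, fixed = TRUE)]
  })
}

#' Filter a GO table to immunological terms by keyword
#'
#' A term is retained iff any vocabulary keyword occurs case-insensitively
#' as a substring in any configured match field. The filter is monotone in
#' the vocabulary: adding a keyword can only retain more terms.
#'
#' @param table A [go_term_table()].
#' @param cfg A [keyword_config()].
#' @return Subset of `table` with an extra `matched_keywords` column
#'   (comma-joined per term).
#' @export
filter_immune_terms <- function(table, cfg = keyword_config()) {
  stopifnot(inherits(cfg, "keyword_config"))
  hits <- matched_keywords(match_text(table, cfg), cfg$keywords)
  keep <- lengths(hits) > 0L
  out <- table[keep, , drop = FALSE]
  out$matched_keywords <- vapply(hits[keep], paste, character(1L),
                                 collapse = ",")
  rownames(out) <- NULL
  out
}

#' Assign immune functional categories to filtered GO terms
#'
#' Every category whose keyword list hits the term's match fields is
#' assigned; terms hitting no category go to `"other immune"` so nothing is
#' silently dropped.
#'
#' @param table Filtered GO table (rows already retained by
#'   [filter_immune_terms()]).
#' @param cfg A [keyword_config()].
#' @return Named list (by `term_id`) of category-name character vectors.
#' @export
assign_categories <- function(table, cfg = keyword_config()) {
  stopifnot(inherits(cfg, "keyword_config"))
  text <- match_text(table, cfg)
  cats <- names(cfg$category_map)
  out <- lapply(text, function(t) {
    hit <- vapply(cats, function(cat) {
      any(vapply(cfg$category_map[[cat]], grepl, logical(1L), x = t,
                 fixed = TRUE))
    }, logical(1L))
    if (any(hit)) cats[hit] else "other immune"
  })
  names(out) <- table$term_id
  out
}

#' Count significant immune terms for one miRNA
#'
#' Restricts one miRNA's enrichment results to the immune-filtered GO
#' terms, counts those significant at `criterion < alpha` in total and per
#' category, and records `-log2(best p)` per category for the bubble-plot
#' colour scale.
#'
#' @param results `data.frame` of enrichment results for one miRNA
#'   ([run_collection()] output) whose `set_id` are GO term IDs.
#' @param immune_terms Filtered GO table from [filter_immune_terms()].
#' @param cfg A [keyword_config()] (category assignment).
#' @param alpha Significance level (default 0.05).
#' @param criterion `"p_nominal"` (default) or `"fdr"`.
#' @param mirna_id Optional miRNA ID to record (defaults to the attribute
#'   on `results` when present).
#' @return List of class `"mirna_immune_score"` with `mirna_id`,
#'   `n_significant_total`, `n_significant_by_category`,
#'   `min_log2p_by_category` and `n_terms_tested`.
#' @export
count_significant <- function(results, immune_terms, cfg = keyword_config(),
                              alpha = 0.05,
                              criterion = c("p_nominal", "fdr"),
                              mirna_id = NULL) {
  criterion <- match.arg(criterion)
  if (is.null(mirna_id)) {
    mirna_id <- attr(results, "mirna_id")
    if (is.null(mirna_id)) mirna_id <- NA_character_
  }
  imm <- results[results$set_id %in% immune_terms$term_id, , drop = FALSE]
  if (nrow(imm) == 0L) {
    stop("no immune terms among the enrichment results", call. = FALSE)
  }
  crit <- imm[[criterion]]
  sig <- !is.na(crit) & crit < alpha
  term_cats <- assign_categories(
    immune_terms[match(imm$set_id, immune_terms$term_id), , drop = FALSE],
    cfg)
  cats <- c(names(cfg$category_map), "other immune")
  n_by_cat <- stats::setNames(integer(length(cats)), cats)
  minp_by_cat <- stats::setNames(rep(NA_real_, length(cats)), cats)
  for (cat in cats) {
    in_cat <- vapply(term_cats, function(z) cat %in% z, logical(1L))
    n_by_cat[[cat]] <- sum(sig & in_cat)
    p_cat <- imm$p_nominal[in_cat]
    if (length(p_cat)) minp_by_cat[[cat]] <- -log2(min(p_cat))
  }
  structure(list(mirna_id = mirna_id,
                 n_significant_total = sum(sig),
                 n_significant_by_category = n_by_cat,
                 min_log2p_by_category = minp_by_cat,
                 n_terms_tested = nrow(imm)),
            class = "mirna_immune_score")
}

#' Rank miRNAs by number of significant immune terms
#'
#' Descending by total significant immune terms; ties broken by the sum of
#' per-category `-log2(best p)` colour scores (descending), then by miRNA
#' ID. Rank 1 is the screen hit.
#'
#' @param scores List of `"mirna_immune_score"` records.
#' @return `data.frame` with `rank`, `mirna_id`, `n_significant_total`,
#'   `sum_min_log2p`, `n_terms_tested`.
#' @export
rank_mirnas <- function(scores) {
  if (!length(scores)) stop("no scores to rank", call. = FALSE)
  df <- data.frame(
    mirna_id = vapply(scores, `[[`, character(1L), "mirna_id"),
    n_significant_total = vapply(scores, `[[`, integer(1L),
                                 "n_significant_total"),
    sum_min_log2p = vapply(scores, function(s) {
      sum(s$min_log2p_by_category, na.rm = TRUE)
    }, numeric(1L)),
    n_terms_tested = vapply(scores, `[[`, integer(1L), "n_terms_tested"),
    stringsAsFactors = FALSE)
  ord <- order(-df$n_significant_total, -df$sum_min_log2p, df$mirna_id,
               method = "radix")
  df <- df[ord, , drop = FALSE]
  df <- cbind(rank = seq_len(nrow(df)), df)
  rownames(df) <- NULL
  df
}

#' Long-format bubble table for the per-category summary plot
#'
#' One row per (miRNA, category) with a non-zero significant count —
#' plot-ready with bubble size = count and colour = `-log2(best p)`.
#'
#' @param scores List of `"mirna_immune_score"` records.
#' @return `data.frame` with `mirna_id`, `category`, `count`,
#'   `neg_log2_p`.
#' @export
bubble_table <- function(scores) {
  if (!length(scores)) stop("no scores given", call. = FALSE)
  rows <- lapply(scores, function(s) {
    nz <- s$n_significant_by_category > 0L
    if (!any(nz)) return(NULL)
    data.frame(mirna_id = s$mirna_id,
               category = names(s$n_significant_by_category)[nz],
               count = unname(s$n_significant_by_category[nz]),
               neg_log2_p = unname(s$min_log2p_by_category[nz]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(mirna_id = character(), category = character(),
                      count = integer(), neg_log2_p = numeric(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
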