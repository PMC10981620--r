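#' Run the per-miRNA immune screen over a cohort in memory
#'
#' The screen's core loop: for every miRNA, rank all genes by signed
#' Pearson correlation with its expression, run pre-ranked GSEA over the GO
#' gene sets, count significant immune-filtered terms, and finally rank the
#' miRNAs by that count.
#'
#' @param mirnas miRNA [expression_matrix()].
#' @param genes Gene [expression_matrix()].
#' @param go_sets [gene_set_collection()] of per-GO-term gene sets.
#' @param go_table [go_term_table()] of term annotations.
#' @param keywords A [keyword_config()].
#' @param params A [gsea_params()].
#' @param alpha Significance level for counting (default 0.05).
#' @param criterion `"p_nominal"` (default) or `"fdr"`.
#' @return List with `ranking` (from [rank_mirnas()]), `scores` (per-miRNA
#'   `"mirna_immune_score"` records), `bubble` (from [bubble_table()]),
#'   `enrichment` (named list of per-miRNA [run_collection()] tables) and
#'   `immune_terms` (the filtered GO table).
#' @export
screen_cohort <- function(mirnas, genes, go_sets, go_table,
                          keywords = keyword_config(),
                          params = gsea_params(), alpha = 0.05,
                          criterion = c("p_nominal", "fdr")) {
  criterion <- match.arg(criterion)
  immune_terms <- filter_immune_terms(go_table, keywords)
  if (nrow(immune_terms) == 0L) {
    stop("keyword filter retained no immune terms", call. = FALSE)
  }
  mirna_ids <- rownames(mirnas)
  enrichment <- vector("list", length(mirna_ids))
  names(enrichment) <- mirna_ids
  scores <- vector("list", length(mirna_ids))
  for (i in seq_along(mirna_ids)) {
    ranked <- rank_genes_for_mirna(mirna_ids[i], mirnas, genes)
    enrichment[[i]] <- run_collection(ranked, go_sets, params)
    scores[[i]] <- count_significant(enrichment[[i]], immune_terms,
                                     keywords, alpha = alpha,
                                     criterion = criterion,
                                     mirna_id = mirna_ids[i])
  }
  list(ranking = rank_mirnas(scores), scores = scores,
       bubble = bubble_table(scores), enrichment = enrichment,
       immune_terms = immune_terms)
}

#' Configuration for a full synthetic screen run
#'
#' Bundles every stage's settings and derives per-stage seeds from one
#' master seed (`seed + 1` cohort, `+ 2` GO universe, `+ 3` signatures,
#' `+ 4` GSEA) so a single integer reproduces the whole run.
#'
#' @param out_dir Output directory (created if missing).
#' @param cohort A [cohort_config()]; its seed is overridden by the derived
#'   stage seed.
#' @param n_go_terms,immune_fraction GO universe shape (defaults 120 terms,
#'   one third immune).
#' @param n_signatures,contamination Immune signature collection shape
#'   (defaults 68 signatures, 20% background contamination).
#' @param gsea A [gsea_params()]; its seed is likewise derived.
#' @param keywords A [keyword_config()].
#' @param alpha Significance level (default 0.05).
#' @param criterion `"p_nominal"` or `"fdr"`.
#' @param seed Master integer seed.
#' @return List of class `"screen_config"`.
#' @export
screen_config <- function(out_dir, cohort = cohort_config(),
                          n_go_terms = 120L, immune_fraction = 1 / 3,
                          n_signatures = 68L, contamination = 0.2,
                          gsea = gsea_params(),
                          keywords = keyword_config(), alpha = 0.05,
                          criterion = "p_nominal", seed = 1L) {
  seed <- as.integer(seed)
  cohort$seed <- seed + 1L
  gsea$seed <- seed + 4L
  structure(list(out_dir = out_dir, cohort = cohort,
                 n_go_terms = as.integer(n_go_terms),
                 immune_fraction = immune_fraction,
                 n_signatures = as.integer(n_signatures),
                 contamination = contamination, gsea = gsea,
                 keywords = keywords, alpha = alpha,
                 criterion = match.arg(criterion, c("p_nominal", "fdr")),
                 seed = seed),
            class = "screen_config")
}

#' Run the full synthetic screen end to end
#'
#' simulate -> correlate -> GSEA -> immune filter/count/rank -> ssGSEA ->
#' signature correlation, writing every intermediate artifact under
#' `config$out_dir` and returning a manifest (stage seeds, row counts, MD5
#' checksums of every written file). Re-running with the same config
#' produces bit-identical outputs.
#'
#' @param config A [screen_config()].
#' @return Invisibly, the manifest list (also written as
#'   `manifest.json`).
#' @export
run_full_screen <- function(config) {
  stopifnot(inherits(config, "screen_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  seed <- config$seed

  cohort <- generate_cohort(config$cohort)
  universe <- generate_go_universe(config$n_go_terms,
                                   config$immune_fraction,
                                   config$keywords$keywords,
                                   truth = cohort$truth, seed = seed + 2L)
  signatures <- generate_signature_collection(config$n_signatures,
                                              cohort$truth,
                                              config$contamination,
                                              seed = seed + 3L)

  write_expression_tsv(cohort$genes, out("genes.tsv"), seed = seed + 1L)
  write_expression_tsv(cohort$mirnas, out("mirnas.tsv"), seed = seed + 1L)
  write_results_table(universe$go_table, out("go_terms.tsv"),
                      seed = seed + 2L)
  write_gmt(universe$go_sets, out("go_sets.gmt"))
  write_gmt(signatures, out("signatures.gmt"))
  truth_json <- cohort$truth[c("planted_regulators", "immune_set_ids",
                               "expected_rho", "seed")]
  jsonlite::write_json(truth_json, out("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  screen <- screen_cohort(cohort$mirnas, cohort$genes, universe$go_sets,
                          universe$go_table, config$keywords, config$gsea,
                          alpha = config$alpha,
                          criterion = config$criterion)
  write_results_table(screen$ranking, out("ranked_mirnas.tsv"), seed = seed)
  write_results_table(screen$bubble, out("bubble_table.tsv"), seed = seed)
  enr_all <- do.call(rbind, lapply(names(screen$enrichment), function(m) {
    cbind(mirna_id = m, screen$enrichment[[m]])
  }))
  write_results_table(enr_all, out("enrichment_all.tsv"), seed = seed + 4L)

  sig_scores <- score_matrix(cohort$genes, signatures)
  score_df <- data.frame(signature_id = rownames(sig_scores$scores),
                         as.data.frame(sig_scores$scores,
                                       check.names = FALSE),
                         check.names = FALSE, stringsAsFactors = FALSE)
  write_results_table(score_df, out("signature_scores.tsv"), seed = seed)

  scm <- correlate_signatures(cohort$mirnas, sig_scores)
  rho_df <- data.frame(mirna_id = rownames(scm$rho),
                       as.data.frame(scm$rho, check.names = FALSE),
                       check.names = FALSE, stringsAsFactors = FALSE)
  p_df <- data.frame(mirna_id = rownames(scm$p),
                     as.data.frame(scm$p, check.names = FALSE),
                     check.names = FALSE, stringsAsFactors = FALSE)
  write_results_table(rho_df, out("signature_rho.tsv"), seed = seed)
  write_results_table(p_df, out("signature_p.tsv"), seed = seed)
  direction <- do.call(rbind, lapply(rownames(scm$rho), function(m) {
    d <- directionality_summary(scm, m, alpha = config$alpha)
    data.frame(mirna_id = m, fraction_positive = d$fraction_positive,
               mean_rho = d$mean_rho,
               n_significant_positive = d$n_significant_positive,
               n_signatures = d$n_signatures, stringsAsFactors = FALSE)
  }))
  write_results_table(direction, out("directionality.tsv"), seed = seed)

  files <- c("genes.tsv", "mirnas.tsv", "go_terms.tsv", "go_sets.gmt",
             "signatures.gmt", "truth.json", "ranked_mirnas.tsv",
             "bubble_table.tsv", "enrichment_all.tsv",
             "signature_scores.tsv", "signature_rho.tsv",
             "signature_p.tsv", "directionality.tsv")
  manifest <- list(
    package_version = as.character(utils::packageVersion("mirimmune")),
    master_seed = seed,
    stage_seeds = list(cohort = seed + 1L, go_universe = seed + 2L,
                       signatures = seed + 3L, gsea = seed + 4L),
    counts = list(n_samples = config$cohort$n_samples,
                  n_genes = config$cohort$n_genes,
                  n_mirnas = config$cohort$n_mirnas,
                  n_go_terms = config$n_go_terms,
                  n_immune_terms = nrow(screen$immune_terms),
                  n_signatures = config$n_signatures),
    top_mirna = screen$ranking$mirna_id[1L],
    planted_regulators = cohort$truth$planted_regulators,
    file_md5 = as.list(tools::md5sum(vapply(files, out, character(1L)))))
  names(manifest$file_md5) <- files
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
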