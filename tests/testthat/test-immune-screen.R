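toy_go <- function() {
  go_term_table(data.frame(
    term_id = sprintf("GO:%07d", 1:6),
    name = c("T cell activation",
             "mitochondrion organization",
             "regulation of immune response",
             "inflammatory response to wounding",
             "antigen processing and presentation of peptide antigen",
             "dna replication"),
    description = "",
    stringsAsFactors = FALSE))
}

test_that("keyword filter retains immunological terms case-insensitively", {
  filtered <- filter_immune_terms(toy_go(), keyword_config())
  expect_setequal(filtered$name,
                  c("T cell activation", "regulation of immune response",
                    "inflammatory response to wounding",
                    "antigen processing and presentation of peptide antigen"))
  expect_match(filtered$matched_keywords[filtered$name == "T cell activation"],
               "t cell")
})

test_that("filter is monotone in the vocabulary", {
  base_kw <- c("immune", "inflamm")
  f1 <- filter_immune_terms(toy_go(), keyword_config(keywords = base_kw))
  f2 <- filter_immune_terms(toy_go(),
                            keyword_config(keywords = c(base_kw, "antigen")))
  expect_true(all(f1$term_id %in% f2$term_id))
  expect_gt(nrow(f2), nrow(f1))
})

test_that("categories are assigned by theme with a residual bin", {
  cfg <- keyword_config()
  expect_identical(length(default_category_map()), 7L)
  tab <- toy_go()
  filtered <- filter_immune_terms(tab, cfg)
  cats <- assign_categories(filtered, cfg)
  expect_true("immune response regulation" %in%
                cats[[filtered$term_id[filtered$name ==
                                         "regulation of immune response"]]])
  expect_true("inflammatory response" %in%
                cats[[filtered$term_id[
                  filtered$name == "inflammatory response to wounding"]]])
  expect_true("antigen processing & presentation" %in%
                cats[[filtered$term_id[grepl("antigen", filtered$name)]]])

  # a term hit by the vocabulary but by no category keyword is binned,
  # not dropped
  odd <- go_term_table(data.frame(term_id = "GO:0009999",
                                  name = "immunological memory",
                                  description = "",
                                  stringsAsFactors = FALSE))
  cfg2 <- keyword_config(keywords = "immun",
                         category_map = list(only = "inflamm"))
  expect_identical(assign_categories(filter_immune_terms(odd, cfg2),
                                     cfg2)[[1L]], "other immune")
})

make_results <- function(term_ids, p) {
  data.frame(set_id = term_ids, es = 0.5, nes = 1,
             p_nominal = p, fdr = p, set_size_used = 5L,
             leading_edge = "", stringsAsFactors = FALSE)
}

test_that("the shipped YAML vocabulary reproduces the built-in defaults", {
  path <- system.file("extdata", "immune_keywords.yaml",
                      package = "mirimmune")
  cfg <- read_keyword_config(path)
  expect_setequal(cfg$keywords, keyword_config()$keywords)
  expect_identical(cfg$category_map, keyword_config()$category_map)
  expect_identical(filter_immune_terms(toy_go(), cfg),
                   filter_immune_terms(toy_go(), keyword_config()))
})

test_that("significant immune terms are counted in total and per category", {
  cfg <- keyword_config()
  immune <- filter_immune_terms(toy_go(), cfg)

  all_null <- make_results(immune$term_id, 0.5)
  s0 <- count_significant(all_null, immune, cfg, mirna_id = "mir-x")
  expect_identical(s0$n_significant_total, 0L)
  expect_identical(s0$n_terms_tested, nrow(immune))

  # three inflammatory-category hits at p = 0.01
  infl <- go_term_table(data.frame(
    term_id = sprintf("GO:%07d", 11:13),
    name = paste("inflammatory response variant", 1:3),
    description = "", stringsAsFactors = FALSE))
  immune2 <- filter_immune_terms(infl, cfg)
  s1 <- count_significant(make_results(immune2$term_id, 0.01), immune2, cfg,
                          mirna_id = "mir-y")
  expect_identical(s1$n_significant_total, 3L)
  expect_identical(unname(s1$n_significant_by_category[
    "inflammatory response"]), 3L)
  other <- setdiff(names(s1$n_significant_by_category),
                   "inflammatory response")
  expect_true(all(s1$n_significant_by_category[other] == 0L))
  expect_equal(unname(s1$min_log2p_by_category["inflammatory response"]),
               -log2(0.01))

  # fdr criterion switch counts on the fdr column
  mixed <- make_results(immune2$term_id, 0.01)
  mixed$fdr <- c(0.2, 0.01, 0.2)
  s2 <- count_significant(mixed, immune2, cfg, criterion = "fdr",
                          mirna_id = "mir-z")
  expect_identical(s2$n_significant_total, 1L)
})

test_that("miRNA ranking orders by count with -log2 p then lexicographic ties", {
  mk <- function(id, total, colour) {
    structure(list(mirna_id = id, n_significant_total = as.integer(total),
                   n_significant_by_category = c(a = as.integer(total)),
                   min_log2p_by_category = c(a = colour),
                   n_terms_tested = 40L), class = "mirna_immune_score")
  }
  ranked <- rank_mirnas(list(mk("mir-b", 5, 10), mk("mir-a", 7, 3),
                             mk("mir-c", 5, 12), mk("mir-d", 5, 12)))
  expect_identical(ranked$mirna_id, c("mir-a", "mir-c", "mir-d", "mir-b"))
  expect_identical(ranked$rank, 1:4)
})

test_that("bubble table holds exactly the non-zero (miRNA, category) cells", {
  mk <- function(id, counts) {
    structure(list(mirna_id = id, n_significant_total = sum(counts),
                   n_significant_by_category = counts,
                   min_log2p_by_category = counts + 0.5,
                   n_terms_tested = 40L), class = "mirna_immune_score")
  }
  scores <- list(mk("mir-a", c(catA = 2L, catB = 0L)),
                 mk("mir-b", c(catA = 0L, catB = 0L)),
                 mk("mir-c", c(catA = 1L, catB = 3L)))
  bt <- bubble_table(scores)
  expect_identical(nrow(bt), 3L)
  expect_setequal(paste(bt$mirna_id, bt$category),
                  c("mir-a catA", "mir-c catA", "mir-c catB"))
  expect_identical(bt$count[bt$mirna_id == "mir-a"], 2L)
})

test_that("with no immune structure the per-miRNA count matches the alpha level", {
  # fully null cohort (gamma = beta = 0): immune sets are random with
  # respect to every ranking, so E[count] ~ alpha * n_immune_terms
  counts <- integer(0)
  for (s in 1:8) {
    co <- generate_cohort(cohort_config(n_samples = 100L, n_genes = 800L,
                                        n_mirnas = 5L, n_immune_sets = 10L,
                                        genes_per_set = 8L, gamma = 0,
                                        beta = 0, seed = 300 + s))
    u <- generate_go_universe(n_terms = 45L, immune_fraction = 1 / 3,
                              truth = co$truth, seed = 400 + s)
    sc <- screen_cohort(co$mirnas, co$genes, u$go_sets, u$go_table,
                        params = gsea_params(n_permutations = 200,
                                             seed = 500 + s))
    counts <- c(counts, vapply(sc$scores, `[[`, integer(1L),
                               "n_significant_total"))
  }
  n_imm <- 15L
  expected <- 0.05 * n_imm
  se <- sqrt(n_imm * 0.05 * 0.95 / length(counts))
  expect_lt(abs(mean(counts) - expected), expected * 0.5 + 4 * se)
})
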