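# helper: a ranked list with given scores and alphabetical gene IDs
toy_ranked <- function(scores) {
  data.frame(gene_id = sprintf("g%03d", seq_along(scores)),
             score = sort(scores, decreasing = TRUE),
             stringsAsFactors = FALSE)
}

test_that("extremal single-member sets give ES exactly +/- 1", {
  ranked <- toy_ranked(seq(10, 1))
  expect_equal(enrichment_score(ranked, "g001", w = 1)$es, 1.0)
  expect_equal(enrichment_score(ranked, "g010", w = 1)$es, -1.0)
  expect_equal(enrichment_score(ranked, "g001", w = 0)$es, 1.0)
})

test_that("10-gene worked example matches the hand-computed running sum", {
  # scores 10..1, hits at ranks {1,2,5}, w = 1: increments 10/25, 9/25,
  # 6/25, misses -1/7; the running sum peaks at 19/25 after the second hit
  ranked <- toy_ranked(seq(10, 1))
  members <- c("g001", "g002", "g005")
  res <- enrichment_score(ranked, members, w = 1)
  expect_equal(res$es, 19 / 25)
  expect_equal(res$es, oracle_es(ranked$score,
                                 ranked$gene_id %in% members, 1))
  expect_identical(res$leading_edge, c("g001", "g002"))
})

test_that("enrichment score agrees with the brute-force walk on random instances", {
  set.seed(7)
  for (i in 1:60) {
    n <- sample(8:50, 1)
    k <- sample(1:min(10, n - 1), 1)
    w <- sample(c(0, 1), 1)
    ranked <- toy_ranked(rnorm(n))
    members <- sample(ranked$gene_id, k)
    hit <- ranked$gene_id %in% members
    expect_equal(enrichment_score(ranked, members, w)$es,
                 oracle_es(ranked$score, hit, w), tolerance = 1e-12)
    # compiled position-based kernel agrees with the R reference
    expect_equal(gsea_es_positions(abs(ranked$score)^w, which(hit)),
                 oracle_es(ranked$score, hit, w), tolerance = 1e-12)
  }
})

test_that("running sum ends at zero and ES stays within [-1, 1]", {
  set.seed(8)
  for (i in 1:25) {
    ranked <- toy_ranked(rnorm(sample(10:80, 1)))
    members <- sample(ranked$gene_id, sample(2:8, 1))
    res <- enrichment_score(ranked, members, w = 1)
    expect_lt(abs(res$running_sum[length(res$running_sum)]), 1e-9)
    expect_true(abs(res$es) <= 1)
  }
})

test_that("w = 0 reduces to the classic KS statistic (ECDF difference)", {
  set.seed(9)
  for (i in 1:20) {
    n <- sample(20:60, 1)
    ranked <- toy_ranked(rnorm(n))
    members <- sample(ranked$gene_id, sample(3:8, 1))
    hit <- ranked$gene_id %in% members
    pos_in <- which(hit)
    pos_out <- which(!hit)
    # signed maximal ECDF difference evaluated over all list positions
    diffs <- vapply(seq_len(n), function(j) {
      mean(pos_in <= j) - mean(pos_out <= j)
    }, numeric(1))
    ks_signed <- diffs[which.max(abs(diffs))]
    expect_equal(enrichment_score(ranked, members, w = 0)$es, ks_signed,
                 tolerance = 1e-12)
  }
})

test_that("weighted ES matches the independent fgsea implementation", {
  set.seed(10)
  for (i in 1:20) {
    n <- sample(15:60, 1)
    ranked <- toy_ranked(rnorm(n))
    members <- sample(ranked$gene_id, sample(2:8, 1))
    stats <- stats::setNames(ranked$score, ranked$gene_id)
    ref <- fgsea::calcGseaStat(stats, which(ranked$gene_id %in% members),
                               gseaParam = 1)
    expect_equal(enrichment_score(ranked, members, w = 1)$es, ref,
                 tolerance = 1e-9)
  }
})

test_that("permutation null is deterministic under seed and symmetric when exchangeable", {
  ranked <- toy_ranked(rep(1, 40))
  params <- gsea_params(weight_exponent = 0, n_permutations = 2000,
                        seed = 5)
  null1 <- permutation_null(ranked, 5, params)
  null2 <- permutation_null(ranked, 5, params)
  expect_identical(null1, null2)
  expect_lt(abs(mean(null1)), 2 * sd(null1) / sqrt(length(null1)))
  null3 <- permutation_null(ranked, 5, gsea_params(weight_exponent = 0,
                                                   n_permutations = 2000,
                                                   seed = 6))
  expect_false(identical(null1, null3))
})

test_that("permutation null matches exhaustive enumeration on a small list", {
  # every C(12, 3) = 220 subset vs 4000 sampled permutations
  ranked <- toy_ranked(rnorm(12))
  exact <- apply(utils::combn(12, 3), 2L, function(idx) {
    oracle_es(ranked$score, seq_len(12) %in% idx, 1)
  })
  nulls <- permutation_null(ranked, 3,
                            gsea_params(n_permutations = 4000, seed = 2))
  ks <- suppressWarnings(stats::ks.test(nulls, exact))
  expect_lt(unname(ks$statistic), 0.07)
})

test_that("run_collection applies size filters, reports exclusions, and orders by FDR", {
  set.seed(11)
  ranked <- toy_ranked(rnorm(100))
  coll <- gene_set_collection(list(
    big_top = ranked$gene_id[1:10],
    small = ranked$gene_id[c(4, 9)],     # below min size 3
    mid = sample(ranked$gene_id, 8),
    ghost = c("zzz1", "zzz2", "zzz3")    # no overlap
  ))
  params <- gsea_params(n_permutations = 200, seed = 3)
  res <- run_collection(ranked, coll, params)
  excl <- attr(res, "excluded")
  expect_setequal(excl$set_id, c("small", "ghost"))
  expect_true(all(excl$reason == "below min_set_size"))
  expect_setequal(res$set_id, c("big_top", "mid"))
  expect_true(!is.unsorted(res$fdr, na.rm = TRUE))
  expect_true(all(res$p_nominal >= 1 / (params$n_permutations + 1)))
  # a set made of the top decile is the collection's strongest hit
  expect_identical(res$set_id[1L], "big_top")
  expect_identical(res$fdr[1L], min(res$fdr))
})

test_that("run_collection is reproducible under its seed", {
  set.seed(12)
  ranked <- toy_ranked(rnorm(60))
  coll <- gene_set_collection(list(a = ranked$gene_id[1:5],
                                   b = sample(ranked$gene_id, 7),
                                   c = sample(ranked$gene_id, 5)))
  p <- gsea_params(n_permutations = 100, seed = 9)
  expect_identical(run_collection(ranked, coll, p),
                   run_collection(ranked, coll, p))
})
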