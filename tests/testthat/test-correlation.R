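test_that("pearson matches textbook evaluation on hand-computable vectors", {
  expect_equal(cor_pearson(1:5, 1:5)$r, 1.0)
  expect_equal(cor_pearson(c(1, 2, 3, 4), c(2, 1, 4, 3))$r, 0.6)
  x <- c(0.3, 1.7, 2.2, 5.0, 8.1)
  expect_equal(cor_pearson(x, -2 * x + 7)$r, -1.0)
  # cross-check formula and p against the reference implementation
  set.seed(1)
  for (i in 1:20) {
    a <- rnorm(10)
    b <- rnorm(10)
    ref <- cor.test(a, b)
    got <- cor_pearson(a, b)
    expect_equal(got$r, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("pearson invariances: symmetry, affine maps, sign flip", {
  set.seed(2)
  x <- rnorm(30)
  y <- rnorm(30)
  expect_equal(cor_pearson(x, y)$r, cor_pearson(y, x)$r)
  expect_equal(cor_pearson(3 * x + 2, y)$r, cor_pearson(x, y)$r)
  expect_equal(cor_pearson(-x, y)$r, -cor_pearson(x, y)$r)
  expect_true(abs(cor_pearson(x, y)$r) <= 1)
})

test_that("spearman equals rank-then-pearson and is monotone-invariant", {
  x <- c(1, 2, 2, 3)
  y <- c(1, 3, 2, 4)
  got <- cor_spearman(x, y)
  expect_equal(got$rho,
               oracle_pearson_r(c(1, 2.5, 2.5, 4), c(1, 3, 2, 4)))
  xs <- c(-1.2, 0.1, 0.5, 2.2, 3.0)
  expect_equal(cor_spearman(xs, exp(xs))$rho, 1.0)
  expect_equal(cor_spearman(c(1, 2, 3), c(3, 2, 1))$rho, -1.0)
  set.seed(3)
  a <- rnorm(25)
  b <- rnorm(25)
  expect_equal(cor_spearman(a, b)$rho, cor_spearman(exp(a), b)$rho)
  expect_equal(cor_spearman(a, b)$rho,
               unname(cor.test(a, b, method = "spearman")$estimate),
               tolerance = 1e-12)
})

test_that("degenerate correlation inputs raise explicit errors", {
  expect_error(cor_pearson(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(cor_pearson(1:2, 1:2), "at least 3")
  expect_error(cor_pearson(1:4, 1:5), "equal length")
  expect_error(cor_spearman(rep(2, 5), rnorm(5)), "constant")
})

test_that("per-miRNA gene ranking is deterministic, aligned by sample ID, and complete", {
  co <- small_cohort(seed = 11)
  ranked <- rank_genes_for_mirna("mir-001", co$mirnas, co$genes)
  expect_identical(nrow(ranked), nrow(co$genes))
  expect_true(all(diff(ranked$score) <= 0))
  expect_true(all(abs(ranked$score) <= 1))
  expect_identical(attr(ranked, "n_samples_used"), ncol(co$genes))

  # shuffled sample columns give the same result (ID alignment, not position)
  shuffled <- unclass(co$genes)[, sample(ncol(co$genes))]
  em <- expression_matrix(shuffled, "gene")
  ranked2 <- rank_genes_for_mirna("mir-001", co$mirnas, em)
  expect_equal(ranked2$score, ranked$score, tolerance = 1e-12)
  expect_identical(ranked2$gene_id, ranked$gene_id)
})

test_that("constant genes are dropped with a report and ties break lexicographically", {
  set.seed(4)
  g <- matrix(rnorm(40), nrow = 4,
              dimnames = list(c("gB", "gA", "gFlat", "gC"),
                              sprintf("S%d", 1:10)))
  g["gFlat", ] <- 7
  g["gB", ] <- g["gA", ] # identical rows -> identical scores
  m <- matrix(rnorm(10), nrow = 1,
              dimnames = list("mir-x", sprintf("S%d", 1:10)))
  ranked <- rank_genes_for_mirna("mir-x",
                                 expression_matrix(m, "mirna"),
                                 expression_matrix(g, "gene"))
  expect_identical(attr(ranked, "dropped_constant"), "gFlat")
  expect_false("gFlat" %in% ranked$gene_id)
  iA <- match("gA", ranked$gene_id)
  iB <- match("gB", ranked$gene_id)
  expect_identical(iB, iA + 1L) # tie resolved by gene_id
})

test_that("planted regulator pushes immune genes to the top ranks", {
  co <- generate_cohort(cohort_config(n_samples = 200L, n_genes = 2000L,
                                      n_immune_sets = 20L,
                                      genes_per_set = 10L, seed = 12))
  ranked <- rank_genes_for_mirna(co$truth$planted_regulators[1L],
                                 co$mirnas, co$genes)
  pos <- match(co$truth$immune_gene_ids, ranked$gene_id)
  bg <- match(co$truth$background_gene_ids, ranked$gene_id)
  ws <- wilcox.test(pos, bg, alternative = "less")
  expect_lt(ws$p.value, 0.01)

  # a non-planted miRNA's scores are centred at zero
  ranked0 <- rank_genes_for_mirna("mir-003", co$mirnas, co$genes)
  expect_lt(abs(mean(ranked0$score)), 0.02)
})

test_that("fewer than 3 shared samples is an input error", {
  m <- expression_matrix(matrix(rnorm(4), 1, dimnames = list("mir-1",
                                                             paste0("A", 1:4))),
                         "mirna")
  g <- expression_matrix(matrix(rnorm(8), 2,
                                dimnames = list(c("g1", "g2"),
                                                c("A1", "A2", "B3", "B4"))),
                         "gene")
  expect_error(rank_genes_for_mirna("mir-1", m, g), "3 shared samples")
})
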