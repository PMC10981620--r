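#' Configuration for a synthetic tumour cohort
#'
#' The generator emulates the statistical core of a TCGA-style bulk cohort
#' used by the screen: a latent per-patient immune-activity factor couples a
#' small number of planted regulator miRNAs to the members of immune gene
#' sets, while all remaining genes and miRNAs are independent background
#' noise, variance-matched so that planted features cannot be detected by
#' their variance alone.
#'
#' With loadings `gamma` (miRNA side) and `beta` (gene side) and noise
#' standard deviation `sigma`, the population Pearson correlation between a
#' planted miRNA and any immune-set gene is
#' `rho = gamma * beta / sqrt((gamma^2 + sigma^2) * (beta^2 + sigma^2))`,
#' i.e. 0.5 at the default `gamma = beta = sigma = 1`.
#'
#' @param n_samples Number of patients (default 200).
#' @param n_genes Number of genes (default 5000). The default keeps the
#'   immune compartment (`n_immune_sets * genes_per_set` genes) at 8% of
#'   the transcriptome, matching the immune fraction of the GO universe in
#'   TCGA-style screens; making immune genes a large fraction of the
#'   universe degrades GSEA's permutation null (see the methods vignette).
#' @param n_mirnas Number of miRNAs (default 20).
#' @param n_immune_sets Number of immune gene blocks (default 40).
#' @param genes_per_set Genes per immune block (default 10);
#'   `n_immune_sets * genes_per_set` must not exceed `n_genes`.
#' @param planted_regulators Integer indices (1-based) of the miRNAs coupled
#'   to the latent factor (default miRNA 1).
#' @param gamma Loading of planted miRNAs on the latent factor (default 1).
#' @param beta Loading of immune-set genes on the latent factor (default 1).
#' @param sigma Noise standard deviation, must be positive (default 1).
#' @param seed Integer RNG seed.
#' @return A validated list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_samples = 200L, n_genes = 5000L, n_mirnas = 20L,
                          n_immune_sets = 40L, genes_per_set = 10L,
                          planted_regulators = 1L, gamma = 1, beta = 1,
                          sigma = 1, seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
              n_mirnas = as.integer(n_mirnas),
              n_immune_sets = as.integer(n_immune_sets),
              genes_per_set = as.integer(genes_per_set),
              planted_regulators = as.integer(planted_regulators),
              gamma = as.numeric(gamma), beta = as.numeric(beta),
              sigma = as.numeric(sigma), seed = as.integer(seed))
  with(cfg, {
    if (n_samples < 3L || n_genes < 1L || n_mirnas < 1L) {
      stop("cohort dimensions must be positive (and n_samples >= 3)",
           call. = FALSE)
    }
    if (length(planted_regulators) &&
        (any(planted_regulators < 1L) || any(planted_regulators > n_mirnas))) {
      stop("planted_regulators must be 1-based indices within 1..n_mirnas",
           call. = FALSE)
    }
    if (n_immune_sets * genes_per_set > n_genes) {
      stop("n_immune_sets * genes_per_set exceeds n_genes", call. = FALSE)
    }
    if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  })
  structure(cfg, class = "cohort_config")
}

#' Generate a synthetic tumour cohort with planted immune-regulator miRNAs
#'
#' Per sample `s` a latent immune activity `A_s ~ N(0, 1)` is drawn. Planted
#' miRNA expression is `gamma * A_s + N(0, sigma^2)`; immune-set gene
#' expression is `beta * A_s + N(0, sigma^2)`. All background features are
#' i.i.d. `N(0, sigma^2 + max(gamma, beta)^2)` so every feature has (at
#' least) the planted features' marginal variance. Bit-identical under a
#' fixed seed.
#'
#' @param config A [cohort_config()].
#' @return List with elements `genes` and `mirnas` (both
#'   [expression_matrix()]) and `truth`, a `"synthetic_truth"` record holding
#'   the planted miRNA IDs, immune block memberships, gene pools, the latent
#'   factor and the closed-form planted pairwise correlation
#'   `expected_rho`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_samples
  sample_ids <- sprintf("S%03d", seq_len(n))
  gene_ids <- sprintf("gene%04d", seq_len(config$n_genes))
  mirna_ids <- sprintf("mir-%03d", seq_len(config$n_mirnas))

  A <- stats::rnorm(n)
  bg_sd <- sqrt(config$sigma^2 + max(config$gamma, config$beta)^2)

  n_immune <- config$n_immune_sets * config$genes_per_set
  genes <- matrix(stats::rnorm(config$n_genes * n, sd = bg_sd),
                  nrow = config$n_genes,
                  dimnames = list(gene_ids, sample_ids))
  if (n_immune > 0L) {
    genes[seq_len(n_immune), ] <-
      matrix(rep(config$beta * A, each = n_immune), nrow = n_immune) +
      matrix(stats::rnorm(n_immune * n, sd = config$sigma), nrow = n_immune)
  }

  mirnas <- matrix(stats::rnorm(config$n_mirnas * n, sd = bg_sd),
                   nrow = config$n_mirnas,
                   dimnames = list(mirna_ids, sample_ids))
  for (m in config$planted_regulators) {
    mirnas[m, ] <- config$gamma * A + stats::rnorm(n, sd = config$sigma)
  }

  blocks <- split(gene_ids[seq_len(n_immune)],
                  rep(seq_len(config$n_immune_sets),
                      each = config$genes_per_set))
  names(blocks) <- sprintf("immune_block_%02d",
                           seq_len(config$n_immune_sets))

  truth <- structure(list(
    planted_regulators = mirna_ids[config$planted_regulators],
    immune_set_ids = names(blocks),
    immune_blocks = blocks,
    immune_gene_ids = gene_ids[seq_len(n_immune)],
    background_gene_ids = gene_ids[setdiff(seq_len(config$n_genes),
                                           seq_len(n_immune))],
    expected_rho = planted_pair_rho(config),
    latent_factor = stats::setNames(A, sample_ids),
    seed = config$seed
  ), class = "synthetic_truth")

  list(genes = expression_matrix(genes, "gene", unit = "synthetic z-scale"),
       mirnas = expression_matrix(mirnas, "mirna", unit = "synthetic z-scale"),
       truth = truth)
}

#' Closed-form planted-pair correlation
#'
#' Population Pearson correlation between a planted miRNA and an immune-set
#' gene implied by the single-factor model.
#'
#' @param config A [cohort_config()].
#' @return Scalar correlation.
#' @export
planted_pair_rho <- function(config) {
  with(config, gamma * beta /
         sqrt((gamma^2 + sigma^2) * (beta^2 + sigma^2)))
}

# name templates: immune ones each contain at least one default keyword,
# background ones are screened against the vocabulary at generation time
immune_name_templates <- c(
  "regulation of immune response",
  "immune system process activation",
  "inflammatory response",
  "acute inflammatory reaction",
  "t cell activation",
  "b cell differentiation",
  "lymphocyte proliferation",
  "natural killer cell mediated cytotoxicity",
  "myeloid cell activation",
  "dendritic cell maturation",
  "macrophage polarization",
  "phagocytosis engulfment",
  "antigen processing and presentation",
  "mhc class i assembly",
  "cytokine production",
  "chemokine mediated signaling",
  "interferon gamma response",
  "interleukin secretion",
  "leukocyte migration",
  "complement activation",
  "toll-like receptor signaling"
)

background_name_templates <- c(
  "mitochondrion organization", "dna replication", "rna splicing",
  "golgi vesicle transport", "lipid metabolic process",
  "cell cycle checkpoint", "protein folding", "ribosome biogenesis",
  "axon guidance", "heart development", "ion transport",
  "chromatin remodeling", "translation initiation",
  "oxidative phosphorylation", "actin cytoskeleton organization",
  "autophagosome assembly", "nucleotide excision repair",
  "calcium ion homeostasis", "wnt signaling pathway", "bone mineralization"
)

#' Generate a synthetic GO universe with keyword-identifiable immune terms
#'
#' Builds a GO-style annotation table plus one gene set per term. Immune
#' terms carry at least one vocabulary word in their name; non-immune terms
#' are verified free of every vocabulary word, so downstream keyword
#' filtering recovers the immune terms exactly. Immune term sets sample from
#' the cohort's immune genes, the rest from background genes.
#'
#' @param n_terms Total number of GO terms.
#' @param immune_fraction Fraction (0, 1) of terms that are immune; the
#'   immune count is `round(immune_fraction * n_terms)` and must be >= 1.
#' @param keyword_vocab Lowercase keyword vocabulary the immune names must
#'   hit and background names must avoid (default [default_keywords()]).
#' @param truth `"synthetic_truth"` from [generate_cohort()], supplying the
#'   immune and background gene pools.
#' @param set_size_range Length-2 integer range of per-term set sizes
#'   (default 5-25).
#' @param seed Integer RNG seed.
#' @return List with `go_table` (a [go_term_table()] with attribute
#'   `immune_term_ids`) and `go_sets` (a [gene_set_collection()] keyed by
#'   term ID).
#' @export
generate_go_universe <- function(n_terms = 120L, immune_fraction = 1 / 3,
                                 keyword_vocab = default_keywords(),
                                 truth, set_size_range = c(5L, 25L),
                                 seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"), length(keyword_vocab) > 0L)
  n_terms <- as.integer(n_terms)
  n_immune <- as.integer(round(immune_fraction * n_terms))
  if (immune_fraction <= 0 || immune_fraction >= 1 || n_immune < 1L) {
    stop("immune_fraction must give at least one immune term", call. = FALSE)
  }
  kv <- tolower(keyword_vocab)
  bg_names <- background_name_templates[
    !vapply(background_name_templates,
            function(nm) any(vapply(kv, grepl, logical(1L), x = nm,
                                    fixed = TRUE)),
            logical(1L))]
  imm_names <- immune_name_templates[
    vapply(immune_name_templates,
           function(nm) any(vapply(kv, grepl, logical(1L), x = nm,
                                   fixed = TRUE)),
           logical(1L))]
  if (!length(imm_names)) {
    stop("no immune name template contains a vocabulary keyword",
         call. = FALSE)
  }

  set.seed(seed)
  n_bg <- n_terms - n_immune
  name_of <- function(templates, k) {
    sprintf("%s variant %02d", templates[((seq_len(k) - 1L) %%
                                            length(templates)) + 1L],
            seq_len(k))
  }
  names_all <- c(name_of(imm_names, n_immune), name_of(bg_names, n_bg))
  is_immune <- c(rep(TRUE, n_immune), rep(FALSE, n_bg))
  term_ids <- sprintf("GO:%07d", seq_len(n_terms))

  sizes <- sample(seq(set_size_range[1L], set_size_range[2L]),
                  n_terms, replace = TRUE)
  pools <- list(truth$background_gene_ids, truth$immune_gene_ids)
  sets <- lapply(seq_len(n_terms), function(i) {
    pool <- pools[[is_immune[i] + 1L]]
    sample(pool, min(sizes[i], length(pool)))
  })
  names(sets) <- term_ids

  tab <- go_term_table(data.frame(
    term_id = term_ids, name = names_all,
    description = paste("synthetic gene ontology term:", names_all),
    stringsAsFactors = FALSE))
  attr(tab, "immune_term_ids") <- term_ids[is_immune]
  list(go_table = tab,
       go_sets = gene_set_collection(sets, descriptions = names_all))
}

#' Generate a synthetic immune-signature collection
#'
#' Emulates a curated collection of anti-cancer immune signatures: each
#' signature samples predominantly immune-set genes, with a configurable
#' contamination fraction of background genes (at `contamination = 1` the
#' signatures are indistinguishable from random background sets). The
#' default size of 68 mirrors a published anti-cancer immune signature
#' compendium.
#'
#' @param n_signatures Number of signatures (default 68).
#' @param truth `"synthetic_truth"` from [generate_cohort()].
#' @param contamination Fraction in \[0, 1\] of members drawn from background
#'   genes (default 0.2).
#' @param set_size_range Length-2 range of signature sizes (default 10-30).
#' @param seed Integer RNG seed.
#' @return A [gene_set_collection()] of `n_signatures` sets.
#' @export
generate_signature_collection <- function(n_signatures = 68L, truth,
                                          contamination = 0.2,
                                          set_size_range = c(10L, 30L),
                                          seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  n_signatures <- as.integer(n_signatures)
  if (n_signatures < 1L) stop("n_signatures must be >= 1", call. = FALSE)
  if (contamination < 0 || contamination > 1) {
    stop("contamination must be in [0, 1]", call. = FALSE)
  }
  set.seed(seed)
  sizes <- sample(seq(set_size_range[1L], set_size_range[2L]),
                  n_signatures, replace = TRUE)
  sets <- lapply(seq_len(n_signatures), function(i) {
    k_bg <- round(contamination * sizes[i])
    k_im <- sizes[i] - k_bg
    unique(c(sample(truth$immune_gene_ids, min(k_im,
                                               length(truth$immune_gene_ids))),
             if (k_bg > 0L)
               sample(truth$background_gene_ids,
                      min(k_bg, length(truth$background_gene_ids)))))
  })
  names(sets) <- sprintf("IMMSIG_%02d", seq_len(n_signatures))
  gene_set_collection(sets,
                      descriptions = "synthetic anti-cancer immune signature")
}
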