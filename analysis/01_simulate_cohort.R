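#!/usr/bin/env Rscript
# Simulate the synthetic tumour cohort the screen is evaluated on:
# 200 patients, 5000 genes (400 of them immune, coupled to a latent
# immune-activity factor), 20 miRNAs with one planted immune regulator,
# a 120-term GO universe (40 immune terms) and 68 immune signatures.

suppressPackageStartupMessages(library(mirimmune))

seed <- 1L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- cohort_config(seed = seed)
cohort <- generate_cohort(cfg)
cat(sprintf("cohort: %d genes x %d samples, %d miRNAs; planted regulator %s\n",
            nrow(cohort$genes), ncol(cohort$genes), nrow(cohort$mirnas),
            cohort$truth$planted_regulators))
cat(sprintf("model-implied planted-pair correlation rho = %.3f\n",
            cohort$truth$expected_rho))

universe <- generate_go_universe(n_terms = 120L, immune_fraction = 1 / 3,
                                 truth = cohort$truth, seed = seed + 1L)
cat(sprintf("GO universe: %d terms, %d immune by construction\n",
            nrow(universe$go_table),
            length(attr(universe$go_table, "immune_term_ids"))))

signatures <- generate_signature_collection(68L, cohort$truth,
                                            seed = seed + 2L)
cat(sprintf("immune signature collection: %d signatures\n",
            length(signatures)))

write_expression_tsv(cohort$genes, file.path(out, "genes.tsv"), seed = seed)
write_expression_tsv(cohort$mirnas, file.path(out, "mirnas.tsv"),
                     seed = seed)
write_results_table(universe$go_table, file.path(out, "go_terms.tsv"),
                    seed = seed + 1L)
write_gmt(universe$go_sets, file.path(out, "go_sets.gmt"))
write_gmt(signatures, file.path(out, "signatures.gmt"))
jsonlite::write_json(
  cohort$truth[c("planted_regulators", "immune_set_ids", "expected_rho",
                 "seed")],
  file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
cat("wrote cohort inputs under", out, "\n")
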