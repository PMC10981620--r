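#!/usr/bin/env Rscript
# ssGSEA scores for the 68 immune signatures per patient, then Spearman
# correlation of every miRNA with every signature score, summarising how
# consistently positive the screen hit's correlations are.

suppressPackageStartupMessages(library(mirimmune))

seed <- 1L
inp <- "results/data"
out <- "results/signatures"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

genes <- read_expression_tsv(file.path(inp, "genes.tsv"), "gene")
mirnas <- read_expression_tsv(file.path(inp, "mirnas.tsv"), "mirna")
signatures <- read_gmt(file.path(inp, "signatures.gmt"))
truth <- jsonlite::read_json(file.path(inp, "truth.json"),
                             simplifyVector = TRUE)

scores <- score_matrix(genes, signatures, alpha = 0.25)
scm <- correlate_signatures(mirnas, scores)

direction <- do.call(rbind, lapply(rownames(scm$rho), function(m) {
  d <- directionality_summary(scm, m)
  data.frame(mirna_id = m, fraction_positive = d$fraction_positive,
             mean_rho = d$mean_rho,
             n_significant_positive = d$n_significant_positive,
             stringsAsFactors = FALSE)
}))
direction <- direction[order(-direction$mean_rho), ]
cat("miRNAs by mean Spearman rho against the 68 immune signatures:\n")
print(utils::head(direction, 5), row.names = FALSE)
planted <- direction[direction$mirna_id == truth$planted_regulators, ]
cat(sprintf(
  "\nplanted regulator %s: %.0f%% of signature correlations positive, mean rho %.2f\n",
  planted$mirna_id, 100 * planted$fraction_positive, planted$mean_rho))

score_df <- data.frame(signature_id = rownames(scores$scores),
                       as.data.frame(scores$scores, check.names = FALSE),
                       check.names = FALSE, stringsAsFactors = FALSE)
write_results_table(score_df, file.path(out, "signature_scores.tsv"),
                    seed = seed)
rho_df <- data.frame(mirna_id = rownames(scm$rho),
                     as.data.frame(scm$rho, check.names = FALSE),
                     check.names = FALSE, stringsAsFactors = FALSE)
write_results_table(rho_df, file.path(out, "signature_rho.tsv"),
                    seed = seed)
write_results_table(direction, file.path(out, "directionality.tsv"),
                    seed = seed)
cat("wrote signature tables under", out, "\n")
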