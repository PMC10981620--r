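Package: mirimmune
Title: Screening miRNAs for Immune Regulation with Pre-Ranked GSEA and ssGSEA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A transcriptome-wide screen that prioritises microRNAs by their
    association with tumour immune activity. For each miRNA, genes are ranked
    by signed Pearson correlation with its expression across a tumour cohort;
    pre-ranked gene set enrichment analysis (weighted running-sum enrichment
    score with a gene-label permutation null, normalised enrichment scores and
    permutation-based FDR) is run over a Gene Ontology collection; GO terms are
    filtered to immunological ones by keyword, grouped into functional
    categories, and significant immune terms are counted per miRNA to rank
    candidate immune-regulator miRNAs. Single-sample GSEA scores immune gene
    signatures per patient for Spearman correlation with miRNA expression, and
    a synthetic tumour-cohort generator plants known regulator miRNAs through a
    latent immune-activity factor so every stage of the screen is testable
    against ground truth. A 2^-ddCt relative-quantitation helper supports qPCR
    validation of screen hits.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
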