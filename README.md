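# mirimmune

Tumours that exclude cytotoxic T cells respond poorly to immunotherapy,
and microRNAs — which repress many transcripts at once — are candidate
master regulators of the tumour immune microenvironment. `mirimmune`
implements a transcriptome-wide screen that prioritises miRNAs by how
broadly their expression associates with immune activity across a tumour
cohort (the analysis design that surfaced Let-7i as an immune-regulator
candidate in high-grade serous ovarian cancer), together with a synthetic
cohort generator that plants a known regulator so every stage can be
verified against ground truth.

## What it computes

For each miRNA $m$ and cohort expression matrices (genes × samples,
miRNAs × samples):

1. **Ranked gene list** — genes ordered by signed Pearson correlation
   $r_g = \mathrm{cor}(y_g, x_m)$ across patients.
2. **Pre-ranked GSEA** over a GO gene-set collection: running-sum
   enrichment score with hit increments $|r_i|^w / \sum_{hits}|r|^w$
   (default $w = 1$) and miss decrements $1/(N - N_h)$; gene-label
   permutation null (default 500 permutations, minimum set size 3),
   sign-sided nominal p with add-one correction, NES, and pooled-NES
   permutation FDR.
3. **Immune screen** — GO terms filtered by an editable immunological
   keyword vocabulary, assigned to 7 functional categories; significant
   immune terms (default $p < 0.05$) are counted per miRNA and miRNAs are
   ranked by that count. Rank 1 is the screen hit.
4. **ssGSEA signature analysis** — per-patient enrichment scores for 68
   immune signatures ($\sum_i [P^w_{in}(i) - P_{out}(i)]$ with rank
   weights $r^{0.25}$), then Spearman correlation of each miRNA with each
   signature score and a directionality summary (fraction of positive
   correlations).
5. **2^-ΔΔCt** relative quantitation for qPCR validation of hits.

The synthetic cohort couples planted miRNAs and immune genes through a
latent per-patient immune-activity factor, giving a closed-form planted
pairwise correlation $\rho = \gamma\beta / \sqrt{(\gamma^2+\sigma^2)
(\beta^2+\sigma^2)}$ (0.5 at defaults). See the methods vignette
(`vignettes/mirna-immune-screen.Rmd`) for the model, parameter rationale
and known limitations.

## Worked example

The `analysis/` scripts run the whole study on the default synthetic
cohort (200 patients, 5000 genes with a 400-gene immune compartment, 20
miRNAs with `mir-001` planted as the immune regulator, 120 GO terms of
which 40 immune, 68 immune signatures):

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_immune_screen.R
Rscript analysis/03_signature_correlation.R
Rscript analysis/04_relative_quantification.R
```

`02_immune_screen.R` prints:

```
keyword filter retained 40 of 120 GO terms

top of the miRNA ranking (significant immune terms, p < 0.05):
 rank mirna_id n_significant_total sum_min_log2p n_terms_tested
    1  mir-001                  40      69.61218             40
    2  mir-010                  38      62.60463             40
    3  mir-017                  37      59.53693             40
    4  mir-005                  27      56.72381             40
    5  mir-015                  25      55.40805             40

screen hit: mir-001 (planted regulator: mir-001) -> recovered
```

The planted regulator tops the ranking with all 40 immune terms
significant; `sum_min_log2p` (the per-category $-\log_2$ best p-values
used as the bubble-plot colour scale) breaks count ties. Background
miRNAs also count more terms than the nominal level would suggest —
immune genes are mutually correlated, which inflates permutation GSEA for
every ranking; the between-miRNA comparison is the screen's readout (see
the vignette). `03_signature_correlation.R` then reports:

```
planted regulator mir-001: 100% of signature correlations positive, mean rho 0.60
```

i.e. the hit shows a consistently positive association with all 68 immune
signatures, while non-planted miRNAs centre near zero mean correlation.
Each script writes its plot-ready tables (ranked miRNAs, bubble table,
per-term enrichment, signature score/correlation matrices) under
`results/`.

The same pipeline can be driven in one call with
`run_full_screen(screen_config(...))`, which writes every intermediate
artifact plus a manifest of seeds and MD5 checksums; two runs with one
seed are bit-identical.

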