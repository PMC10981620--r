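---
title: "Screening miRNAs for immune regulation: models, parameters and verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening miRNAs for immune regulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The screen

Tumours with few functional tumour-infiltrating lymphocytes respond poorly
to immunotherapy, and microRNAs are attractive candidate regulators of the
tumour immune microenvironment because a single miRNA represses many
transcripts at once. `mirimmune` implements a transcriptome-wide screen
that prioritises miRNAs by how broadly their expression associates with
immune activity across a tumour cohort:

1. For each miRNA, every gene is ranked by the signed Pearson correlation
   of its expression with the miRNA's expression across patients.
2. Pre-ranked GSEA is run over a Gene Ontology gene-set collection
   (weighted running-sum enrichment score, gene-label permutation null,
   NES, permutation FDR).
3. GO terms are filtered to immunological ones by keyword, assigned to
   seven functional categories, and the significant immune terms
   (`p < 0.05` by default) are counted per miRNA.
4. miRNAs are ranked by that count; rank 1 is the screen hit.
5. Independently, single-sample GSEA scores a collection of 68 immune
   signatures per patient, and each miRNA's Spearman correlation with the
   signature scores summarises the direction of its immune association.

Because the screen is a statistical pipeline over cohort data rather than
a wet-lab result, every stage is verified on a synthetic cohort with a
*planted* immune-regulator miRNA whose ground truth is known.

## The synthetic cohort model

`generate_cohort()` draws, for each patient $s$, a latent immune activity
$A_s \sim N(0, 1)$. A planted regulator miRNA $m$ and the members $g$ of
the immune gene compartment load on it:

$$x_{m,s} = \gamma A_s + \varepsilon, \qquad
  y_{g,s} = \beta A_s + \varepsilon, \qquad
  \varepsilon \sim N(0, \sigma^2),$$

while all background genes and miRNAs are i.i.d.
$N(0, \sigma^2 + \max(\gamma, \beta)^2)$ — variance-matched so planted
features cannot be found by variance alone. The implied Pearson
correlation between a planted miRNA and an immune gene is

$$\rho = \frac{\gamma\beta}{\sqrt{(\gamma^2+\sigma^2)(\beta^2+\sigma^2)}},$$

which is 0.5 at the defaults $\gamma = \beta = \sigma = 1$. A single
shared factor is deliberately the simplest structure that makes "many
immune GO terms enriched for one miRNA" true — exactly the pattern the
screen must detect.

Default shapes: 200 patients, 20 miRNAs with one planted regulator, and
5000 genes of which 40 blocks of 10 (400 genes, 8%) are immune. The 8%
immune share mirrors the immune fraction of a real GO universe (roughly
3.9k immunological terms in a 51k-term ontology); it matters because GSEA's
gene-label permutation null assumes the ranked universe is dominated by
exchangeable background genes — when the mutually correlated immune
compartment is made a large fraction of the universe, every permutation
subset picks up correlated genes and the null degrades for all miRNAs at
once. The GO universe default (120 terms, one third immune, per-term sets
of 5–25 genes) and the signature collection (68 signatures of 10–30 genes,
20% background contamination) are the conditions under which the screen's
recovery behaviour is tested; contamination acknowledges that curated
immune signatures are never purely tumour-immune genes.

What the generator does **not** emulate: count-like expression
distributions, batch effects, copy-number structure, miRNA-target
*repression* (planted correlations are positive; the screen itself is
sign-agnostic), correlation between distinct immune signatures beyond the
shared factor, and clinical sample filtering. Passing recovery tests on
this cohort therefore demonstrates that the pipeline's statistics behave
as designed, not that any particular real miRNA would be found.

## Pre-ranked GSEA

Walking the ranked list, set members increment the running sum by
$|r_i|^w / \sum_{\text{hits}} |r|^w$ and non-members decrement it by
$1/(N - N_h)$; the enrichment score is the signed maximal deviation from
zero. The weight exponent defaults to $w = 1$, the canonical weighted
scheme; $w = 0$ recovers the classic Kolmogorov–Smirnov statistic, and
both are tested against a brute-force walk.

The null is gene-label permutation — `n_permutations` (default 500, the
screen's standard setting) uniformly random subsets of the set's size.
Since the null depends only on the ranked scores and the set size, one
null sample is cached per size, which is what makes screening hundreds of
terms with hundreds of permutations cheap; the heavy loop is compiled.

Nominal p-values are sign-sided with add-one correction on both counts:
for a positive score, $p = (1 + \#\{ES^\ast \ge ES,\ ES^\ast \ge 0\}) /
(1 + \#\{ES^\ast \ge 0\})$. Restricting the denominator to the matching
sign keeps the p-value calibrated (empirical type-I error at the nominal
level under a global null — verified in the test suite); normalising the
count by all permutations instead would roughly double the type-I error.
NES divides the score by the mean |null ES| of matching sign for the
size class, and FDR follows the canonical pooled-NES procedure. With very
asymmetric nulls (almost all permutation scores on one side) the
minority-side NES and FDR estimates rest on few permutations and are
reported as computed; the screen's counting therefore defaults to the
nominal p-value, with `criterion = "fdr"` available as a switch.

Exact running-sum ties (possible with $w = 0$) are resolved to the
*earliest* extremum, with a $10^{-12}$ tolerance so the choice cannot be
flipped by floating-point accumulation order. Ranking ties between genes
are broken lexicographically by gene ID before the walk; both choices are
purely for determinism.

### A known limitation worth stating plainly

Gene-label permutation treats genes as exchangeable, but immune genes are
mutually correlated through the latent factor (as they are in real
tumours). Consequently *every* miRNA — planted or not — shows more
"significant" immune terms than $\alpha \times n_\text{terms}$: even a
null miRNA's small, random alignment with the latent factor shifts the
whole immune compartment coherently in its ranking. The screen still
recovers the planted regulator because its enrichment is far stronger and
more uniform across terms, but absolute counts should be read as
competitive scores, not calibrated discoveries. The test suite checks the
calibrated behaviour ($E[\text{count}] \approx \alpha \times n$) on a
cohort with no latent structure, and exchangeability (uniform rank-1
identity) on cohorts where the planted coupling is switched off.

## Single-sample GSEA

For one sample, genes are sorted by expression (ties by gene ID) and with
rank values $r_i = N - i + 1$ the signature score is
$\sum_i [P^w_{\text{in}}(i) - P_{\text{out}}(i)]$, where $P^w_{\text{in}}$
accumulates $r^\alpha$ over signature genes (normalised to 1) and
$P_{\text{out}}$ is the cumulative fraction of non-members. Only ranks
enter, so any strictly monotone transform of a sample's expression leaves
its scores unchanged — the defining invariance, asserted exactly in the
tests. The exponent defaults to $\alpha = 0.25$, the canonical ssGSEA
choice. Optional normalisation rescales the whole matrix by its global
range into $[0, 1]$, preserving between-signature comparability;
signature–miRNA correlation uses Spearman's rank coefficient and is
therefore identical on raw and normalised scores.

## Keyword filter and categories

A GO term is immunological if any vocabulary word occurs
case-insensitively as a substring of its name or description; the
vocabulary (20 words from "immun" to "myeloid") ships as an editable YAML
file (`inst/extdata/immune_keywords.yaml`) because no canonical word list
exists — everything downstream is parameterised by it. Retained terms are
assigned to all of seven categories whose own keyword lists match (GO is
not partitioned by theme, so multi-membership is expected); terms matching
none go to a residual "other immune" bin rather than being dropped. Two
category names follow the screen's published description directly (immune
response regulation, inflammatory response); the remaining five are
thematic stand-ins and fully overrideable.

The filter is monotone in the vocabulary (adding a word never removes a
term), and on synthetic GO universes — where immune names embed vocabulary
words and background names are generated provably free of them — the
filter recovers the constructed immune terms exactly.

## Relative quantitation

For qPCR validation of a screen hit, `relative_quantity()` implements
$2^{-\Delta\Delta C_t}$ with group aggregation by mean
$\Delta C_t = C_t^{\text{target}} - C_t^{\text{reference}}$ before
differencing (the standard convention); per-sample fold changes against
the control mean are also returned. Closed forms
($\Delta\Delta C_t = 0, -1, 3 \Rightarrow$ fold $1, 2, 0.125$) and the
reciprocity property are asserted exactly.

## Determinism and numerical conventions

- One master seed drives a run: stage seeds are derived by fixed offsets
  (cohort +1, GO universe +2, signatures +3, GSEA +4), and the permutation
  null for set size $k$ is seeded with `seed + k`, so identical-size sets
  share their cached null reproducibly.
- `run_full_screen()` writes every intermediate artifact and a manifest of
  MD5 checksums; two runs with one seed are bit-identical (asserted).
- Written tables render floats with 6 significant digits under a
  provenance comment (package version and seed); round-trips reproduce
  values to that precision.
- Genes with constant expression have no defined correlation; they are
  excluded per miRNA and reported, never silently dropped.
- Degenerate gene sets (empty overlap with the universe, or covering it
  entirely) are excluded and reported; set sizes below the minimum
  (default 3) likewise.

## Verification problem sizes

The test suite verifies the enrichment score against a brute-force walk on
1000 random instances ($N \le 50$, $|S| \le 10$, $w \in \{0,1\}$, agreement
to $10^{-9}$), the permutation null against exhaustive enumeration of all
$\binom{20}{3} = 1140$ subsets, p-value calibration over 2000 random
set-tests on unstructured rankings, and ssGSEA against its cumulative-sum
oracle with 100 exact monotone-invariance checks. Screen recovery runs 100
replicate cohorts at the default conditions with 200 permutations per
null (the permutation count is the one reduction from the screen default,
chosen to keep the replicate study compact) plus 200 decoupled
($\gamma = 0$) cohorts of 10 miRNAs for the exchangeability checks;
signature directionality uses 4 replicates of the 68-signature analysis,
judging null-miRNA behaviour by the mean over all non-planted miRNAs —
a single null miRNA's fraction of positive correlations is dominated by
its one random alignment with the shared latent factor, so only its
expectation is a stable property of the method.

## Limitations

- The pipeline takes expression matrices as given (no normalisation or
  transformation); the declared unit is metadata only.
- Counting significant terms per miRNA inherits GSEA's anti-conservative
  behaviour under inter-gene correlation (above); between-miRNA
  *comparison* is the screen's valid readout.
- The 68-signature collection is treated as an input GMT; the shipped
  generator produces a synthetic stand-in, not the published signature
  gene lists.
- No partial correlation or covariate adjustment (tumour purity, stage),
  no survival association, and no phenotype-permutation GSEA.
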