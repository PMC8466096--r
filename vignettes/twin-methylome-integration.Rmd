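---
title: "Methods: twin-discordant methylome-transcriptome integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: twin-discordant methylome-transcriptome integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinmeth)
```

## The design and its statistics

A monozygotic twin pair discordant for *KMT2A/AFF1* infant ALL provides two
matched controls for the affected child: her genetically identical healthy
twin, and her own remission sample. The package chains five statistical
stages on top of this design.

**Twin-contrast filter.** For each CpG the three β-values of the trio
(proband S1, twin S2, remission S3) are contrasted. The probe is retained
when |β_S1 − β_S2| ≥ `delta_min` and |β_S1 − β_S3| ≥ `delta_min` (default
0.30, inclusive) while |β_S2 − β_S3| ≤ `delta_max_healthy` (default 0.10,
inclusive). All deltas are signed proband-minus-healthy. The direction label
requires both proband contrasts to share a sign (hyper if both positive);
the inequalities alone do not force this, so probes passing the magnitudes
with opposite signs are retained but labelled `discordant` and excluded from
direction counts. Probes missing any of the three values are excluded rather
than imputed — three samples give no basis for imputation.

**Replication.** Independent diagnosis-remission pairs provide per-probe
paired differences d_i = β_diag,i − β_rem,i. The replication criterion is
effect size and direction: |d̄| strictly greater than `effect_min` (0.30)
with the same hyper/hypo direction as the twin contrast. The paired *t*
statistic t = d̄/(s_d/√n), df = n − 1, and its two-sided p-value are always
reported, and an optional `rep_alpha` cutoff can be switched on, but by
default no p-value threshold applies — with three pairs the t-test is a
descriptive companion to the effect-size rule, not the gatekeeper. The
degenerate case s_d = 0 with d̄ ≠ 0 (all pairs showing the identical shift)
is treated as maximally consistent: flagged, p reported as 0, effect
retained. The test is computed on all probes and then intersected with the
twin-retained set; this is equivalent to testing only the twin set but keeps
the reporting of both stages independent.

**Annotation.** Probes map to semicolon-joined gene/region annotations in
the Illumina 450K manifest dialect. "Promoter" is TSS1500 ∪ TSS200 (within
1500 bp or 200 bp upstream of a transcription start site). Because "gene
regions" can be counted as distinct gene symbols or distinct (gene, region)
pairs, both counts are emitted; the pipeline's `n_genes_annotated` uses
distinct symbols. Manifest positions are 1-based.

**Differential expression.** Counts are normalized by median-of-ratios size
factors (genes containing any zero excluded from the reference; the factor is
the plain median of count/geometric-mean ratios) and transformed to
log2(count/factor + 1). Per gene, the log2 fold change is the mean paired
difference of normalized values (diagnosis minus remission) and the p-value a
two-sided paired *t* with df = n − 1, BH-adjusted; significance is
P_FDR < 0.05. The DE stage is deliberately pluggable: `run_pipeline(de_table =
...)` accepts an externally produced table (gene, log2fc, p_fdr) verbatim, so
a count-model DE tool can be substituted without touching the integration
stages. The pseudocount of 1 biases |log2FC| downward for genes whose
shifted-side counts approach zero; this matters only for strongly
downregulated, lowly expressed genes and is the price of a defined value at
zero counts.

**Correlation signature.** For every candidate (probe, gene) — replicated
probe annotated to a DE-significant gene — the Pearson correlation between
the probe's β and the gene's normalized log2 expression is computed over the
samples with both assays (six, in the default design: three
diagnosis-remission pairs). Two-sided p-values use t = ρ√((n−2)/(1−ρ²)),
df = n − 2; BH adjustment runs across all tested candidates. With n = 6,
|ρ| ≥ 0.7 alone does not imply a small p-value, so a record passes only when
|ρ| ≥ `rho_min` **and** Pcorr ≤ `alpha` (each criterion can be toggled). A
signature gene needs ≥ `min_cpgs` (3) passing CpGs; its sign is `-` when all
passing correlations are negative, `+` when all positive, `mixed` otherwise.
The correction family for Pcorr is a design choice (BH across all tested
candidate pairs, α = 0.05), consistent with the BH control used for
expression.

**Structural QC.** Euclidean distances between methylation profiles (scaled
by √(P/P_shared) where probes are missing) feed complete-linkage
agglomerative clustering — the linkage is a configurable default chosen for
determinism, since distance heatmaps do not dictate one — and the
two-cluster cut is scored by purity against leukemic/non-leukemic labels. The
targeted PCA over the replicated probes is column-centered and unscaled, on
β-values directly (an M-value transform, log2(β/(1−β)) with β clipped to
[0.001, 0.999], is available as an option); component signs follow the fixed
convention that each component's largest-magnitude loading is positive, which
makes results fully deterministic. The parental check flags a signature CpG
as comparable when every parent lies within `tolerance` (default 0.10, the
same concordance bound as the twin filter's healthy contrast — no numeric
criterion is standard for this check) of the healthy adult reference mean.

## What the generator emulates

`simulate_dataset()` produces a complete study: the twin trio, both parents,
`n_pairs` (3) diagnosis-remission pairs with methylation and RNA, one
expression-only pair (which therefore contributes to DE, df = 3, but not to
correlation), and three reference profiles each of CD34+ progenitor and
CD19+ mature B cells.

* **Baselines** are a bimodal beta mixture (42% low, 42% high, 16%
  intermediate), matching the U-shape of real arrays; per-sample β is
  beta-distributed with precision `beta_precision` (300; sd ≈ 0.03 at
  β = 0.5) and clipped to [0.001, 0.999]. Noise is beta- rather than
  Gaussian-distributed to respect the [0, 1] support, and (mean, precision)
  parameterization keeps the two knobs interpretable.
* **Signature CpGs**: `n_signature_genes` (30) × `cpgs_per_signature_gene`
  (4) probes shifted by ±`planted_delta_beta` (0.45, within the 0.3–0.85
  range the twin filter targets) in diagnosis-condition samples only.
  Directions are planted as an exact quota — round(`hyper_fraction` × n)
  genes hypermethylated (0.855, i.e. 26 of 30) — rather than Bernoulli
  draws, so the recovered hypermethylated fraction estimates the parameter
  without binomial noise; all CpGs of a gene share its direction. About 65%
  of signature probes get promoter regions.
* **Cell-composition confounding**: `n_composition_probes` probes carry an
  offset (0.35–0.55, hyper quota 0.855) in all diagnosis-condition samples
  and in the reference cells (CD19+ at 0.6 scale, mimicking a distinct
  mature cell type). These probes pass the twin filter and replicate —
  exactly the confounding the reference-cell PCA is meant to expose — but
  are annotated to genes whose expression is methylation-independent and
  not differentially expressed, so the expression-integration stages purge
  them. Composition is modelled as a probe-level offset shared by
  blast-like samples, not as an explicit cell-mixture model, because the
  analysis itself handles composition only through reference-cell QC. The
  default count (60, against 120 signature CpGs) makes disease effects
  dominate the structural QC, the regime in which the first dendrogram
  split divides affected from healthy samples.
* **Expression**: negative-binomial counts with dispersion `nb_dispersion`
  (0.05) and base means spanning 10^0.5–10^3.5; planted genes sit above
  10^`planted_log10_mean_min` (1.5) so their fold change is identifiable
  above the count-noise floor. Signature genes follow a deterministic
  methylation→expression link: log2 mean offset = slope × (mean signature-CpG
  β − baseline), slope = ±`planted_abs_log2fc`/`planted_delta_beta`,
  negative for the (1 − `positive_correlation_gene_fraction`) majority and
  positive for the MACROD2-like exceptions, so realized log2FC and per-CpG
  correlation signs follow from one mechanism. Non-signature DE genes
  (`n_de_genes`, 150) get direct condition offsets so the DE stage has
  positives outside the signature.
* **Link-noise calibration.** `target_abs_rho` (0.9) sets the minimum
  coupling the planted signature must exhibit: Gaussian log2 noise of sd
  (1 − `target_abs_rho`) × `planted_abs_log2fc`/2 (0.3 log2 units at the
  defaults) is added to signature-gene expression. The planted coupling is
  kept near-deterministic — realized per-CpG |ρ| ≈ 0.99, comfortably at or
  above the target — deliberately. With four pairs the DE stage is a df-3
  paired *t* under BH correction across 2,000 genes, and planted |log2FC| = 6
  genes stay reliably significant only when the total per-sample expression
  noise is well under one log2 unit; a weaker planted coupling (realized
  |ρ| near 0.9, noise sd ≈ 1.4) would push a third of the true genes past
  the BH threshold at this sample size. The generator therefore treats the
  target as a floor, not an aim point; the |ρ| ≥ 0.7 selection operates with
  margin either way.
* **Missingness** (`missing_rate`, 0.2%) is completely at random; truth
  labels are written to `truth.json` so recovery tests never re-derive truth
  from simulation internals.

With a fixed `seed` the entire dataset is bit-reproducible (β is rounded to
six decimals so the plain-text round trip through `write_dataset()` /
`read_dataset()` is exact).

## What passing tests do and do not show

The generator's noise is exchangeable across probes and samples: it has no
batch or chip effects, no probe cross-reactivity or SNP-affected probes, no
age-related drift (in real data, adult CD19+ references separate from infant
samples partly by age), no QC-driven probe attrition from the 485k array,
and composition confounding collapses onto a single shared offset rather
than a mixture of cell-type profiles. Recovery results on synthetic data
therefore validate the pipeline's logic and calibration, not its robustness
to artefacts that real 450K/RNA-seq studies must additionally handle
upstream.

## Numerical conventions and degenerate inputs

* Twin-filter bounds are inclusive (≥ `delta_min`, ≤ `delta_max_healthy`);
  the replication effect bound is strict (> `effect_min`). Both mirror the
  "at least 30%" versus "|effect size| > 30%" phrasing of the criteria they
  implement and are configurable.
* Paired tests with zero spread: p = 0 when the common difference is nonzero
  (degenerate flag set), p = 1 when it is zero.
* Correlations with a constant vector are flagged degenerate and excluded
  from BH; |ρ| = 1 maps to p = 0.
* PCA on samples with no variance returns zero scores with a degenerate
  flag; all-equal distance matrices flag the clustering as a degenerate tie.
* Probes/genes are matched by case-sensitive exact symbol; multi-gene probes
  contribute one correlation record per gene.
* Internal interval arithmetic is not needed anywhere; manifest coordinates
  stay 1-based throughout.

## Problem sizes used by the test suite

Unit tests run on scaled-down datasets (2,000 probes, 300 genes, 8 signature
genes). The end-to-end recovery checks use the default study conditions —
20,000 probes, 30 signature genes × 4 CpGs, Δβ = 0.45, hyper quota 0.855,
|log2FC| = 6, target |ρ| = 0.9, 3 DNA+RNA pairs plus 1 expression-only pair —
over five seeds, and the null calibration uses twenty seeds with no planted
effects. Oracle-equivalence checks compare each statistical primitive against
brute-force reimplementations on 100 random instances. A full default-size
pipeline run takes about a second.

```{r example}
run <- run_pipeline(simulate_dataset(sim_config(seed = 1)))
run
```

## Known limitations

* The replication *t*-test with three pairs has df = 2; its p-values are
  reported but deliberately not decisive.
* With six correlation samples the Pcorr criterion is conservative; genes
  whose realized |ρ| sits between 0.7 and ~0.85 can pass the magnitude rule
  yet fail BH at α = 0.05.
* The DE stage's paired *t* on log2 normalized counts is a simple,
  transparent substitute for a count-model test; for real data the pluggable
  `de_table` interface is the recommended route.
* `n_twin_filtered` counts in the run report include direction-`discordant`
  probes only in the total, never in the hyper/hypo tallies.
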