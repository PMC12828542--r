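---
title: "Methods: integrating differential methylation and expression in a 2x2 design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrating differential methylation and expression in a 2x2 design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methexpr)
```

# The question and the design

Brown adipose tissue remodels its transcriptome massively when animals
move from thermoneutrality (30 °C) to cold (8 °C), and obesity blunts
that response. `methexpr` asks which of those expression changes travel
with DNA-methylation changes: it calls *differentially methylated and
expressed genes* (DMEGs) — genes that are differentially expressed in a
contrast **and** carry at least one nearby differentially methylated
CpG whose methylation level co-varies with the gene's expression across
samples.

The design is a 2×2 factorial: metabolic state (lean vs diet-induced
obese, DIO) × temperature (30 °C vs 8 °C), with around seven animals
per cell. Three contrasts are analysed throughout:

* `COLD_lean` — 8 °C vs 30 °C within lean animals,
* `COLD_DIO` — 8 °C vs 30 °C within DIO animals,
* `DeltaCOLD` — the interaction, i.e. the difference between the two
  cold responses.

# Expression model

Counts are pre-filtered by removing genes with a **total count sum
below 10**, normalised with median-of-ratios size factors, and fitted
per gene with a negative-binomial log-linear model

\[
\log \mu_{gj} = \log s_j + \beta_0 + \beta_s\,\mathrm{DIO}_j +
\beta_t\,\mathrm{cold}_j + \beta_{st}\,\mathrm{DIO}_j\mathrm{cold}_j ,
\]

treatment-coded with reference lean/30 °C. Then `COLD_lean` $=\beta_t$,
`COLD_DIO` $=\beta_t+\beta_{st}$ and `DeltaCOLD` $=\beta_{st}$, so the
identity `DeltaCOLD = COLD_DIO − COLD_lean` holds exactly by
construction (and is asserted in the tests). Per-coefficient Wald tests
are BH-adjusted across genes within each contrast; genes whose IRLS fit
does not converge are reported with `NA` statistics and excluded from
the FDR ranking.

**Dispersion.** Each gene's dispersion is estimated by method of
moments from the pooled within-cell variance of normalised counts and
shrunk 50/50 toward a fitted `a0 + a1/mean` mean–dispersion trend (a
robust two-pass least-squares fit with non-negative coefficients). This
is deliberately lighter than DESeq2's empirical-Bayes machinery — the
aim is a calibrated Wald test, not numerical replication of any
particular tool. The tests verify calibration directly: on null
synthetic data (2,000 genes, 7 samples per cell, 20 datasets) the
pooled rejection rate at p < 0.05 must fall in [3 %, 7 %], and fold
changes must correlate > 0.98 with an independent NB engine on the same
data.

**Stabilised expression.** PCA and the downstream correlations use
`log2(count/size factor + 1)`. A full variance-stabilising transform
would differ mainly at very low counts; since this representation only
feeds PCA and Pearson correlation (not the Wald tests), the simpler
transform is used and documented here as a deliberate divergence.

**Outlier flagging.** Samples are projected onto PC1–PC2 and the
distance of each sample to its design-cell centroid is converted to a
z-score against the pooled mean and SD of all within-cell distances; a
sample is flagged when z exceeds `k_sd` (default 3). The z-score form
(rather than flagging distances above `k_sd` SD outright) matters
because centroid distances have a positive mean; the raw rule would
flag ~15 % of perfectly homogeneous samples. Flagging is advisory —
the function reports, the analyst decides and re-runs; nothing is
dropped silently.

# Methylation model

Per-CpG calls arrive as Bismark-style cytosine reports (chrom,
position, strand, methylated, unmethylated). Reliability masking is
applied per sample and site: coverage below `min_cov = 5` reads,
coverage above the per-sample `0.999` quantile, positions in a supplied
SNP list (dropped for all samples), and sex chromosomes (`chrX`,
`chrY`, `X`, `Y` by default). A site is dropped outright when any
design cell retains fewer than two unmasked samples.

Testing uses **M-values** $M = \log_2\frac{\beta+\varepsilon}
{1-\beta+\varepsilon}$ with $\varepsilon = 0.01$, which are closer to
homoscedastic than betas; fold changes use **beta values**, as
$\mathrm{log2FC} = \log_2\frac{\bar\beta_{cold}+\varepsilon}
{\bar\beta_{warm}+\varepsilon}$. The same $\varepsilon$ guards every
ratio or logit that could be undefined. A DMP is retained iff
|log2FC| > 1 **and** p < 0.05; the joint gate is verified to be
stricter than either alone on null data.

* For `COLD_lean`/`COLD_DIO` the p-value is a two-sided Welch t on
  M-values between cold and warm samples of that state. Zero variance
  in both groups is reported as p = 1 with a `degenerate` flag rather
  than an error.
* For `DeltaCOLD` the p-value is the interaction-term t-test of an OLS
  model `M ~ state * temperature`, and the fold change is the
  ratio-of-ratios
  $\log_2\!\big[\tfrac{(\bar\beta_{DIO,8}+\varepsilon)/(\bar\beta_{DIO,30}+\varepsilon)}
  {(\bar\beta_{lean,8}+\varepsilon)/(\bar\beta_{lean,30}+\varepsilon)}\big]$,
  chosen so the methylation side mirrors the expression identity
  `DeltaCOLD = COLD_DIO − COLD_lean`.

The Welch/OLS choice (rather than a moderated-t with empirical-Bayes
variance shrinkage) is a documented substitute validated by the null
calibration above, not by numeric identity with any reference tool.

**Regions.** Promoters span 1,500 bp upstream to 500 bp downstream of
the TSS, strand-aware, clipped to the chromosome (an unclipped promoter
is 2,001 bp in 1-based inclusive coordinates). Coordinates are 1-based
inclusive internally (GTF convention); BED export converts to 0-based
half-open at the boundary. Retained DMPs are grouped per (gene,
context, contrast) into DMRs; the region significance is Fisher's
combination $-2\sum\log p \sim \chi^2_{2k}$. Only the *ranking* of
regions matters downstream (context assignment), which is why a simple
combination suffices. A site overlapping both the body of one gene and
the promoter of another — or of the same gene, since the downstream
promoter segment overlaps the 5' gene body — receives every
assignment; deduplication happens at DMEG assignment, not in the
interval index.

# DMEG integration

For each contrast, DEGs passing |log2FC| > 0.5 and FDR < 0.05 are
intersected with their DMRs. Every member DMP's M-values are correlated
(Pearson) with the gene's stabilised expression across the contrast's
samples — the state's own samples for the simple contrasts, all
samples for `DeltaCOLD` — using only unmasked calls (≥ 3 pairs
required). A DMP qualifies when |r| > 0.5 and its correlation p,
BH-adjusted within the gene's candidate-DMP set, is below 0.05; the
gene is emitted iff at least one DMP qualifies.

Whether the correlation p should survive adjustment or be used raw is
genuinely open; adjusting within the gene keeps genes independent of
each other and is the more conservative default, and
`adjusted_correlation_p = FALSE` switches to raw p.

Deterministic tie-breaks: the assigned context is the region with the
smaller combined p, exact ties going to the promoter; the best DMP
within that context is the qualifying DMP with the smallest correlation
p, ties broken by larger |r|, then smaller genomic position. The
four-way category is the sign pair (methylation change, expression
change): `hypo_up`, `hypo_down`, `hyper_up`, `hyper_down`. Every
emitted record satisfies all six gates simultaneously, and the four
categories partition the set — both are asserted record-by-record in
the tests.

# Comparative layer

`classify_overlap()` partitions the union of two directed significant
sets into `similar_up`, `similar_down`, `contrary`, `unique_A`,
`unique_B` — mutually exclusive and exhaustive by construction.
`crossref_regulators()` reports, per regulator symbol, the contrasts
where it is a DEG, whether any retained DMP lies in its regions and
whether it meets full DMEG criteria (`is_dmeg ⇒ has_dmp` is an
invariant). `celltype_overlap()` reports, per cell type, the share of
its marker genes that are DMEGs; the denominator is genuinely ambiguous
in this kind of summary, so marker-set size is the default and
`denominator = "dmegs"` exposes the alternative.

**Printed percentages.** Reported ratios are rounded to an integer
unless the value lies within 0.05 points of a half-integer — where
integer rounding is unstable — in which case one decimal is kept. This
single rule reproduces mixed-precision figures such as 1,524/7,089 →
"21.5" next to 1,001/5,249 → "19".

# Motif enrichment

Promoter-context DMEGs contribute the ±20 nt window around their best
DMP (41 bp unclipped; clipped windows are flagged). The background is
5,000 windows of identical length, each drawn by picking a promoter
uniformly among those long enough and a start uniformly within it —
the sampler records the promoter index so uniformity is testable.
PWMs are probability matrices with a 0.01 pseudocount per cell;
scanning scores every offset on both strands with log-odds against a
uniform 0.25 background, `N` bases contributing zero, and counts an
offset as a match at ≥ 80 % of the PWM's **maximum attainable** score
(the relative-score convention; note this differs from conventions
based on the score *range*). Enrichment per motif compares foreground
and background per-window counts with a quasipoisson GLM Wald test
(two-sided, direction from the sign), BH across motifs; a degenerate
background falls back to an exact Poisson rate test, flagged as such.
The DIO-vs-lean comparison is a one-sided upper-tail hypergeometric
test. Null calibration of the rate comparison is tested (p < 0.05
fraction within a [0.5 %, 10 %] band under resampled nulls), and the
scanner and hypergeometric tail are checked against brute-force
enumeration.

# The synthetic-data generator

The generator emulates exactly the structure the analysis assumes, with
defaults chosen as the study conditions: 2,000 genes on four autosomes
plus a synthetic `chrX` (5 % of genes, to exercise exclusion), 7
samples per design cell, NB counts with dispersion 0.1 around
log-uniform base means in [20, 2000], CpG coverage Poisson with mean
30, 2,000 background CpGs (5 % at low coverage, 5 % on chrX), 50
forced low-count genes, 10 % planted DMEGs and 15 % expression-only
genes; planted effects |expression log2FC| = 1.5 and |methylation
log2FC| = 1.5 with a target correlation magnitude around 0.8. Planted
DMEGs follow one of three profiles — `shared` (equal cold response in
both states), `lean_only`, `dio_only` — in proportions 40/30/30, which
yields both overlapping and condition-specific DMEGs for the
comparative layer.

**Coupling model.** For a planted gene, one latent standard-normal
deviation $z_{gj}$ per sample is shared between the two layers: the
count mean is multiplied by $2^{\tau z_{gj}}$ ($\tau = 0.4$) and the
methylation logit is shifted by $\lambda\,\mathrm{sign}\, z_{gj}$
($\lambda = 0.6$), with sign = (methylation sign) × (expression sign).
The achieved correlation has two sources: the between-group separation
(both layers move with temperature) and this shared within-group
deviation. The scaling → |r| mapping was established empirically: with
$\lambda$ around 1.2 the logit noise dominates the Welch test's
within-group variance and the realised group-mean fold change, costing
sensitivity, while $\lambda = 0.6$ leaves the planted DMPs detectable
and the planted correlations comfortably above the 0.5 gate (the tests
require median planted |r| > 0.5 at 50 samples per cell and ≥ 95 %
sign agreement). Methylation levels realise a planted fold change f by
placing group means at $\beta_{low} = 0.2$ and
$\beta_{high} = (\beta_{low}+\varepsilon)2^{f}-\varepsilon$; background
CpGs get site-specific base levels from a mildly bimodal beta
distribution plus logit-normal per-sample jitter (SD 0.3).

**What it does not emulate.** Read-level data (no FASTQ, no
bisulfite-conversion error model), real genome sequence (motif windows
come from uniform-random DNA), linkage between neighbouring CpGs,
realistic RRBS fragment clustering, GC/length biases, batch effects,
or annotation complexity (one transcript per gene, non-overlapping).
Passing the recovery tests therefore demonstrates that the pipeline's
logic and thresholds behave as specified under the assumed statistical
model — not that the pipeline is robust to artefacts real RRBS/RNA-seq
data can carry.

# Problem sizes and seeds

All tests run on fixed seeds. The shared fixture uses 400 genes; the
calibration and recovery checks use 20 datasets of 2,000 genes at 7
samples per cell; oracle-equivalence checks use 1,000 randomised
instances per primitive; large-sample generator checks use 50 samples
per cell. These sizes keep the full suite in the low minutes on one
CPU while leaving the binomial/NB sampling noise small relative to the
tested bands. The acceptance script (`scripts/acceptance.R`) re-derives
every headline quantity from scratch at the same sizes, seeded from its
`--seed` argument.

# Known limitations

* The NB Wald engine targets calibration, not equivalence with any
  specific reference implementation; at very small per-cell counts the
  normal approximation of the Wald statistic becomes liberal.
* The Welch-t DMP test ignores the mean–variance relationship a
  moderated test would exploit; power at coverage ≪ 30 is accordingly
  lower.
* Fisher's combination treats member DMPs as independent; adjacent
  CpGs in real data are correlated, so `region_p` is an optimistic
  ranking score, used only for context assignment.
* Correlation across ~14–28 samples cannot distinguish causal
  direction; a DMEG is an association call, nothing more.
* The motif stage assumes a uniform background base composition; on a
  real genome a GC-matched background would be preferable.
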