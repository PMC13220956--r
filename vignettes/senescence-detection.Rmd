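---
title: "Detecting senescent cells in bulk and single-cell transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting senescent cells in bulk and single-cell transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(senescreen)
```

Cellular senescence (CS) is a stable proliferation arrest accompanied by a
characteristic secretory programme (the senescence-associated secretory
phenotype, SASP), extracellular-matrix (ECM) remodelling, and induction of
cyclin-dependent kinase inhibitors (CDKi; the INK4 family CDKN2A/B/C/D and
the CIP/KIP family CDKN1A/B/C). No single transcript is a reliable
senescence marker, so practical detection rests on panels of markers that
behave consistently across independent senescence models, and on combining
several orthogonal criteria when classifying individual cells. `senescreen`
implements that strategy end to end and ships seeded simulators for every
input, so each stage can be validated against planted ground truth.

## Moderated differential expression

Per-gene two-group comparisons on log2 expression use the standard
empirical-Bayes moderated t. For gene $g$ with pooled residual variance
$s_g^2$ on $d$ degrees of freedom, the marginal distribution of the
$\log s_g^2$ is used to estimate a scaled inverse-chi-square prior
($d_0$, $s_0^2$) by method of moments; the posterior variance
$\tilde s_g^2 = (d_0 s_0^2 + d\, s_g^2)/(d_0 + d)$ replaces $s_g^2$ in the
t statistic, which is referred to a t distribution on $d + d_0$ degrees of
freedom. Two limits are exposed for verification: `prior_df = 0` recovers
the ordinary pooled-variance t exactly, and `prior_df = Inf` shares a single
variance across genes so that ranking by $|t|$ equals ranking by
$|\log_2 \mathrm{FC}|$. The test suite additionally cross-checks the full
fit against the independent implementation in `limma` to $10^{-8}$. When
the moment estimator finds no excess dispersion, the prior degrees of
freedom are infinite and the common variance is the arithmetic mean of the
sample variances (the maximum-likelihood choice in that limit, and the
convention of the reference implementation).

Genes with zero residual variance are flagged (`zero_variance`), never
silently dropped, so gene universes stay aligned across datasets for the
consensus stage; a fully constant matrix yields p = 1 everywhere with a
warning. P values are two-sided throughout. Multiple testing uses
Benjamini–Hochberg (`adjust_bh()`, a validated wrapper over the base R
step-up implementation), and a differentially expressed gene (DEG) requires
adjusted p < 0.05 **and** |log2 FC| > 0.5, both strict inequalities.

## Consensus and common markers

A gene enters the consensus panel when it is a same-direction DEG in at
least `min_datasets` (default 3) of the supplied datasets. Because
"consistent deregulation" leaves conflict handling open, the default is the
conservative exclusive rule — any opposite-direction DEG call vetoes the
gene; a majority variant (`exclusive = FALSE`) is provided. The short
"common" lists used by the single-cell caller apply linear fold-change
rules: common up markers need FC > 1.7 in at least 4 datasets, common down
markers FC < 0.5 in *all* datasets; both are ranked by mean log2 FC across
datasets (unweighted — the ranking statistic is not otherwise specified)
and truncated to 8 and 7 genes. Region scoring uses all consensus up
markers plus the 133 most-downregulated consensus markers.

## The four-criterion single-cell caller

`score_cells()` flags a cell senescent when all of the following hold:

1. cumulative expression of the up-marker panel exceeds `up_sum_min`
   (default 1000, in matrix units);
2. summed down-marker expression is at most `down_tolerance` (default 0 —
   strict absence; the tolerance exists because dropout in sparse data may
   warrant a small allowance);
3. the cell's summed SASP expression is in the top `top_quantile`
   (default 15%) of cells;
4. the cell's summed ECM expression is in the top 15%;

plus CDKi positivity: at least `min_cdki_expressed` (default 1) CDKi genes
detected. The up-panel defaults to the 8-gene common list
(`up_panel = "common_up"`); the full consensus list is a configuration
switch, since the wording "upregulated CS genes" is compatible with either.
The threshold 1000 is kept in the units of the input matrix and is
deliberately configurable: the normalisation of the matrix it was
calibrated on is not recorded, so `up_sum_distribution()` reports the
per-cell up-sum quantiles to support recalibration on other normalisations.

The top-15% rule takes the k-th largest total with
$k = \lceil q \cdot n \rceil$ as the boundary and admits ties inclusively,
so slightly more than 15% of cells can pass. Raising `up_sum_min` can only
shrink the called set (monotonicity), which the tests assert.

Senescence escape is assessed on the base set of p21-positive
(CDKN1A > 0) cells with SASP totals in the top quantile — the same
high-SASP rule as the main caller, an interpretation made for internal
consistency. Escape cells are base cells that also express MKI67; the
report gives the MKI67+ fraction of the base set and, among escape cells,
the fractions expressing PCNA and the MCM complex. "MCM complex
expression" defaults to at least one of MCM2–7 detected (`mcm_rule =
"any"`); requiring all six is available.

## Region scoring

For each gene, expression is min–max scaled to [0, 1] **across regions**
(this orientation is forced by the goal of ranking regions); down-marker
contributions are multiplied by −1 and contributions are summed per region.
A gene constant across regions has an undefined scaling and is assigned
contribution 0. Scores are bounded by the panel sizes, invariant to
per-gene positive rescaling (so FPKM normalisation constants do not
matter), and exactly antisymmetric under exchanging the up and down sets.
When multiple samples exist per region they are aggregated first
(`aggregate_regions()`, arithmetic mean by default, median optionally);
mean is an assumption, as the aggregation used upstream of the published
regional profiles is not recorded.

## Ligand–receptor permutation test

Interaction strength between a sender and a receiver cluster is the mean of
the ligand's and the receptor's min–max scaled cluster-mean expression
(scaled per gene across clusters), the scaled-mean convention of
CellPhoneDB-style tools; receptor complexes take the minimum over
components, and the score is 0 whenever either side's raw cluster mean is
0. Significance comes from globally shuffling the cell-to-cluster
assignment (preserving cluster sizes) and computing
$p = (r + 1)/(B + 1)$ with $r$ the number of permuted scores at or above
the observed one — the standard floor that avoids zero p values. Clusters
with fewer than 3 cells are excluded, not imputed.

One property of this score matters for calibration: it is bounded at 1, and
an observed score at the bound has null tail probability of about
$1/K^2$ for $K$ clusters (the chance that a permuted sender is the
ligand's argmax cluster while the receiver is the receptor's argmax). With
few clusters, p values are therefore bounded away from 0 regardless of
effect size; with 3 clusters nothing can fall below ≈ 0.11. The suite's
null-calibration check consequently uses an 8-cluster design, where the
atom (1/64) is far below the resolution of the Kolmogorov–Smirnov test,
and the planted-signal check uses 6 clusters so that the attainable
p ≈ 0.03 clears 0.05. Users testing communication between a handful of
clusters should be aware of this floor.

## Proteogenomic concordance and overlap

Per-gene mRNA–protein concordance uses average-rank Spearman correlation on
pairwise-complete samples (minimum 4 pairs, a package policy; the source
convention is unrecorded) with two-sided p from the t approximation.
Set-vs-background comparisons report medians and a Mann–Whitney U test.
The "fraction of genes with significant correlation" intentionally uses
raw p < 0.05, not adjusted p, matching the convention of the analysis it
reproduces. Phosphosite prevalence counts non-missing normalized
intensities among tumor samples (detection without imputation), with a
Welch t test against normal samples when at least two intensities per
class exist.

Proteome/marker-panel overlap reports, per panel set, the fractions of
member genes up, down, detected-but-unchanged and not detected. Because
pie-chart denominators can be read as either detected-only or all members,
both bases are emitted: `frac_*` columns over all members (summing to 1
with `frac_missing`) and `det_frac_*` columns over detected members.

## The synthetic-data generators

The generators define the conditions under which the pipeline is validated;
their defaults were chosen once to mirror the study design the pipeline
addresses and are not tuning knobs.

* **Bulk panel** (`simulate_bulk_panel()`): six microarray-like datasets,
  Gaussian on the log2 scale, with per-dataset replicate counts
  `c(4, 3, 2, 5, 2, 3)` echoing the heterogeneous replicate structure of
  real senescence series; 128 planted up and 461 planted down markers
  carrying a 2 log2FC effect in 4 of 6 datasets over noise SD 0.5. A core
  subset (the first 8 up / 7 down markers) carries a 1.5× effect in every
  dataset, emulating universal common markers whose fold changes replicate
  across all datasets — this makes the downstream common-marker selection
  land on a knowable set, so the single-cell simulation can boost exactly
  the genes a derived panel will contain.
* **Single cell** (`simulate_single_cell()`): negative-binomial counts
  (dispersion 2) thinned by Bernoulli dropout (rate 0.3), 5000 cells ×
  1500 genes at a mean library size of 5000, 12 clusters, 2.5% planted
  senescent cells — the prevalence the caller was designed around — and a
  small escape subpopulation. Planted senescent cells are guaranteed to
  pass all four criteria *by construction*, not just with high
  probability: down-markers and proliferation machinery are hard zeros
  (absence of expression is modelled as zeros, consistent with the
  caller's zero-tolerance default), CDKN1A is floored at 1, and up/SASP/ECM
  sums are deterministically topped up where sampling noise would leave
  them short. The SASP/ECM top-up raises deficient planted cells exactly
  to the pre-existing top-quantile boundary value; since no cell is raised
  *above* that value, the boundary itself cannot move, which makes the
  guarantee exact. Planted escape cells are CDKN1A+/high-SASP/MKI67+/
  PCNA+/MCM+ and retain down-marker expression, so they can never be
  called senescent.
* **Regions** (`simulate_region_matrix()`): log-normal FPKM with one
  region carrying 3× up-marker and 0.25× down-marker expression over 20%
  log-normal noise.
* **Paired omics** (`simulate_paired_omics()`): a bivariate Gaussian
  copula per gene with Pearson parameter $r = 2\sin(\pi\rho/6)$, so the
  *population Spearman* correlation equals the configured target; 99
  shared samples by default.

What the generators deliberately do **not** emulate: pathway-level
co-regulation, copy-number structure, batch effects, platform-specific
probe behaviour, compositional library-size artefacts, or any tumor
biology beyond the statistical structure the pipeline's criteria actually
read. Passing tests therefore demonstrate that the implementation computes
its criteria correctly and recovers structure of the stated kind and
magnitude — not that the thresholds themselves are optimal for any
particular real dataset.

## Numerical choices and degenerate inputs

* Strict inequalities at every published threshold (p < .05, |log2FC| >
  0.5, FC > 1.7, FC < 0.5, up-sum > 1000, |log2FC| > 1 for the pathway
  export).
* Zero-variance genes: flagged, p = 1 when the fold change is also 0.
* Constant genes in region scoring and in cluster-mean scaling: contribution
  or scaled value 0.
* Permutation p values: floored at $1/(B+1)$, never 0; seeded and
  deterministic.
* Significance stars: `*` for .01 ≤ p < .05, `**` for .001 ≤ p < .01,
  `***` for .0001 ≤ p < .001, `****` for p < .0001, `ns` at or above .05.
* Ties: quantile criteria admit ties inclusively; Mann–Whitney uses the
  tie-corrected normal approximation for large samples.
* Seeds are explicit arguments everywhere; no generator touches the global
  RNG state (`withr::with_seed`).

## Problem sizes used by the test suite

The suite validates recovery at 20 simulation seeds for the consensus
(6 × 2000-gene datasets) and single-cell (5000 cells × 1500 genes)
stages, 100 seeds for region identification, 1000 permutations for the
ligand–receptor calibration (200 null pairs, 8 clusters), and 600 genes ×
99 samples for the null-concordance calibration — sizes chosen so the
whole suite completes in about a minute while keeping the binomial noise
of each estimated rate well inside its acceptance margin.

## Known limitations

* The caller takes cluster labels as given; no clustering, embedding or
  cell-type annotation is performed.
* The up-sum threshold of 1000 is normalisation-dependent; recalibrate via
  `up_sum_distribution()` for matrices on other scales.
* No curated ligand–receptor database is bundled; users supply pair lists.
* `fit_moderated()` supports exactly two groups with no covariates — the
  design it is used for throughout — and does no count-based (voom-style)
  weighting.
* Probe-to-gene harmonisation across microarray platforms is the caller's
  responsibility; one row per gene symbol is assumed.
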