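# senescreen

Detection of cellular senescence in transcriptomic data: consensus marker
derivation across bulk datasets, a four-criterion senescent-cell caller for
single-cell matrices with a senescence-escape detector, anatomic-region
senescence scoring, a permutation test for ligand–receptor communication
between cell clusters, and mRNA–protein concordance / proteome-overlap
summaries. Every input can be simulated with planted ground truth, so the
whole pipeline is testable offline.

The package is for computational biologists who need a reproducible,
threshold-explicit implementation of marker-panel senescence scoring — for
example in tumor single-cell atlases, where senescent cells are rare
(a few percent) and no single marker is reliable.

## The statistics at the core

**Moderated differential expression.** Per-gene two-group tests on log2
expression with empirical-Bayes variance moderation: the prior
(d₀, s₀²) is estimated by method of moments from the marginal
distribution of log sample variances, each gene's variance is shrunk to
s̃²ᵍ = (d₀s₀² + d·s²ᵍ)/(d₀ + d), and the moderated t is referred to a t
distribution on d + d₀ degrees of freedom. DEGs require BH-adjusted
p < .05 and |log2FC| > 0.5 (strict).

**Consensus markers.** A gene is a consensus marker when it is a
same-direction DEG in ≥ 3 datasets and an opposite-direction DEG in none.
Common (core) marker lists additionally require linear FC > 1.7 in ≥ 4
datasets (up, top 8 by mean log2FC) or FC < 0.5 in all datasets (down,
top 7).

**Four-criterion cell calling.** A cell is senescent when its cumulative
up-marker expression exceeds 1000 (matrix units, configurable), its
down-marker sum is 0, its SASP and ECM totals are both in the top 15% of
cells, and it expresses at least one CDK inhibitor
(CDKN2A/B/C/D, CDKN1A/B/C). Escape cells are p21⁺/high-SASP cells that
also express MKI67, with PCNA and MCM2–7 co-expression reported.

**Region score.** Per gene, expression is min–max scaled to 0–1 across
regions; down-marker contributions are negated; the per-region sum ranks
regions by senescence-marker enrichment.

**Ligand–receptor test.** Interaction strength = mean of the ligand's and
receptor's min–max scaled cluster-mean expression; null from globally
shuffled cluster labels; p = (r+1)/(n_perm+1).

See `vignettes/senescence-detection.Rmd` for assumptions, parameter
meanings and numerical edge-case policy.

## Worked example

Simulate six senescent-vs-proliferating bulk datasets, derive a marker
panel, and call senescent cells in a simulated 5000-cell matrix:

```r
library(senescreen)

sim <- simulate_bulk_panel(bulk_panel_config(seed = 1))
tables <- lapply(sim$datasets, \(d) call_degs(fit_moderated(d$matrix, d$groups)))
panel <- derive_marker_panel(tables,
                             sasp = sprintf("SASP%03d", 1:50),
                             ecm  = sprintf("ECM%03d", 1:40))
panel
#> <marker_panel>
#>   consensus_up    124 genes: UPM001, UPM002, UPM003, UPM004, ...
#>   consensus_down  454 genes: DNM001, DNM002, DNM003, DNM004, ...
#>   common_up         8 genes: UPM007, UPM005, UPM002, UPM004, ...
#>   common_down       7 genes: DNM005, DNM007, DNM001, DNM002, ...
#>   ...
```

Of the 128 + 461 planted markers, 124 + 454 are recovered with zero false
inclusions. Calling cells with the derived panel:

```r
sc <- simulate_single_cell(single_cell_config(seed = 1), synthetic_marker_panel())
calls <- score_cells(sc$counts, panel, clusters = sc$clusters)
glance(calls)
#> # A tibble: 1 × 8
#>   n_cells n_senescent frac_senescent  n_c1  n_c2  n_c3  n_c4  n_c5
#> 1    5000         125          0.025   125   126   761   763  4955

detect_escape(sc$counts, panel, clusters = sc$clusters)
#> <escape_report>
#>   p21+/high-SASP cells: 449; escape (MKI67+): 253 (56.3%)
#>   escape cells PCNA+: 75.9%; MCM complex+: 100.0%
```

All 125 planted senescent cells (2.5% of 5000) are recovered; the
per-criterion columns show how each filter narrows the candidate set
(761/763 cells pass the SASP/ECM top-15% criteria, 125 survive the
conjunction). `autoplot(calls)` shows the up-sum distribution against the
1000 threshold; `summarize_clusters(calls)` gives the cluster composition
of the called cells.

Region scoring with the derived panel:

```r
reg <- simulate_region_matrix(n_regions = 5, panel = panel, seed = 2)
score_regions(reg$fpkm, panel$consensus_up, panel$consensus_down)
#> # A tibble: 5 × 3
#>   region score n_genes_scored
#> 1 R05     124             578
#> 2 R03    -338.            578
#> ...
```

The planted region (R05) ranks first by a wide margin.

A full synthetic run of every stage, with all artifacts written to disk
and a run record capturing thresholds, seed and timings:

```r
res <- run_pipeline(pipeline_config(out_dir = "run1", seed = 1))
```

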