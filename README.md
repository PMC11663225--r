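# switchsig

Melanoma cells respond to TGFB1 with a phenotype switch toward an invasive,
AXL-high state — unless the MAPK pathway is blocked. Under combined TGFB1 +
MEK-inhibitor (MEKi) treatment the very same ligand instead induces
apoptosis, driven by a distinctive gene program that neither single treatment
activates. `switchsig` is an R package for analysts working with such
treatment-series designs: it implements the full computational route from

* **bulk RNA-seq counts** (DMSO / TGFB1 / MEKi / TGFB1+MEKi, per cell line),
* **SMAD4 CUT&RUN peak intervals** (two antibody replicates per condition),
* **curated gene-set universes** (GMT), and
* **MTT dose–response viability series** (CSV)

to a context-specific apoptosis gene signature, program-level enrichment
statistics, per-cell module scores, and a MEKi-sensitivity classification.
A seeded synthetic-data generator with known ground truth stands in for
deposited sequencing data, so the whole pipeline is testable offline.

## The models at the core

* **Differential expression.** Per-gene negative binomial model,
  `var = mu + alpha * mu^2`, median-of-ratios size factors, method-of-moments
  dispersions shrunk 50/50 toward a fitted `a0 + a1/mu` trend, and a Wald
  test on the log2 fold change of each treatment vs DMSO within a cell line
  (Fisher scoring, vectorised across genes), BH-adjusted.
* **Program enrichment.** Weighted Kolmogorov–Smirnov running-sum enrichment
  score on log2FC-ranked significant genes (weight p = 1), with gene-label
  permutation p-values and sign-matched NES.
* **Signature assembly.** Row-z-score clustering (Euclidean, complete
  linkage, fixed-k dendrogram cuts) selects double-treatment-high gene
  groups per cell line; consensus CUT&RUN peaks (base-pair intersection of
  antibody replicates) are mapped to genes through GREAT-style
  basal-plus-extension regulatory domains (TSS −5 kb/+1 kb, capped
  extension); a four-set Venn partition over {line-A DEGs, line-B DEGs,
  double-treatment-unique peak genes, pro-apoptotic universe} yields the
  signature as the union of four exclusive Venn regions, provenance-tagged.
* **Module scores.** Mean expression of signature genes minus mean of
  expression-bin-matched control genes (24 bins, 100 controls/gene), per cell.
* **Dose–response.** Four-parameter logistic
  `r = bottom + (top − bottom)/(1 + 10^(hill·(log10 d − log10 IC50)))`
  least-squares fit with restarts, flat-curve detection (undefined IC50), a
  2000 pM sensitivity threshold, and a rank-extremes (bottom-20 / top-20 +
  undefined) grouping.

## Worked example

```r
library(switchsig)

report <- run_pipeline(pipeline_config(seed = 1))
report$truth_recovery
#> $switch_sensitivity
#> [1] 1
#> $null_contamination
#> [1] 0
```

Every implanted "switch" gene (up-regulated only under the double treatment,
bound by SMAD4 only in that condition, member of the pro-apoptotic universe)
is recovered by the assembled signature, with no null-gene contamination.
The invasive program is depleted in the double-treatment ranking:

```r
report$gsea$TGFB1_MEKI[, c("set", "es", "nes", "pvalue")]
#>                set         es       nes pvalue
#> 1 invasive_program -0.9322034 -5.387313  0.001
#> 2     mitf_program -0.7111111 -1.191290  0.221
```

and the double-treatment signature's module score peaks in the NCSC-like
cell state (mean 0.75 vs ≈ −0.22 in the other three states), while the
dose–response stage classifies the three fixture lines as expected:

```r
unlist(report$dose_response$labels)
#>      M_SENS       M_RES      M_FLAT
#> "sensitive" "resistant" "resistant"
```

The signature-assembly worked example reproduces the published set algebra on
the four subset lists of interest (sizes 2, 8, 21, 11; bundled as a synthetic
stand-in because the full lists are only printed as figure graphics):

```r
apoptosis_signature_example()
#> gene_signature 'context_specific_apoptosis': 42 genes
#>  GADD45B, UBE4B, BCL2L11, SYNB01, SYNB02, SYNB03, SYNB04, SYNB05, SYNB06, SYNB07, ...
```

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from scratch —
the full synthetic-fixture pipeline (DE, clustering, signatures, GSEA, peak
consensus and association, Venn assembly, module scoring, motif enrichment,
4PL classification) plus the 42-gene worked example — under the given seed,
and writes the requested JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

A full machine-readable run report (parameters, per-stage summaries,
signature provenance, truth-recovery metrics) is written alongside as
`run_report.json`.

## Documentation

The methods vignette (`vignettes/switchsig-methods.Rmd`) describes the
models and their assumptions, all tunable parameters with defaults and units,
what the synthetic generator does and does not emulate, and the design
decisions taken where the re-implemented analysis left choices open.
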