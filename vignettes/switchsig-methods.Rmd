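---
title: "Methods: models, parameters and design choices in switchsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in switchsig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(switchsig)
```

# The biological question

In melanoma, TGFB1 signalling normally drives a phenotype switch toward an
invasive, AXL-high state. When the MAPK pathway is blocked with a MEK
inhibitor (MEKi), the same ligand instead triggers apoptosis: the
double-treated cells up-regulate a distinctive gene program that neither
single treatment induces. `switchsig` implements the computational route from
(i) treatment-series bulk RNA-seq counts, (ii) SMAD4 CUT&RUN binding
intervals, and (iii) curated gene-set universes to a context-specific
apoptosis signature, program-level enrichment, cell-state module scores, and
a MEKi-sensitivity classification — plus a seeded synthetic-data generator so
that every stage is testable without any external download.

# Negative binomial differential expression

Counts for gene $g$ in sample $j$ are modelled as
$y_{gj} \sim \mathrm{NB}(\mu_{gj},\, \alpha_g)$ with
$\mu_{gj} = s_j q_{gc(j)}$ and variance $\mu + \alpha_g \mu^2$; $s_j$ is a
median-of-ratios size factor (geometric-mean reference over genes nonzero in
all samples, total-count fallback with a warning otherwise), and $c(j)$ the
condition of sample $j$.

* **Dispersions.** Per-gene method-of-moments estimates
  $\hat\alpha_g = \max\{0, (\hat v - \hat\mu)/\hat\mu^2\}$ pooled across
  condition groups (df-weighted), then shrunk toward a fitted
  mean–dispersion trend $\alpha(\mu) = a_0 + a_1/\mu$ by a 50/50 weighted
  average (`shrink_weight = 0.5`) and floored at $10^{-8}$. The trend is fit
  by least squares on genes with positive raw estimates only — fitting on all
  genes would drag the trend toward the zero-truncated mass. By default
  `de_test()` pools the dispersion estimate over *all* of a cell line's
  condition groups (twelve samples in the default design), as a full-design
  fit would, rather than over the two contrast groups alone.
* **Contrasts.** Each treatment is compared with DMSO within one cell line:
  group log-means are fit by Fisher scoring (vectorised over genes, max 50
  iterations, tolerance $10^{-8}$), the Wald statistic is
  $z = \widehat{\mathrm{lfc}} / \mathrm{se}$ with
  $\mathrm{se}^2 = (1/I_{\mathrm{trt}} + 1/I_{\mathrm{ref}})/\ln^2 2$ from the
  expected information $I = \sum_j \mu_j/(1+\alpha\mu_j)$, and p-values are
  BH-adjusted (step-up, NA excluded from $m$). Genes all-zero in both groups
  get NA statistics and are excluded from the BH denominator; genes all-zero
  on one side only get a sign-capped $|\mathrm{lfc}| = 10$ and NA p.
* **Known limitation.** With three replicates per group the plug-in Wald test
  is mildly anticonservative: on all-null fixtures the rejection rate at
  $p<0.05$ is about 0.06 rather than 0.05 (with the true dispersion plugged
  in it is 0.05, so the inflation is entirely the dispersion-estimation
  noise). The 50% gene-level weight is kept because it is the package's
  stated default; raising `shrink_weight` restores near-exact calibration in
  homogeneous-dispersion data at the cost of per-gene adaptivity.

# Clustering, group selection and GSEA

Heatmap-style analysis z-scores each gene across condition means (sample SD;
constant rows map to zeros and are flagged), clusters rows by Euclidean
distance with complete linkage (the heatmap-package convention; the linkage
was not pinned down by the analysis we re-implement, so it is configurable
among complete/average/ward), and cuts the dendrogram into exactly $k$ groups
— five for the sensitive line and seven for the resistant line in the default
configuration, mirroring the published cuts. The published analysis chose its
"double-treatment-high" gene groups visually; we formalise that as: a group
qualifies when its mean z in the double-treatment condition is positive and
maximal across conditions. This is objective and reproduces the described
pattern, but it is an interpretation, not a published rule.

The enrichment score is the weighted Kolmogorov–Smirnov running-sum
statistic on a pre-ranked list (sorted log2 fold changes of padj < 0.05
genes, descending, ties broken by symbol): hits add
$|m_i|^p / \sum_{\mathrm{hits}} |m|^p$, misses subtract $1/(N - N_h)$, and ES
is the signed extremum. The weight defaults to $p = 1$ (the classic weighted
statistic). Significance uses gene-label permutation — the only scheme
available on a pre-ranked list —, with
$p = (1 + \#\{|ES_{\mathrm{null}}| \ge |ES|\})/(1 + n_{\mathrm{perm}})$ and
$NES = ES / \mathrm{mean}(|ES_{\mathrm{null}}|)$ over same-sign null scores.
One caveat discovered while testing: appending zero-metric non-member genes
to the bottom of a ranking changes $N$ and hence the miss decrement, so ES is
only invariant to such padding when the extremum is reached before the first
miss (e.g. fully top-loaded sets); the property tests exercise exactly that
regime.

# Signatures and module scores

Treatment-specific signatures are the genes passing padj < 0.05 **and**
log2FC > 1 (one-sided: up-regulated only) in exactly one treatment — the
binary-membership-matrix construction makes them pairwise disjoint by
definition. Module scores re-implement the familiar bin-matched control
approach: genes are ranked by average expression (ties by symbol), split into
`n_bins = 24` near-equal bins, each signature gene draws `n_ctrl = 100`
controls from its own bin (without replacement when the bin allows), and the
cell's score is the mean signature expression minus the mean control
expression. The two defaults are the conventional ones for this scoring
method; the published analysis did not state its parameters. Scores are
invariant under global additive shifts and bit-reproducible under a seed.

# CUT&RUN peaks and regulatory domains

All intervals are 0-based half-open internally (BED-native; GRanges
conversion happens only at the I/O boundary). Antibody-reproducible
consensus is the base-pair **intersection** of the two replicate peak sets —
the strictest reading of "called in both replicates". Condition-unique gene
sets are computed from gene sets *after* peak-to-gene association (matching
the published Venn over peak-associated genes), not from raw base pairs.
Peak-to-gene association uses basal-plus-extension regulatory domains: basal
= TSS −5000/+1000 bp strand-oriented, extension up to a cap in both
directions stopping at the nearest other gene's basal domain. The function
default cap is the association tool's 1 Mb; the pipeline's synthetic-fixture
configuration scales it to 50 kb because the synthetic genome is roughly a
thousandfold smaller than a mammalian genome. Midpoint-based feature
annotation uses priority promoter-TSS (±1000 bp) > exonic > intronic >
intergenic; exon intervals are optional, and without them gene-body midpoints
count as intronic.

# Motif enrichment

PWMs (JASPAR 2016 text) are converted to probabilities with a $10^{-4}$
floor; scanning computes log-odds against the background on both strands and
calls a hit at ≥ 0.8 of the maximum attainable score (`score_fraction`,
configurable; the threshold is conventional — the tool we substitute for
keeps its own internal defaults). Enrichment counts *sequences with at least
one hit* (robust to peak-length variation), compares foreground vs background
with a one-sided hypergeometric tail over the pooled universe, and adjusts
across motifs by BH. The default background is a per-sequence exact
dinucleotide shuffle (random Eulerian walk over the dinucleotide multigraph)
— the simplest composition-matched null.

# Dose–response

The four-parameter logistic
$r = b + (t - b) / (1 + 10^{h(x - e)})$ is fit by bounded least squares on
$x = \log_{10}$ micromolar dose (vehicle wells anchored at $x = -5$, the
protocol convention adopted generally), with initialisation from the response
extremes and half-range crossing, five jittered restarts, and $e$ bounded to
the dose range ± one decade. The published analysis reports only that "flat
curves" have no IC50; our quantitative rule flags a fit as flat when the
amplitude $|t - b|$ is below `flat_frac = 0.2` of the vehicle-level response,
when the hill slope's approximate 95% CI spans zero, or when $e$ is pinned at
its boundary — a flat fit always reports an undefined IC50. Two
classification rules are provided and never mixed: the absolute threshold
(sensitive iff IC50 strictly below 2000 pM) and the rank-extremes grouping
(bottom-20 IC50 = sensitive; top-20 plus all undefined-IC50 lines =
resistant; middle unclassified; boundary ties broken by name).

# The synthetic world

The generator's defaults state the fixture world once:

* 4 treatments (DMSO, TGFB1, MEKI, TGFB1_MEKI) × 2 cell lines × 3 replicates
  (three replicates being the replication level of the deeply sequenced
  lines); 2000 genes with log-normal baselines (median ≈ 200 counts,
  sdlog 1.2) and constant dispersion $\alpha = 0.05$ — mid-range for
  well-replicated bulk RNA-seq; library sizes log-uniform in [0.7, 1.4] to
  exercise size-factor estimation.
* Implanted blocks: *invasive* (60 genes; +2 log2 units under TGFB1, −1 under
  the double treatment — the anti-correlation the double treatment shows),
  *switch* (50 genes; +3 under the double treatment only), *MITF* (40 genes;
  +1.5 under MEKi), remainder null.
* Peaks: two antibody replicates per condition; a peak is present in both
  with probability `reproducible_fraction = 0.8` (endpoints jittered by at
  most width/4 so flagged-reproducible pairs always overlap); the double
  treatment's condition-specific peaks sit 300 bp downstream of the switch
  genes' TSS — inside their basal regulatory domains.
* Sequences: motif implanted (consensus word) in foreground peaks at rate
  0.8; background = exact dinucleotide shuffle.
* Single cells: the four drug-exposure states (pigmented, SMC, NCSC,
  invasive), 200 cells each, log-scale expression with 0.5 SD noise; NCSC
  over-expresses the switch block by 1.0 log unit.
* Dose–response: 5-fold trametinib dilution 250 nM → 16 pM plus vehicle,
  three replicates, Gaussian noise SD 2 (2% of a 0–100 viability scale); one
  sensitive line (IC50 500 pM), one resistant line (IC50 50 nM), one flat
  (unfittable) line.

All randomness flows from the root seed, split deterministically per
sub-generator (annotation 1, counts 2, peaks 3, sequences 4, single-cell 5,
dose–response 6, library sizes 7, gene sets 8, module-score draw 31, 4PL
restarts 41).

What the generator does **not** emulate: batch effects, dropout/doublet
structure in single cells, GC- or mappability-dependent coverage, peak-width
distributions of real CUT&RUN, or correlated gene–gene noise. A green
fixture-recovery test therefore establishes that the pipeline's set algebra,
statistics and thresholds do what they claim on data matching their model
assumptions — not that the biological conclusions of any particular dataset
are reproduced.

# Orchestration

`run_pipeline()` chains the stages on the synthetic fixture and emits a
versioned, machine-readable report carrying every parameter, per-stage
summaries, the assembled signature with per-member provenance tags, module
score summaries, motif and dose–response tables, and truth-recovery metrics
(switch-gene sensitivity, null contamination). Reports are byte-identical
across runs at a fixed seed, modulo the runtime field. The stage functions
themselves are the package's public interface; there is deliberately no
shell wrapper — an R user drives the pipeline from R, and
`scripts/acceptance.R` shows the one-command form.
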