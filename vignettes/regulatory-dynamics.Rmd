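---
title: "Dissecting regulatory dynamics along a bifurcating hematopoietic trajectory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting regulatory dynamics along a bifurcating hematopoietic trajectory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`regdyn` analyses paired single-cell RNA + ATAC (multiome) data along a
differentiation pseudotime to answer three questions about a bifurcating
hematopoietic trajectory: which distal chromatin elements regulate which
genes, which transcription factors drive the dynamic regulatory programs,
and how a perturbation (here, a control vs inflammatory-disease contrast)
biases lineage fate. Clustering, trajectory inference and pseudotime
estimation are treated as upstream inputs: the package consumes cluster
labels, trajectory state labels and per-cell pseudotime scores, and starts
its own modelling from there.

This vignette explains the statistical procedures, the parameters that
matter, what the bundled synthetic generator does and does not emulate,
and the numerical choices made where the design was open.

# The analysis chain

## Quality control and markers

Cells must pass both assays jointly: at least 200 detected genes, at most
25% mitochondrial RNA, and total ATAC counts between 1,000 and 50,000
(counts stand in for fragments, since fragment files are outside the
package's scope; the QC report states this proxy openly). Boundary
semantics are strict on the removal side — a cell at exactly 200 features,
25.0% mitochondrial reads, 1,000 or 50,000 fragments is kept. On very
small simulated gene panels the feature floor is rescaled accordingly
(e.g. 30 of 60 genes); the defaults describe genome-wide data.

Cluster markers use the standard one-vs-rest recipe: expression is
depth-normalized to 10,000 counts per cell and log1p-transformed; genes
with natural-log fold change above 0.25 (ratio of normalized group means
with pseudocount 1) and an expressing fraction above 0.25 in either
population are tested with a two-sided Wilcoxon rank-sum test, with BH
adjustment per cluster. The union of cluster markers defines the genes
that enter peak-to-gene linking.

## Pseudobulk aggregation

Cells on the trajectory are sorted by pseudotime (ties broken by cell id
for determinism) and summed in consecutive blocks of 50 cells for both
assays. The paper-level sources are silent on remainders; the rule here
merges a trailing block of fewer than 25 cells into the previous block
and otherwise keeps it, which bounds sample-size heterogeneity at two-fold.
Each pseudobulk sample is CPM-normalized (rows sum to 1e6 exactly).
Pseudobulks are built on the pooled cell set so that both groups share one
series; a per-group run is a matter of subsetting the dataset first.

## Peak-to-gene linking

Candidate pairs are protein-coding or lincRNA marker genes paired with
same-chromosome peaks whose midpoint lies 1–250 kb from the TSS,
inclusive at both ends (the peak midpoint is the single anchor used, the
usual convention when one coordinate per peak suffices). For each pair,
Pearson correlation between the peak's CPM accessibility and the gene's
CPM expression is computed across pseudobulk samples, with the two-sided
p-value from `t = r*sqrt((n-2)/(1-r^2))` on `n-2` degrees of freedom.
High-confidence links satisfy `|PCC| >= 0.3` (inclusive) and `P < 0.05`
(strict). No multiple-testing correction is applied to link p-values —
the thresholds are read literally as a raw-P rule; the correlation floor
does most of the filtering at typical series lengths (40 samples).

High-confidence links are clustered with k-means (k = 6) on the z-scored
expression profile of the linked gene (mean 0, sd 1 across samples).
Expression-only clustering is used; accessibility profiles of the peaks
are deliberately not concatenated, since the cluster identity is meant to
describe when the target program is active. k-means uses k-means++
seeding with 10 restarts under a logged seed (the initialisation scheme
is not prescribed anywhere upstream; this choice is for stability), and
clusters are renumbered by the pseudotime position of their mean-profile
maximum so that cluster 1 always peaks earliest. Motif enrichment within
a cluster is a one-sided hypergeometric test of motif-bearing peaks
against all linked peaks, BH-adjusted across motifs within the cluster.

## Motif deviations

Motif activity follows the chromVAR idea. For motif *m* with peak set
*S*, the raw deviation of sample *i* is `(o_i - x_i)/x_i`, with `o_i` the
observed counts in *S* and `x_i = depth_i * sum(e_p)` the depth-scaled
expectation, where `e_p` is each peak's share of total counts. Bias
correction replaces every member peak with one of its GC- and
accessibility-matched background draws (50 iterations by default, the
published chromVAR default) and z-scores the observed deviation against
that background distribution per sample. Background draws come from the
nearest 5% of peaks in standardized (GC, log1p mean accessibility) space,
sampled with Gaussian-kernel weights (bandwidth = median neighbour
distance); a peak never draws itself. Variability is the standard
deviation of a motif's z-scores across samples.

Synergy and correlation between motif pairs follow the chromVAR concept
self-containedly: correlation is the Pearson r of two motifs' z-score
profiles; synergy asks whether the peaks shared by two motifs are more
variable than random same-size subsets of their union (100 subsets,
z-score of the observed intersection variability; pairs sharing fewer
than 5 peaks are NA). Exact numerical parity with the original chromVAR
implementation is a non-goal — the definition here is fully specified and
oracle-tested instead. When the reference subset distribution is
degenerate (identical peak sets), the synergy is reported as 0, the
distributional center.

Group-wise differential motif accessibility contrasts mean bias-corrected
deviations between two sample groups with a two-sided Wilcoxon rank-sum
test and BH adjustment across motifs — the test is unstated upstream and
a rank test is the robust choice for z-scales. Deviations may be computed
on pseudobulks (for pseudotime analyses) or directly on cells (pass the
cell x peak matrix), which is the natural input for a control-vs-case
volcano.

## Positive TF regulators and promoter networks

Gene activity scores are accessibility-derived: CPM accessibility of
peaks within 100 kb of the TSS, weighted by `exp(-distance/5000)` and
log1p-transformed. The formula is this package's own (upstream sources
state only that gene scores derive from peak accessibility); window and
decay are exposed in the configuration, and the defaults mirror the
common distance-decay gene-activity models for scATAC-seq. A motif is a
positive TF regulator when its deviation profile correlates with its own
TF gene's activity score across the pseudobulk series at `r >= 0.5` and
BH-adjusted `p < 0.05`; these two thresholds are likewise this package's
choice, mirroring common practice for regulator calling, and are
configurable.

Promoter windows span 2,000 bp upstream to 500 bp downstream of the TSS,
strand-aware, half-open, clipped at zero — 2,500 bp for every unclipped
gene. PWM scanning converts a JASPAR-style PFM to log2-odds with
pseudocount 0.8 against a uniform background, scores both strands, and
keeps matches with relative score ("homology", min-max rescaled) above
0.85 and raw log-odds ("binding score") above 8, both strict. Windows
containing N are skipped. The target gene set (e.g. an interferon
signaling pathway list) is supplied by the user as a plain gene list; no
ontology access happens at run time.

## Lineage fate composition

Cells belonging to a fate (a set of trajectory states — myeloid
{1,3,4,5}, lymphoid {1,3,4,6}) are binned into 50 equal-width bins over
the pooled pseudotime range; within each group and bin, the proportions
of cluster labels are reported. Bin edges come from the pooled range so
the groups share an axis, which is what makes an upper-vs-lower stacked
comparison meaningful. Empty bins carry zero proportions and an explicit
flag rather than NaN.

# The synthetic generator

`simulate_multiome()` is first-class, tested code, and the source of
ground truth for every downstream validation. It emulates:

- a bifurcating trajectory: latent `t ~ U(0,1)`, a myeloid/lymphoid
  branch drawn with group-dependent probability (defaults Ctrl 0.4,
  LIP 0.8), cluster labels following an LSK → GMP → NeuP / LSK → CLP →
  proB layout, and trajectory states arranged so the two fate state sets
  above are realizable;
- smooth gene programs (logistic ramps or Gaussian bumps, optionally
  branch-restricted) with NB counts (shared dispersion 2, per-cell
  log-normal depths around 5,000) — minimal realistic overdispersion;
- planted peak–gene links: 200 peaks placed uniformly 1–250 kb from
  their partner gene's TSS whose Poisson accessibility rate tracks the
  partner's program with weight `link_effect` (default 0.9); every gene
  also gets a flat decoy peak inside the window, and decoys outside the
  window exercise the distance filter in the other direction;
- planted positive regulators: 3 of 20 motifs whose 150-peak sets are 80%
  peaks tracking the TF's own gene program (the three programs are an
  opening ramp, a closing ramp and a mid-trajectory pulse, so one pair is
  anti-correlated by construction), with tracking promoter-proximal peaks
  so the TF's accessibility-derived gene score follows the same program;
- per-peak GC from Beta(5,5), and observed pseudotime as a
  rank-preserving Gaussian(0, 0.02) perturbation of t — enough noise to
  scramble fine order while preserving the coarse signal linking needs.

Genes sit every 600 kb on one synthetic chromosome, so linking windows
never overlap and each planted peak can pair only with its partner. That
is a deliberate simplification: real genomes have overlapping windows,
co-regulated neighbouring genes, sequence-driven GC structure, batch
effects and doublets, none of which the generator emulates. Passing the
planted-truth checks therefore demonstrates that the statistics recover
the signal they define under their own assumptions — not that real-data
performance will match.

Each draw is a deterministic function of the spec (single seeded RNG
stream); written fixtures are byte-identical across runs, which is what
the pipeline-manifest reproducibility check asserts.

# Problem sizes and numerical choices

Validation runs use the generator's default study conditions — 2,000
cells, 500 genes, 5,000 peaks, 200 planted links, 20 motifs with 3
planted regulators, `link_effect` 0.9, seeds 1–5 — for the recovery
checks, and reduced panels (400–1,000 cells, 60–300 genes) for
structural and null-behaviour properties, where the check depends on
labels or on null statistics rather than on matrix scale. Fate-bias
checks keep 2,000 cells (binomial resolution per bin matters there) with
a small gene/peak panel, since only the cell labels enter.

Numerical details worth knowing:

- CPM rows are exact to 1e-6 of 1e6; correlation p-values are exact
  t-tail computations, not approximations.
- k-means centers receive a 1e-9 jitter to avoid the duplicate-center
  corner case when profiles coincide exactly; assignments are seeded and
  reproducible.
- Background-deviation means and variances use single-pass accumulation
  over the 50 iterations; with O(1) deviations this agrees with two-pass
  computation to ~1e-12, which the enumeration oracles confirm.
- Degenerate inputs have defined behaviour rather than NaN: constant
  profiles drop pairs with a reason code, zero-expectation samples yield
  NA deviations with a warning, all-identical peak covariates fall back
  to uniform background sampling with a warning.

# Known limitations

- Fragment counts are approximated by ATAC matrix totals; QC on true
  fragment files is out of scope.
- Motif–peak membership must be supplied (or simulated); the package
  scans promoter windows with PWMs but does not scan genome-wide peak
  sequences.
- The synergy score is a self-contained definition inspired by chromVAR,
  not a re-implementation of it; values are comparable within a run, not
  across tools.
- Trajectory inference, clustering, dimensionality reduction and GO/GSEA
  enrichment are intentionally absent — the package starts after them and
  stops before interpretation.
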