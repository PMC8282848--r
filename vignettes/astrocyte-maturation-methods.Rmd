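---
title: "Methods: reconstructing the astrocyte maturation programme"
author: "astromat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reconstructing the astrocyte maturation programme}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The biological question and the analysis it requires

After birth, postmitotic immature astrocytes transition over several weeks
into their adult functional state. This maturation is transcriptionally
deep — hundreds of genes are switched on or off — and is accompanied by
extensive chromatin remodelling, particularly at distal regulatory
elements. `astromat` implements the integrative analysis that connects
these two layers:

1. **Pseudotime gene modules.** From a genes × cells count matrix and a
   per-cell pseudotime (trajectory inference itself is an input, not part
   of this package), genes with dynamic expression are grouped into
   modules with shared temporal profiles and each module is labelled
   *immature* (peaking early or mid-trajectory) or *mature* (peaking at
   the trajectory end).
2. **Bulk differential expression.** A simplified negative-binomial Wald
   test contrasts an early-postnatal-like condition ("early") against an
   adult-like condition ("late") on bulk RNA counts.
3. **Maturation signatures.** High-confidence immature/mature gene sets
   are the intersections of the single-cell module genes with the bulk
   down-/up-calls — genes supported by both experimental designs.
4. **Regulatory elements.** ATAC peaks are floored, tested for
   differential accessibility ("opening" = more accessible in the late
   condition, "closing" = the reverse), classified as
   promoter/enhancer/distal by annotation overlap, and linked to genes by
   closest TSS plus long-range interaction tables, with a 100 kb distance
   cap variant.
5. **Integration.** Per-gene tallies of linked differential peaks yield
   the fraction of signature genes associated with chromatin remodelling
   and the predominant direction per class; Wilcoxon rank-sum contrasts
   and replicate-consistent ChIP-overlap Fisher tests quantify the
   coupling.

All coordinates are BED-convention throughout: 0-based, half-open, so
interval length is `end - start` and abutting intervals do not overlap.

## Module detection: procedure and parameters

Cells are assigned to `n_bins = 20` bins spanning **equal pseudotime
ranges** (not equal cell counts); bins with 10 cells or fewer are dropped.
Expression is variance-stabilised by a documented stand-in for regression-
based single-cell normalisation: counts are depth-scaled to the median
cell total and `log1p`-transformed. The stand-in is swappable — every
module function accepts an already-normalised matrix.

Dynamic genes are found with a per-gene Kruskal–Wallis test of normalised
expression across retained bins, BH-adjusted (`dynamic_padj = 0.05`). This
replaces GAM-based trajectory association testing: at twenty bins the
rank test is assumption-light, exact under permutation, and detects any
location shift across the trajectory; it is a methodological substitution
and is flagged as such. Genes whose mean-centred bin profile never deviates
by at least `min_deviation = 0.2` (inclusive) are removed as minimally
changing.

Profiles of the retained genes are clustered hierarchically (Euclidean
distance, `ward.D2` linkage — the linkage used by the heatmap clustering
this procedure automates) and cut at `k_initial = 50` clusters. Because
manual merging of similar clusters is not reproducible, merging is
automated: while any two module mean profiles correlate at
`merge_r >= 0.8` (Pearson), the best pair is merged and profiles are
recomputed; ties break deterministically towards the first pair in module
order. A module is **mature** iff its mean profile peaks within the last
`ceiling(0.25 * b)` of the `b` retained bins, with ties at the maximum
broken towards the later bin; otherwise **immature**. The 0.8 merge
threshold and the last-quartile window are package decisions (the original
procedure classified by visual inspection); both are exposed in
`module_params()`.

## The differential test and its deliberate simplifications

`nb_wald_test()` is a small, dependency-free stand-in for a DESeq2-style
analysis, applied identically to RNA and ATAC tables:

* size factors by median-of-ratios over features positive in every sample
  (factors are anchored to the pooled geometric mean and not rescaled);
* group means on the normalised scale with a 0.5 pseudocount, so zero
  counts give finite fold changes: `log2FC = log2((mB + 0.5)/(mA + 0.5))`
  (B = "late", the second factor level);
* a **common dispersion** `alpha` estimated by method of moments, pooling
  residual second moments across both groups and all features (ratio of
  summed `s^2 - m` to summed `m^2`, clamped at `1e-8`). Per-feature moment
  estimates at n = 3 per group are too noisy to calibrate a normal Wald
  statistic; the pooled estimator is precise and matches the generative
  model used throughout this package, where one dispersion is shared. This
  is a moment analogue of a common-dispersion estimate, not empirical-Bayes
  shrinkage;
* delta-method standard error of the fold change from the NB variance
  `m + alpha m^2` of each group mean; two-sided normal p; BH adjustment
  over the tested features only (features removed by the expression floor
  are never tested and carry no adjusted p).

There is no outlier filtering, no independent filtering and no multi-factor
design. Thresholds are inclusive everywhere: `padj <= 0.05`,
`|log2FC| >= 1`, deviation `>= 0.2` retained, accessibility floor removes
peaks below 25 in **all** samples, and the 100 kb cap keeps a link at
exactly 100,000 bp.

Calibration under the package's own null (2000 features, NB dispersion
0.3, 3 vs 3 samples) puts the raw-p rejection rate at 0.05 in the 0.06
neighbourhood — acceptably close to nominal for a normal-reference Wald
test at this sample size — with power above 0.8 at fold 4. Both properties
are asserted by the test suite, which recomputes them from scratch.

## Peak classification and linking

Classification precedence follows the annotation order of the original
procedure: *promoter* (overlap with the promoter track, or optionally
within `tss_window` of an annotated TSS — off by default) beats *enhancer*
(overlap with the enhancer track **or** the H3K4me1 track) beats *distal*.
Every peak gets exactly one class.

Peak-to-gene links come from two sources. The closest-TSS link minimises
`|TSS - peak centre|` (centre = `floor((start+end)/2)`; distance measured
from the centre rather than the edge so it is stable under peak-width
changes), signed in gene orientation, with equidistant ties broken towards
the smaller gene id. Long-range links attach non-promoter peaks to genes
via named interaction regions (a 2-column region → gene table resolved
against a named BED), dropping duplicates of the closest-TSS link.
Chromosomes are independent: a peak never links across chromosomes, and a
peak on a gene-less chromosome is flagged rather than dropped silently.
`apply_distance_cap()` removes only closest-TSS links beyond the cap;
long-range links are exempt by definition.

Signal heatmap matrices sum bedGraph-style coverage in 100 consecutive
20 bp bins over peak centre ± 1 kb and divide by the sample's frip score
(fraction of reads in peaks), the per-sample sequencing-quality scalar
used for all displayed accessibility signal. Windows clipped at a
chromosome start are zero-filled.

## Integration statistics

`associate_genes_peaks()` tallies each signature gene's linked peaks by
direction; a gene "has differential accessibility" iff at least one linked
peak is opening or closing. Per class, `direction_concordance()` reports
the fraction with differential peaks and — among genes whose opening and
closing counts differ — the fraction predominantly opening/closing.
Opening/closing **ties are excluded from both numerator and denominator**
of the predominance fractions; the tie rule is a package decision made
explicit because the source analysis states direction only qualitatively.

`wilcoxon_rank_sum()` is exact by complete enumeration when the pooled
sample size is at most 12 with no ties (two-sided p doubles the smaller
tail, capped at 1) and otherwise uses the normal approximation with tie
and continuity correction; the switch point keeps the exact path
verifiable by brute force while matching standard practice at larger n.
`fisher_enrichment()` computes the two-sided Fisher exact p by summing
hypergeometric probabilities not exceeding the observed table's (the
probability-mass definition, not tail doubling) and the conditional
maximum-likelihood odds ratio; degenerate margins give p = 1 and an
undefined-odds-ratio flag. ChIP binding requires overlap in **both**
replicate tracks.

## What the synthetic data generator emulates

`sim_config()` defaults define the reference scenario used by the tests
and the analysis scripts: 2000 genes × 1500 cells with pseudotime uniform
on [0, 1]; 700 temporally patterned genes split over six archetypes — four
immature (early exponential decline; early Gaussian peak at t ≈ 0.15; mid
peak at t ≈ 0.4; plateau then decline around t ≈ 0.6) and two mature (a
logistic rise centred at t ≈ 0.55; a sharp late switch at t ≈ 0.85) in the
≈71:29 immature:mature gene ratio of the maturation programme — plus 1300
flat background genes. Counts are negative binomial (dispersion 0.3, a
typical single-cell value) with expected value *cell library factor ×
gene baseline × shape(t)* and expected totals of 2000–5000 counts per
cell.

Two design choices keep the generator self-consistent with the analysis:

* **Stationary composition.** Per-archetype baseline multipliers, obtained
  from a ridge-regularised least-squares fit that flattens the summed
  archetype output along pseudotime, keep a cell's expected total output
  approximately constant in t. Without this, depth normalisation would
  imprint the (declining) total of the patterned genes onto every flat
  gene as a spurious trend.
* **Low-expressed background.** Flat genes are drawn at ~0.25 expected
  counts per cell — as the untested background of a single-cell experiment
  is — which keeps their binned profiles well inside the 0.2 deviation
  floor. The patterned fraction (35%) mirrors the scale of a real
  maturation dataset, where a few thousand dynamic genes sit in a much
  larger measured transcriptome; it also keeps the median-of-ratios
  assumption (a majority of non-differential features) true in the bulk
  tables.

Bulk counts use fold 4 between conditions for maturation genes at
dispersion 0.05 (typical for bulk replicates, 3 per condition). ATAC peaks
(6000; one promoter peak per gene, stable filler enhancer/distal peaks,
3 early / 4 late samples) attach an opening peak to 71% of mature genes
and a closing peak to 50% of immature genes — the association rates the
integration stage is expected to recover — with a 4-fold accessibility
ratio; 40% of opening peaks carry a ChIP interval in both replicate
tracks versus a 5% background. Gene spacing is 50 kb with all per-gene
peak offsets within ±15 kb, so each constructed peak is genuinely closest
to its own gene; 5% of enhancer regions link long-range to a non-nearest
gene.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: doublets, ambient RNA, batch effects,
branching trajectories, mean-dependent dispersion trends, peak-width
variation, GC or mappability biases, and genuinely manual module merging.
The recovery results (six modules, 4/2 class split, ARI ≈ 1) demonstrate
the procedure is implemented correctly under its assumptions, not that the
thresholds are optimal for any particular real dataset.

## Numerical and degenerate-input conventions

* One global seed per generator run; stage streams derive from it by fixed
  offsets (genome +1, single-cell +2, bulk +3, ATAC +4), so every output
  is byte-identical under the same configuration.
* All tie-breaks are documented and deterministic (merge pair order,
  closest-TSS gene id, argmax towards the later bin).
* `t = max(pseudotime)` belongs to the last bin; an all-equal pseudotime
  vector is an error (no span).
* An all-zero count matrix has no valid size factors and errors with an
  instruction to pre-filter.
* Dispersion estimates are clamped below at `1e-8` (method-of-moments can
  go negative for underdispersed draws); a feature with zero counts in
  both groups gets z = 0, p = 1.
* Problem sizes in the tests and analysis scripts (2000 × 1500 single-cell
  matrix, 6000 peaks) were chosen as the smallest scale at which every
  recovery statistic is stable across seeds; the full workflow runs in
  well under a minute on one CPU.

## Known limitations

The dynamic-gene test detects distributional location shifts across bins,
not smooth-trend shape; genes dynamic only in variance are missed. The
common-dispersion NB test is anti-conservative when true dispersions vary
strongly across features. Module classification by profile argmax can
mislabel a module whose profile is bimodal with a late secondary peak.
Long-range links are taken at face value from the interaction table; no
confidence weighting is applied. Coordinate lift-over between assemblies
is out of scope — all inputs must share one coordinate system.
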