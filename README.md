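# astromat

Integrative analysis of astrocyte maturation: pseudotime gene modules,
maturation signatures, ATAC regulatory elements and chromatin–expression
association statistics, with a bundled synthetic-data generator so the
whole workflow runs and is tested offline.

## The problem

Postnatal astrocytes mature from a proliferative immature state into the
adult functional state. Along a single-cell pseudotime trajectory *t*,
maturation genes follow temporally patterned mean profiles; in bulk RNA-seq
the same genes change between an early-postnatal condition and an adult
condition; and in ATAC-seq, accessible chromatin near those genes opens or
closes. This package implements the analysis that ties the three layers
together, for computational biologists who want a tested, reusable version
of each step:

* **Modules.** Cells are grouped into 20 equal-range pseudotime bins (bins
  with ≤ 10 cells dropped); per-gene bin profiles of normalised expression
  are mean-centred; genes are kept if a Kruskal–Wallis test across bins is
  significant (BH ≤ 0.05) and the profile deviates by ≥ 0.2; profiles are
  clustered (Euclidean, ward.D2, 50 initial clusters) and merged while any
  two module mean profiles have Pearson *r* ≥ 0.8. A module is **mature**
  iff its profile peaks in the last quarter of bins, else **immature**.
* **Differential testing.** A simplified negative-binomial Wald test:
  median-of-ratios size factors, common method-of-moments dispersion α
  (variance *m* + α*m*²), log₂FC = log₂((m_B + 0.5)/(m_A + 0.5)),
  delta-method SE, normal two-sided p, BH adjustment; calls at padj ≤ 0.05
  and |log₂FC| ≥ 1 (inclusive). Expression floor 10 (RNA) / accessibility
  floor 25 (ATAC), applied before testing.
* **Signatures.** mature = sc-mature ∩ bulk-up; immature = sc-immature ∩
  bulk-down, with Venn counts.
* **Regulatory elements.** Peak classes by precedence promoter > enhancer
  (enhancer build or H3K4me1) > distal; closest-TSS links by
  |TSS − peak centre| with signed distances and a 100 kb cap variant;
  long-range region→gene links for non-promoter peaks; frip-normalised
  signal matrices (peak centre ± 1 kb in 100 × 20 bp bins).
* **Integration.** Per-gene tallies of linked opening/closing peaks,
  association and predominance fractions per gene class, exact/normal
  Wilcoxon rank-sum contrasts, both-replicate ChIP binding and two-sided
  Fisher exact enrichment with the conditional odds ratio.

## Worked example

The numbered scripts under `analysis/` run the complete workflow on the
default synthetic scenario (seed 1) and write their tables under
`results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_modules.R
Rscript analysis/03_differential_expression.R
Rscript analysis/04_peaks.R
Rscript analysis/05_integration.R
```

Stage 2 prints the module decomposition:

```
dynamic genes retained: 698 of 2000
  module_01:  150 genes, immature (profile peak at bin 1 of 20)
  module_02:  125 genes, immature (profile peak at bin 4 of 20)
  module_03:   99 genes, immature (profile peak at bin 8 of 20)
  module_04:  125 genes, immature (profile peak at bin 6 of 20)
  module_05:  120 genes, mature (profile peak at bin 17 of 20)
  module_06:   79 genes, mature (profile peak at bin 20 of 20)
module genes: 499 immature, 199 mature
```

Six modules, four peaking early/mid-trajectory (immature) and two at the
end (mature) — the structure the generator planted. Stage 3 intersects
them with the bulk calls (203 up, 497 down) into signatures of 199 mature
and 496 immature genes; stage 4 retains 5765 of 6000 peaks past the
accessibility floor and calls 145 opening and 267 closing; stage 5 reports
the chromatin–expression association:

```
    class n_genes frac_with_differential frac_predominantly_opening frac_predominantly_closing
 immature     496              0.5443548                          0                          1
   mature     199              0.7185930                          1                          0
expression contrast (n = 270 immature vs 143 mature genes with differential peaks): W = 36,585, p = 8.44e-63
ChIP binding in opening vs other accessible chromatin: OR = 12.70, p = 4.78e-34
```

Reading the fractions: 72% of mature genes carry a linked differential
peak (generator truth: 71%), all of them predominantly opening; 54% of
immature genes do (truth: 50%), all predominantly closing — chromatin
direction concordant with expression direction, and opening chromatin
strongly enriched for replicate-consistent ChIP binding.

The same steps are available programmatically:

```r
library(astromat)
res <- run_pipeline(sim_config(seed = 1), outdir = "results/run")
res$summary$n_modules         # 6
res$concordance
```

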