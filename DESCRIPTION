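Package: astromat
Title: Integrative Analysis of Astrocyte Maturation Transcriptomics and
    Chromatin Accessibility
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs the gene-expression and chromatin-accessibility
    programme of postnatal astrocyte maturation. Detects temporally
    patterned gene modules along a single-cell pseudotime trajectory by
    equal-range binning, deviation filtering and hierarchical clustering
    with correlation-based merging; derives high-confidence maturation
    signatures by intersecting module genes with bulk differential calls
    from a simplified negative-binomial Wald test; classifies ATAC-seq
    peaks into promoter, enhancer and distal elements, links them to genes
    by closest TSS and long-range interactions, and quantifies the
    association between chromatin remodelling and expression with rank-sum
    and Fisher exact statistics. Includes a synthetic-data generator with
    known ground truth so the complete pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    IRanges
Config/testthat/edition: 3
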