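#!/usr/bin/env Rscript
# Stage 3: bulk differential expression and maturation signatures.
#
# Normalises the two-condition bulk counts by median-of-ratios, removes
# genes below the expression floor (maximal normalised expression < 10),
# tests with the simplified NB Wald test (padj <= 0.05, |log2FC| >= 1,
# late vs early) and intersects the calls with the single-cell module
# genes to obtain the high-confidence immature/mature signatures.

source("analysis/00_config.R")

counts <- read_count_matrix(file.path(DATA_DIR, "bulk_counts.tsv"))
cond_tab <- read.delim(file.path(DATA_DIR, "bulk_condition.tsv"))
condition <- setNames(cond_tab$condition, cond_tab$sample)[colnames(counts)]

sf <- size_factors_median_of_ratios(counts)
keep <- filter_low_features(normalize_counts(counts, sf), 10)
de <- nb_wald_test(counts[keep, ], condition, sf)
calls <- call_differential(de, padj_threshold = 0.05, lfc_threshold = 1)
write.table(de, file.path(RESULTS_DIR, "bulk_differential.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

sc_imm <- readLines(file.path(RESULTS_DIR, "sc_immature_genes.txt"))
sc_mat <- readLines(file.path(RESULTS_DIR, "sc_mature_genes.txt"))
sig <- intersect_signatures(sc_mat, sc_imm, calls$up, calls$down)
writeLines(sig$mature, file.path(RESULTS_DIR, "signature_mature.txt"))
writeLines(sig$immature, file.path(RESULTS_DIR, "signature_immature.txt"))
write.table(sig$venn, file.path(RESULTS_DIR, "signature_venn.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("bulk: %d genes tested (of %d), %d up in late, %d down\n",
            nrow(de), nrow(counts), length(calls$up), length(calls$down)))
cat(sprintf("signatures: %d mature (sc mature x bulk up), %d immature (sc immature x bulk down)\n",
            length(sig$mature), length(sig$immature)))
print(sig$venn, row.names = FALSE)
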