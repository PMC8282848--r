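#!/usr/bin/env Rscript
# Stage 5: chromatin-expression integration.
#
# Tallies linked differential peaks per signature gene, reports the
# fraction of immature/mature genes associated with differential
# accessibility and the direction predominance, contrasts the expression
# fold changes of the two gene groups (Wilcoxon rank-sum), and tests
# whether opening chromatin is enriched for replicate-consistent ChIP
# binding (Fisher exact).

source("analysis/00_config.R")

sig <- list(mature = readLines(file.path(RESULTS_DIR, "signature_mature.txt")),
            immature = readLines(file.path(RESULTS_DIR, "signature_immature.txt")))
links <- read.delim(file.path(RESULTS_DIR, "peak_gene_links.tsv"))
pk <- read.delim(file.path(RESULTS_DIR, "peaks_classified.tsv"))
direction <- setNames(pk$direction, pk$name)
bulk_de <- read.delim(file.path(RESULTS_DIR, "bulk_differential.tsv"))
chip1 <- read_bed(file.path(DATA_DIR, "chip_rep1.bed"))
chip2 <- read_bed(file.path(DATA_DIR, "chip_rep2.bed"))

assoc <- associate_genes_peaks(sig, links, direction)
cc <- direction_concordance(assoc)
write.table(assoc, file.path(RESULTS_DIR, "gene_peak_associations.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(cc, file.path(RESULTS_DIR, "concordance.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
print(cc, row.names = FALSE)

# expression contrast between gene groups with associated differential peaks
with_diff <- assoc[assoc$has_differential, ]
lfc <- setNames(bulk_de$log2fc, bulk_de$feature_id)
imm_lfc <- lfc[intersect(with_diff$gene_id[with_diff$class == "immature"],
                         names(lfc))]
mat_lfc <- lfc[intersect(with_diff$gene_id[with_diff$class == "mature"],
                         names(lfc))]
wt <- wilcoxon_rank_sum(imm_lfc, mat_lfc)
cat(sprintf("expression contrast (n = %d immature vs %d mature genes with differential peaks): W = %s, p = %.3g\n",
            length(imm_lfc), length(mat_lfc),
            format(wt$W, big.mark = ","), wt$p))

# ChIP enrichment in opening chromatin
peaks_iv <- pk[, c("chrom", "start", "end", "name", "strand")]
bound <- chip_bound_regions(peaks_iv, chip1, chip2)
enr <- fisher_enrichment(direction[peaks_iv$name] == "opening", bound)
cat(sprintf("ChIP binding in opening vs other accessible chromatin: OR = %.2f, p = %.3g\n",
            enr$odds_ratio, enr$p))
print(enr$table)

summary <- list(
  concordance = cc,
  expression_contrast = list(n_immature = length(imm_lfc),
                             n_mature = length(mat_lfc),
                             W = wt$W, p = wt$p),
  chip_enrichment = list(odds_ratio = enr$odds_ratio, p = enr$p,
                         table = as.data.frame(enr$table)))
jsonlite::write_json(summary, file.path(RESULTS_DIR, "integration_summary.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE,
                     dataframe = "rows")
cat("summary written to", file.path(RESULTS_DIR, "integration_summary.json"), "\n")
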