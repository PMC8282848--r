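#!/usr/bin/env Rscript
# Stage 4: ATAC regulatory elements.
#
# Removes minor peaks (normalised accessibility < 25 in all samples),
# tests differential accessibility (opening = more accessible in the late
# condition, closing = the reverse), classifies retained peaks as
# promoter/enhancer/distal by annotation overlap, links every peak to its
# closest TSS plus long-range interaction targets, and caps closest-TSS
# links at 100 kb.

source("analysis/00_config.R")

counts <- read_count_matrix(file.path(DATA_DIR, "atac_counts.tsv"))
samp <- read.delim(file.path(DATA_DIR, "atac_samples.tsv"))
condition <- setNames(samp$condition, samp$sample)[colnames(counts)]
peaks_all <- read_bed(file.path(DATA_DIR, "peaks.bed"))
genes <- read_gene_models(file.path(DATA_DIR, "genes.tsv"))
tracks <- list(promoters = read_bed(file.path(DATA_DIR, "promoters.bed")),
               enhancers = read_bed(file.path(DATA_DIR, "enhancers.bed")),
               h3k4me1 = read_bed(file.path(DATA_DIR, "h3k4me1.bed")))
link_table <- read_links(file.path(DATA_DIR, "longrange_links.tsv"))

sf <- size_factors_median_of_ratios(counts)
keep <- filter_low_features(normalize_counts(counts, sf), 25)
peaks <- peaks_all[peaks_all$name %in% keep, ]
de <- nb_wald_test(counts[peaks$name, ], condition, sf)
calls <- call_differential(de, 0.05, 1)
direction <- setNames(rep("stable", nrow(peaks)), peaks$name)
direction[calls$up] <- "opening"
direction[calls$down] <- "closing"

peaks <- classify_peaks(peaks, tracks)
closest <- link_closest_tss(peaks, genes)
longrange <- link_long_range(peaks, tracks$enhancers, link_table,
                             closest = closest)
links <- apply_distance_cap(
  rbind(closest[!closest$no_gene, names(longrange)], longrange),
  cap = 100000)

write.table(de, file.path(RESULTS_DIR, "atac_differential.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(peaks, direction = direction[peaks$name]),
            file.path(RESULTS_DIR, "peaks_classified.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(links, file.path(RESULTS_DIR, "peak_gene_links.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("peaks: %d called, %d retained after the accessibility floor\n",
            nrow(peaks_all), nrow(peaks)))
cat(sprintf("differential accessibility: %d opening, %d closing\n",
            sum(direction == "opening"), sum(direction == "closing")))
print(table(peaks$class))
cat(sprintf("links: %d closest-TSS (within 100 kb), %d long-range\n",
            sum(links$source == "closest_tss"),
            sum(links$source == "long_range")))
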