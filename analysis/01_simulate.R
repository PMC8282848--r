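#!/usr/bin/env Rscript
# Stage 1: materialise the synthetic maturation dataset.
#
# Generates the toy genome with its annotation tracks, the single-cell
# trajectory counts, the two-condition bulk RNA-seq counts and the
# two-condition ATAC-seq peaks with ChIP replicate tracks, all with known
# ground truth, and writes every table under results/data/.

source("analysis/00_config.R")

cfg <- analysis_config()
data <- simulate_dataset(cfg, dir = DATA_DIR)

cat(sprintf("genome: %d genes on %d chromosomes; %d enhancer regions, %d long-range links\n",
            nrow(data$genome$genes), cfg$n_chroms,
            nrow(data$genome$enhancers), nrow(data$genome$links)))
cat(sprintf("single-cell: %d genes x %d cells (%d patterned, %d flat)\n",
            nrow(data$sc$counts), ncol(data$sc$counts),
            sum(data$truth$gene_class != "flat"),
            sum(data$truth$gene_class == "flat")))
cat(sprintf("bulk: %d samples; ATAC: %d peaks x %d samples (%d opening, %d closing by construction)\n",
            ncol(data$bulk$counts), nrow(data$atac$counts),
            ncol(data$atac$counts),
            sum(data$truth$peak_direction == "opening"),
            sum(data$truth$peak_direction == "closing")))
cat("written to", DATA_DIR, "\n")
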