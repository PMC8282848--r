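#!/usr/bin/env Rscript
# Stage 2: pseudotime gene modules.
#
# Bins cells into 20 equal-range pseudotime bins, keeps genes that are
# dynamic (Kruskal-Wallis across bins, BH <= 0.05, centred-profile
# deviation >= 0.2), clusters their bin profiles into 50 initial modules
# (Euclidean, ward.D2) and merges modules whose mean profiles correlate at
# r >= 0.8; each final module is labelled immature or mature by where its
# profile peaks.

source("analysis/00_config.R")

counts <- read_count_matrix(file.path(DATA_DIR, "sc_counts.tsv"))
pt_tab <- read.delim(file.path(DATA_DIR, "pseudotime.tsv"))
pt <- setNames(pt_tab$pseudotime, pt_tab$cell)

res <- detect_modules(counts[, names(pt)], pt, module_params())

membership <- do.call(rbind, lapply(names(res$modules), function(id)
  data.frame(module = id, gene_id = res$modules[[id]]$genes,
             class = res$modules[[id]]$class, stringsAsFactors = FALSE)))
write.table(membership, file.path(RESULTS_DIR, "module_membership.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

profiles <- data.frame(gene_id = rownames(res$profiles), res$profiles,
                       check.names = FALSE)
write.table(profiles, file.path(RESULTS_DIR, "module_profiles.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(res$immature_genes, file.path(RESULTS_DIR, "sc_immature_genes.txt"))
writeLines(res$mature_genes, file.path(RESULTS_DIR, "sc_mature_genes.txt"))

cat(sprintf("dynamic genes retained: %d of %d\n", nrow(res$profiles),
            nrow(counts)))
for (id in names(res$modules))
  cat(sprintf("  %s: %4d genes, %s (profile peak at bin %d of %d)\n", id,
              length(res$modules[[id]]$genes), res$modules[[id]]$class,
              which.max(res$modules[[id]]$profile),
              length(res$modules[[id]]$profile)))
cat(sprintf("module genes: %d immature, %d mature\n",
            length(res$immature_genes), length(res$mature_genes)))
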