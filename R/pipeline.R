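#' Run the full integrative maturation analysis on a synthetic dataset
#'
#' Executes every stage in dependency order: data generation, pseudotime
#' module detection, bulk differential expression, signature intersection,
#' ATAC peak processing (normalisation, accessibility floor, differential
#' accessibility, classification, peak-to-gene linking with distance cap),
#' chromatin-expression association statistics and ChIP-overlap enrichment.
#' Stage outputs are written as TSV/BED under \code{outdir} together with a
#' machine-readable \code{summary.json} recording the seed, parameters and
#' headline numbers.
#'
#' @param config [sim_config()] controlling the dataset and the seed.
#' @param outdir Output directory (default: no files written).
#' @param params [module_params()] for the module stage.
#' @param padj_threshold,lfc_threshold Differential thresholds (defaults
#'   0.05 and 1, inclusive).
#' @param rna_floor,atac_floor Normalised expression/accessibility floors
#'   (defaults 10 and 25).
#' @param distance_cap Closest-TSS link distance cap in bp (default 100 kb).
#' @return List with all stage results and the \code{summary} list.
#' @export
run_pipeline <- function(config = sim_config(), outdir = NULL,
                         params = module_params(),
                         padj_threshold = 0.05, lfc_threshold = 1,
                         rna_floor = 10, atac_floor = 25,
                         distance_cap = 100000) {
  data <- simulate_dataset(config, dir = if (is.null(outdir)) NULL else
    file.path(outdir, "data"))

  # --- pseudotime modules -------------------------------------------------
  mods <- detect_modules(data$sc$counts, data$sc$pseudotime, params)

  # --- bulk differential expression (filter, then test) -------------------
  bulk_sf <- size_factors_median_of_ratios(data$bulk$counts)
  bulk_keep <- filter_low_features(
    normalize_counts(data$bulk$counts, bulk_sf), rna_floor)
  bulk_de <- nb_wald_test(data$bulk$counts[bulk_keep, , drop = FALSE],
                          data$bulk$condition, bulk_sf)
  bulk_calls <- call_differential(bulk_de, padj_threshold, lfc_threshold)

  # --- maturation signatures ---------------------------------------------
  signature <- intersect_signatures(mods$mature_genes, mods$immature_genes,
                                    bulk_calls$up, bulk_calls$down)

  # --- ATAC peaks ---------------------------------------------------------
  atac_sf <- size_factors_median_of_ratios(data$atac$counts)
  atac_keep <- filter_low_features(
    normalize_counts(data$atac$counts, atac_sf), atac_floor)
  peaks <- data$atac$peaks[data$atac$peaks$name %in% atac_keep, ,
                           drop = FALSE]
  atac_de <- nb_wald_test(data$atac$counts[peaks$name, , drop = FALSE],
                          data$atac$condition, atac_sf)
  atac_calls <- call_differential(atac_de, padj_threshold, lfc_threshold)
  direction <- stats::setNames(rep("stable", nrow(peaks)), peaks$name)
  direction[atac_calls$up] <- "opening"
  direction[atac_calls$down] <- "closing"

  tracks <- list(promoters = data$genome$promoters,
                 enhancers = data$genome$enhancers,
                 h3k4me1 = data$genome$h3k4me1,
                 genes = data$genome$genes)
  peaks <- classify_peaks(peaks, tracks)
  closest <- link_closest_tss(peaks, data$genome$genes)
  longrange <- link_long_range(peaks, data$genome$enhancers,
                               data$genome$links, closest = closest)
  links <- apply_distance_cap(rbind(closest[!closest$no_gene,
                                            names(longrange)], longrange),
                              distance_cap)

  # --- integration --------------------------------------------------------
  assoc <- associate_genes_peaks(signature, links, direction)
  concordance <- direction_concordance(assoc)
  bound <- chip_bound_regions(peaks, data$atac$chip_rep1,
                              data$atac$chip_rep2)
  enrich <- fisher_enrichment(direction[peaks$name] == "opening", bound)

  summary <- list(
    seed = config$seed,
    params = list(n_bins = params$n_bins,
                  min_cells_per_bin = params$min_cells_per_bin,
                  min_deviation = params$min_deviation,
                  k_initial = params$k_initial, merge_r = params$merge_r,
                  padj_threshold = padj_threshold,
                  lfc_threshold = lfc_threshold,
                  rna_floor = rna_floor, atac_floor = atac_floor,
                  distance_cap = distance_cap),
    n_modules = length(mods$modules),
    n_immature_modules = sum(vapply(mods$modules, `[[`, character(1),
                                    "class") == "immature"),
    n_mature_modules = sum(vapply(mods$modules, `[[`, character(1),
                                  "class") == "mature"),
    n_immature_module_genes = length(mods$immature_genes),
    n_mature_module_genes = length(mods$mature_genes),
    n_bulk_up = length(bulk_calls$up), n_bulk_down = length(bulk_calls$down),
    signature_mature = length(signature$mature),
    signature_immature = length(signature$immature),
    n_peaks_retained = nrow(peaks),
    n_opening = sum(direction == "opening"),
    n_closing = sum(direction == "closing"),
    concordance = concordance,
    enrichment = list(odds_ratio = enrich$odds_ratio, p = enrich$p))

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    membership <- do.call(rbind, lapply(names(mods$modules), function(id)
      data.frame(module = id, gene_id = mods$modules[[id]]$genes,
                 class = mods$modules[[id]]$class,
                 stringsAsFactors = FALSE)))
    write_tsv_plain(membership, file.path(outdir, "module_membership.tsv"))
    write_tsv_plain(bulk_de, file.path(outdir, "bulk_differential.tsv"))
    write_tsv_plain(atac_de, file.path(outdir, "atac_differential.tsv"))
    write_tsv_plain(data.frame(peaks, direction = direction[peaks$name]),
                    file.path(outdir, "peaks_classified.tsv"))
    write_tsv_plain(links, file.path(outdir, "peak_gene_links.tsv"))
    write_tsv_plain(assoc, file.path(outdir, "gene_peak_associations.tsv"))
    write_tsv_plain(concordance, file.path(outdir, "concordance.tsv"))
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
  }

  list(data = data, modules = mods, bulk_de = bulk_de,
       bulk_calls = bulk_calls, signature = signature, peaks = peaks,
       atac_de = atac_de, direction = direction, links = links,
       associations = assoc, concordance = concordance,
       enrichment = enrich, summary = summary)
}
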