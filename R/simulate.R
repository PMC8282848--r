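# Synthetic astrocyte-maturation data with known ground truth.
#
# The generator emulates a complete maturation experiment end-to-end: a 1-D differentiation
# trajectory sampled by scRNA-seq (six temporally patterned gene archetypes
# plus flat background genes under negative-binomial noise), a two-condition
# bulk RNA-seq experiment with direction-consistent effects, a two-condition
# ATAC-seq experiment whose opening/closing peaks are coupled to the gene
# classes, and the annotation tracks (promoters, enhancers, H3K4me1,
# long-range links, ChIP replicate peak sets) the regulatory-element module
# consumes. Conditions are labelled "early" (immature, P4-like) and "late"
# (mature, adult-like) so that factor level order - and hence the sign of
# log2 fold changes (late vs early) - does not depend on the locale.

# Archetype mean shapes over pseudotime t in [0,1]: multiplicative factors
# between 0.1 (floor) and 1. Four shapes peak before t = 0.75 (immature
# patterns), two at the end (mature patterns).
archetype_shapes <- list(
  early_decline   = function(t) 0.1 + 0.9 * exp(-t / 0.15),
  early_peak      = function(t) 0.1 + 0.9 * exp(-((t - 0.15) / 0.08)^2),
  mid_peak        = function(t) 0.1 + 0.9 * exp(-((t - 0.4) / 0.1)^2),
  plateau_decline = function(t) 0.1 + 0.9 / (1 + exp((t - 0.6) / 0.07)),
  late_rise       = function(t) 0.1 + 0.9 / (1 + exp(-(t - 0.55) / 0.1)),
  late_switch     = function(t) 0.1 + 0.9 / (1 + exp(-(t - 0.85) / 0.04))
)

archetype_classes <- c(early_decline = "immature", early_peak = "immature",
                       mid_peak = "immature", plateau_decline = "immature",
                       late_rise = "mature", late_switch = "mature")

#' Simulation configuration
#'
#' Defaults define the reference synthetic maturation scenario: 2000 genes x
#' 1500 cells along a uniform pseudotime trajectory, six archetypes split
#' 4 immature / 2 mature in roughly the 71:29 gene-count ratio of the
#' immature and mature module genes, plus low-expressed flat background
#' genes; two-condition bulk counts at fold 4; ATAC peaks whose opening
#' (closing) direction is attached to 71% of mature (50% of immature) genes.
#'
#' @param seed Integer seed; every generator stage derives its own stream
#'   from it (genome +1, single-cell +2, bulk +3, ATAC +4).
#' @param n_genes,n_cells Genes and cells in the single-cell matrix.
#' @param n_bulk_reps Bulk replicates per condition.
#' @param archetype_spec Data frame with columns \code{shape} (a name in
#'   \code{archetype_shapes}), \code{count}, \code{class}
#'   (immature/mature).
#' @param flat_gene_count Flat background genes; archetype counts plus
#'   \code{flat_gene_count} must equal \code{n_genes}.
#' @param nb_dispersion Single-cell NB dispersion alpha
#'   (variance \code{m + alpha m^2}).
#' @param bulk_dispersion,atac_dispersion NB dispersion of bulk RNA and ATAC
#'   replicates.
#' @param bulk_fold Bulk fold change of maturation genes between conditions.
#' @param atac_fold Accessibility ratio of differential peaks (>= 4 makes
#'   them unambiguous "opening"/"closing" events).
#' @param library_size_range Range of expected total counts per cell.
#' @param bulk_depth_range,atac_depth_range Relative per-sample depth factor
#'   ranges.
#' @param n_chroms,chrom_length,gene_spacing Toy genome layout; genes are
#'   placed on a regular grid with jitter, spacing >= 10 kb enforced.
#' @param n_peaks Total ATAC peaks (one promoter peak per gene, one
#'   differential enhancer peak per selected maturation gene, the remainder
#'   stable enhancer/distal peaks).
#' @param frac_mature_opening Probability a mature gene carries an opening
#'   peak (default 0.71).
#' @param frac_immature_closing Probability an immature gene carries a
#'   closing peak (default 0.50).
#' @param frac_h3k4me1 Fraction of enhancer regions also carrying the
#'   H3K4me1 mark.
#' @param frac_k_only Fraction of genes with an H3K4me1-only region (no
#'   enhancer-build interval), exercising the H3K4me1 classification path.
#' @param frac_enhancer_longrange Fraction of enhancer regions linked
#'   long-range to a non-nearest gene.
#' @param chip_frac_opening,chip_frac_background Probability an opening
#'   (resp. any other) peak carries a ChIP interval in both replicates.
#' @param atac_reps Named vector: ATAC replicates per condition (default
#'   3 early, 4 late).
#' @return A validated list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000L,
                       n_cells = 1500L,
                       n_bulk_reps = 3L,
                       archetype_spec = default_archetype_spec(),
                       flat_gene_count = 1300L,
                       nb_dispersion = 0.3,
                       bulk_dispersion = 0.05,
                       atac_dispersion = 0.05,
                       bulk_fold = 4,
                       atac_fold = 4,
                       library_size_range = c(2000, 5000),
                       bulk_depth_range = c(0.7, 1.3),
                       atac_depth_range = c(0.7, 1.3),
                       n_chroms = 4L,
                       chrom_length = 25500000,
                       gene_spacing = 50000,
                       n_peaks = 6000L,
                       frac_mature_opening = 0.71,
                       frac_immature_closing = 0.50,
                       frac_h3k4me1 = 0.5,
                       frac_k_only = 0.2,
                       frac_enhancer_longrange = 0.05,
                       chip_frac_opening = 0.4,
                       chip_frac_background = 0.05,
                       atac_reps = c(early = 3L, late = 4L)) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

default_archetype_spec <- function() {
  data.frame(shape = names(archetype_shapes),
             count = c(150L, 125L, 100L, 125L, 120L, 80L),
             class = unname(archetype_classes),
             stringsAsFactors = FALSE)
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_genes > 0, cfg$n_cells > 0, cfg$n_bulk_reps >= 2,
            cfg$nb_dispersion > 0, cfg$bulk_dispersion > 0,
            cfg$atac_dispersion > 0, cfg$n_peaks > 0,
            length(cfg$library_size_range) == 2,
            cfg$library_size_range[1] > 0,
            diff(cfg$library_size_range) >= 0)
  probs <- c(cfg$frac_mature_opening, cfg$frac_immature_closing,
             cfg$frac_h3k4me1, cfg$frac_k_only, cfg$frac_enhancer_longrange,
             cfg$chip_frac_opening, cfg$chip_frac_background)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  spec <- cfg$archetype_spec
  if (!all(spec$shape %in% names(archetype_shapes)))
    stop("unknown archetype shape: ",
         setdiff(spec$shape, names(archetype_shapes))[1])
  if (sum(spec$count) + cfg$flat_gene_count != cfg$n_genes)
    stop("archetype gene counts + flat_gene_count must equal n_genes")
  if (cfg$gene_spacing < 10000)
    stop("gene_spacing must be >= 10 kb")
  invisible(cfg)
}

# Ridge-regularised least-squares multipliers that flatten the summed
# archetype output along t. Keeps the cell's expected composition stationary
# so depth normalisation does not impose a pseudotime trend on flat genes.
archetype_balance <- function(spec) {
  tg <- seq(0, 1, length.out = 201)
  A <- vapply(seq_len(nrow(spec)), function(k)
    spec$count[k] * archetype_shapes[[spec$shape[k]]](tg), numeric(201))
  lam <- 0.02 * mean(diag(crossprod(A)))
  target <- mean(A %*% rep(1, ncol(A)))
  m <- solve(crossprod(A) + lam * diag(ncol(A)),
             crossprod(A, rep(target, length(tg))) + lam * rep(1, ncol(A)))
  stats::setNames(pmax(drop(m), 0.05), spec$shape)
}

#' Simulate the toy genome and annotation tracks
#'
#' Places genes on a jittered grid (spacing >= 10 kb), builds the promoter
#' track (TSS +/- 500 bp), an enhancer region ~6 kb downstream of each TSS,
#' H3K4me1 intervals over a fraction of enhancers plus H3K4me1-only regions
#' ~8-9 kb upstream of a fraction of genes, and a long-range link table
#' attaching a fraction of enhancer regions to a non-nearest gene.
#'
#' @param config A [sim_config()].
#' @return List: \code{genes} (gene models), \code{promoters},
#'   \code{enhancers}, \code{h3k4me1} (interval data frames),
#'   \code{links} (region -> gene table).
#' @export
simulate_genome <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  per_chrom <- ceiling(config$n_genes / config$n_chroms)
  first_tss <- config$gene_spacing
  needed <- first_tss + per_chrom * config$gene_spacing + 25000
  if (needed > config$chrom_length)
    stop("chrom_length too small to place ", per_chrom,
         " genes at spacing ", config$gene_spacing)
  jit_max <- min(2500, config$gene_spacing / 10)
  ids <- sprintf("g%04d", seq_len(config$n_genes))
  chrom <- sprintf("chr%d", rep(seq_len(config$n_chroms),
                                each = per_chrom)[seq_len(config$n_genes)])
  idx <- sequence(rle(chrom)$lengths) - 1L
  tss <- first_tss + idx * config$gene_spacing +
    floor(stats::runif(config$n_genes, -jit_max, jit_max))
  genes <- data.frame(gene_id = ids, chrom = chrom, tss = tss,
                      strand = sample(c("+", "-"), config$n_genes,
                                      replace = TRUE),
                      stringsAsFactors = FALSE)
  promoters <- genomic_intervals(chrom, tss - 500, tss + 500,
                                 name = paste0("prom_", ids))
  enhancers <- genomic_intervals(chrom, tss + 6000, tss + 7000,
                                 name = paste0("enh_", ids))
  with_k <- stats::runif(config$n_genes) < config$frac_h3k4me1
  k_only <- stats::runif(config$n_genes) < config$frac_k_only
  h3k4me1 <- rbind(
    genomic_intervals(chrom[with_k], tss[with_k] + 6100, tss[with_k] + 6900,
                      name = paste0("k4_enh_", ids[with_k])),
    genomic_intervals(chrom[k_only], tss[k_only] - 9000, tss[k_only] - 8000,
                      name = paste0("k4_only_", ids[k_only])))
  lr <- which(stats::runif(config$n_genes) < config$frac_enhancer_longrange)
  target <- vapply(lr, function(i) {
    pool <- setdiff(which(chrom == chrom[i] & abs(tss - tss[i]) >
                            1.5 * config$gene_spacing), i)
    if (!length(pool)) pool <- setdiff(seq_along(ids), i)
    ids[sample(pool, 1)]
  }, character(1))
  links <- data.frame(region = paste0("enh_", ids[lr]), gene_id = target,
                      stringsAsFactors = FALSE)
  list(genes = genes, promoters = promoters, enhancers = enhancers,
       h3k4me1 = h3k4me1, links = links)
}

#' Simulate the single-cell trajectory counts
#'
#' Pseudotime is Uniform(0,1) per cell. Each patterned gene follows one of
#' six archetype mean shapes; flat genes are constant. Expected counts
#' factorise as cell library factor x gene baseline x shape(t); counts are
#' negative binomial with dispersion \code{nb_dispersion}. Per-archetype
#' baseline multipliers keep the summed output approximately constant along
#' t (see \code{archetype_balance}); flat genes are low-expressed background
#' genes. Cells additionally carry a stage ("early" for t < 0.5, "late"
#' otherwise) and a replicate-of-origin label used by the pseudo-bulk
#' analysis.
#'
#' @param config A [sim_config()].
#' @return List: \code{counts} (genes x cells integer matrix),
#'   \code{pseudotime} (named per-cell vector), \code{cell_metadata}
#'   (cell, stage, sample), \code{truth} (gene_archetype, gene_class,
#'   cell_pseudotime).
#' @export
simulate_sc_pseudotime <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed + 2L)
  spec <- config$archetype_spec
  n_pat <- sum(spec$count)
  arch <- c(rep(spec$shape, spec$count),
            rep("flat", config$flat_gene_count))
  gene_ids <- sprintf("g%04d", seq_len(config$n_genes))
  cell_ids <- sprintf("c%04d", seq_len(config$n_cells))
  t <- stats::runif(config$n_cells)
  mult <- archetype_balance(spec)
  baseline <- numeric(config$n_genes)
  pat <- arch != "flat"
  baseline[pat] <- stats::rlnorm(n_pat, 0, 0.7) * mult[arch[pat]]
  baseline[!pat] <- stats::rlnorm(config$flat_gene_count, log(0.025), 0.3)
  tgrid <- seq(0, 1, length.out = 101)
  sbar <- vapply(arch, function(a)
    if (a == "flat") 1 else mean(archetype_shapes[[a]](tgrid)), numeric(1))
  total_cell <- stats::runif(config$n_cells, config$library_size_range[1],
                             config$library_size_range[2])
  libfac <- total_cell / sum(baseline * sbar)
  shape_mat <- matrix(1, nrow = config$n_genes, ncol = config$n_cells)
  for (a in unique(arch[pat])) {
    rows <- which(arch == a)
    shape_mat[rows, ] <- matrix(archetype_shapes[[a]](t),
                                nrow = length(rows), ncol = config$n_cells,
                                byrow = TRUE)
  }
  mu <- baseline * shape_mat
  mu <- sweep(mu, 2, libfac, `*`)
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / config$nb_dispersion),
                   nrow = config$n_genes,
                   dimnames = list(gene_ids, cell_ids))
  stage <- ifelse(t < 0.5, "early", "late")
  rep_of <- sample.int(3L, config$n_cells, replace = TRUE)
  meta <- data.frame(cell = cell_ids, stage = stage,
                     sample = paste0(stage, "_", rep_of),
                     stringsAsFactors = FALSE)
  gene_class <- ifelse(arch == "flat", "flat",
                       unname(archetype_classes[arch]))
  list(counts = counts,
       pseudotime = stats::setNames(t, cell_ids),
       cell_metadata = meta,
       truth = list(
         gene_archetype = stats::setNames(arch, gene_ids),
         gene_class = stats::setNames(gene_class, gene_ids),
         cell_pseudotime = stats::setNames(t, cell_ids)))
}

#' Simulate two-condition bulk RNA-seq counts
#'
#' Immature-class genes have mean fold \code{bulk_fold} in the early
#' condition over the late one; mature-class genes the reverse; flat genes
#' equal means. Negative-binomial noise at \code{bulk_dispersion},
#' per-sample depth factors from \code{bulk_depth_range}.
#'
#' @param config A [sim_config()].
#' @param truth Truth list from [simulate_sc_pseudotime()].
#' @return List: \code{counts} (genes x samples), \code{condition} (named
#'   per-sample, "early"/"late").
#' @export
simulate_bulk <- function(config, truth) {
  validate_sim_config(config)
  set.seed(config$seed + 3L)
  cls <- truth$gene_class
  n <- length(cls)
  base <- stats::rlnorm(n, log(100), 1)
  mean_early <- ifelse(cls == "immature", base * config$bulk_fold, base)
  mean_late <- ifelse(cls == "mature", base * config$bulk_fold, base)
  reps <- config$n_bulk_reps
  samples <- c(paste0("early_", seq_len(reps)), paste0("late_", seq_len(reps)))
  condition <- stats::setNames(rep(c("early", "late"), each = reps), samples)
  depth <- stats::runif(2 * reps, config$bulk_depth_range[1],
                        config$bulk_depth_range[2])
  mu <- cbind(matrix(mean_early, n, reps), matrix(mean_late, n, reps))
  mu <- sweep(mu, 2, depth, `*`)
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / config$bulk_dispersion),
                   nrow = n, dimnames = list(names(cls), samples))
  list(counts = counts, condition = condition)
}

#' Simulate two-condition ATAC-seq peaks and ChIP replicate tracks
#'
#' Every gene gets a stable promoter peak at its TSS. With probability
#' \code{frac_mature_opening} a mature gene's enhancer region hosts an
#' opening peak (late-condition mean \code{atac_fold} x the early mean);
#' immature genes analogously host closing peaks with probability
#' \code{frac_immature_closing}. Remaining peaks (up to \code{n_peaks}) are
#' stable and occupy free enhancer regions, H3K4me1-only regions, or distal
#' positions ~14 kb from a TSS. Opening peaks carry a ChIP interval in both
#' replicate tracks with probability \code{chip_frac_opening}; all other
#' peaks at rate \code{chip_frac_background}.
#'
#' @param config A [sim_config()].
#' @param truth Truth list from [simulate_sc_pseudotime()].
#' @param genome Output of [simulate_genome()].
#' @return List: \code{peaks} (interval data frame), \code{counts}
#'   (peaks x samples), \code{condition}, \code{frip} (per sample),
#'   \code{chip_rep1}, \code{chip_rep2} (interval data frames), and
#'   \code{truth} (per-peak direction, class, linked gene, bound flag).
#' @export
simulate_atac <- function(config, truth, genome) {
  validate_sim_config(config)
  set.seed(config$seed + 4L)
  genes <- genome$genes
  cls <- truth$gene_class[genes$gene_id]
  n_genes <- nrow(genes)

  diff_dir <- rep("none", n_genes)
  r <- stats::runif(n_genes)
  diff_dir[cls == "mature" & r < config$frac_mature_opening] <- "opening"
  diff_dir[cls == "immature" & r < config$frac_immature_closing] <- "closing"

  mk <- function(ch, s, e, nm)
    data.frame(chrom = ch, start = s, end = e, name = nm, strand = "*",
               stringsAsFactors = FALSE)
  peaks <- mk(genes$chrom, genes$tss - 250, genes$tss + 250,
              paste0("pk_prom_", genes$gene_id))
  peak_class <- rep("promoter", n_genes)
  peak_gene <- genes$gene_id
  peak_dir <- rep("stable", n_genes)

  dsel <- which(diff_dir != "none")
  peaks <- rbind(peaks, mk(genes$chrom[dsel], genes$tss[dsel] + 6200,
                           genes$tss[dsel] + 6700,
                           paste0("pk_enh_", genes$gene_id[dsel])))
  peak_class <- c(peak_class, rep("enhancer", length(dsel)))
  peak_gene <- c(peak_gene, genes$gene_id[dsel])
  peak_dir <- c(peak_dir, diff_dir[dsel])

  # stable filler peaks on free slots
  k_only_gene <- sub("^k4_only_", "",
                     grep("^k4_only_", genome$h3k4me1$name, value = TRUE))
  free <- rbind(
    data.frame(gene = genes$gene_id[-dsel], slot = "enh",
               stringsAsFactors = FALSE),
    data.frame(gene = k_only_gene, slot = "k", stringsAsFactors = FALSE),
    data.frame(gene = genes$gene_id, slot = "d1", stringsAsFactors = FALSE),
    data.frame(gene = genes$gene_id, slot = "d2", stringsAsFactors = FALSE))
  n_extra <- config$n_peaks - nrow(peaks)
  if (n_extra < 0)
    stop("n_peaks smaller than the number of promoter + differential peaks")
  if (n_extra > nrow(free))
    stop("n_peaks too large for the available peak slots")
  pick <- free[sample.int(nrow(free), n_extra), , drop = FALSE]
  gi <- match(pick$gene, genes$gene_id)
  off <- list(enh = c(6200, 6700), k = c(-8800, -8300),
              d1 = c(14000, 14500), d2 = c(-14500, -14000))
  s <- genes$tss[gi] + vapply(pick$slot, function(x) off[[x]][1], numeric(1))
  e <- genes$tss[gi] + vapply(pick$slot, function(x) off[[x]][2], numeric(1))
  peaks <- rbind(peaks, mk(genes$chrom[gi], s, e,
                           paste0("pk_", pick$slot, "_", pick$gene)))
  peak_class <- c(peak_class,
                  ifelse(pick$slot %in% c("enh", "k"), "enhancer", "distal"))
  peak_gene <- c(peak_gene, pick$gene)
  peak_dir <- c(peak_dir, rep("stable", n_extra))
  validate_intervals(peaks)

  # per-sample counts
  reps <- config$atac_reps
  samples <- c(paste0("early_", seq_len(reps[["early"]])),
               paste0("late_", seq_len(reps[["late"]])))
  condition <- stats::setNames(rep(c("early", "late"), times = reps), samples)
  n_pk <- nrow(peaks)
  base <- stats::rlnorm(n_pk, log(80), 0.8)
  low <- stats::rlnorm(n_pk, log(60), 0.4)
  m_early <- ifelse(peak_dir == "stable", base,
                    ifelse(peak_dir == "closing", low * config$atac_fold, low))
  m_late <- ifelse(peak_dir == "stable", base,
                   ifelse(peak_dir == "opening", low * config$atac_fold, low))
  depth <- stats::runif(length(samples), config$atac_depth_range[1],
                        config$atac_depth_range[2])
  mu <- cbind(matrix(m_early, n_pk, reps[["early"]]),
              matrix(m_late, n_pk, reps[["late"]]))
  mu <- sweep(mu, 2, depth, `*`)
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / config$atac_dispersion),
                   nrow = n_pk, dimnames = list(peaks$name, samples))

  frip <- stats::setNames(stats::runif(length(samples), 0.2, 0.6), samples)

  bound <- ifelse(peak_dir == "opening",
                  stats::runif(n_pk) < config$chip_frac_opening,
                  stats::runif(n_pk) < config$chip_frac_background)
  centre <- interval_centre(peaks)
  chip_rep <- function(tag) {
    sh <- floor(stats::runif(sum(bound), -50, 50))
    genomic_intervals(peaks$chrom[bound], centre[bound] - 100 + sh,
                      centre[bound] + 100 + sh,
                      name = paste0("chip_", tag, "_", peaks$name[bound]))
  }
  list(peaks = peaks, counts = counts, condition = condition, frip = frip,
       chip_rep1 = chip_rep("r1"), chip_rep2 = chip_rep("r2"),
       truth = list(
         peak_direction = stats::setNames(peak_dir, peaks$name),
         peak_class = stats::setNames(peak_class, peaks$name),
         peak_gene = stats::setNames(peak_gene, peaks$name),
         peak_bound = stats::setNames(bound, peaks$name)))
}

#' Piecewise-constant coverage track over peak centres
#'
#' A bedGraph-style track (chrom, start, end, value) with a rectangular
#' signal of the given height over \code{centre +/- halfwidth} of each peak
#' and zero elsewhere, for exercising peak-centred signal matrices.
#'
#' @param peaks Interval data frame.
#' @param height Signal height per peak (recycled).
#' @param halfwidth Half-width of the rectangle in bp.
#' @return data.frame with columns chrom, start, end, value.
#' @export
simulate_coverage <- function(peaks, height = 1, halfwidth = 300) {
  centre <- interval_centre(peaks)
  data.frame(chrom = peaks$chrom,
             start = pmax(centre - halfwidth, 0),
             end = centre + halfwidth,
             value = rep_len(height, nrow(peaks)),
             stringsAsFactors = FALSE)
}

#' Generate the complete synthetic dataset
#'
#' Runs all generator stages in order (genome, single-cell, bulk, ATAC) and
#' optionally materialises every table through the package's file formats
#' (BED + TSV), so the full pipeline can be driven from files alone.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory; created if missing.
#' @return List with \code{genome}, \code{sc}, \code{bulk}, \code{atac} and
#'   a merged \code{truth}.
#' @export
simulate_dataset <- function(config = sim_config(), dir = NULL) {
  genome <- simulate_genome(config)
  sc <- simulate_sc_pseudotime(config)
  bulk <- simulate_bulk(config, sc$truth)
  atac <- simulate_atac(config, sc$truth, genome)
  truth <- c(sc$truth, atac$truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_gene_models(genome$genes, file.path(dir, "genes.tsv"))
    write_bed(genome$promoters, file.path(dir, "promoters.bed"))
    write_bed(genome$enhancers, file.path(dir, "enhancers.bed"))
    write_bed(genome$h3k4me1, file.path(dir, "h3k4me1.bed"))
    write_links(genome$links, file.path(dir, "longrange_links.tsv"))
    write_count_matrix(sc$counts, file.path(dir, "sc_counts.tsv"),
                       feature_col = "gene_id")
    write_tsv_plain(data.frame(cell = names(sc$pseudotime),
                               pseudotime = unname(sc$pseudotime)),
                    file.path(dir, "pseudotime.tsv"))
    write_tsv_plain(sc$cell_metadata, file.path(dir, "cell_metadata.tsv"))
    write_count_matrix(bulk$counts, file.path(dir, "bulk_counts.tsv"),
                       feature_col = "gene_id")
    write_tsv_plain(data.frame(sample = names(bulk$condition),
                               condition = unname(bulk$condition)),
                    file.path(dir, "bulk_condition.tsv"))
    write_bed(atac$peaks, file.path(dir, "peaks.bed"))
    write_count_matrix(atac$counts, file.path(dir, "atac_counts.tsv"),
                       feature_col = "peak_id")
    write_tsv_plain(data.frame(sample = names(atac$condition),
                               condition = unname(atac$condition),
                               frip = unname(atac$frip[names(atac$condition)])),
                    file.path(dir, "atac_samples.tsv"))
    write_bed(atac$chip_rep1, file.path(dir, "chip_rep1.bed"))
    write_bed(atac$chip_rep2, file.path(dir, "chip_rep2.bed"))
    write_tsv_plain(data.frame(gene_id = names(truth$gene_class),
                               archetype = unname(truth$gene_archetype),
                               class = unname(truth$gene_class)),
                    file.path(dir, "truth_genes.tsv"))
    write_tsv_plain(data.frame(peak_id = names(truth$peak_direction),
                               direction = unname(truth$peak_direction),
                               class = unname(truth$peak_class),
                               gene_id = unname(truth$peak_gene),
                               bound = unname(truth$peak_bound)),
                    file.path(dir, "truth_peaks.tsv"))
  }
  list(genome = genome, sc = sc, bulk = bulk, atac = atac, truth = truth)
}
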