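# Pseudotime gene-module detection: bin cells along the trajectory, build
# mean-centred bin profiles, keep dynamic genes, cluster them hierarchically
# and merge correlated clusters, then label each module immature or mature
# by where its profile peaks.

#' Module-detection parameters
#'
#' Defaults: 20 equal-range pseudotime bins,
#' bins with more than 10 cells retained, genes with maximum centred
#' deviation below 0.2 removed, 50 initial hierarchical clusters. The merge
#' correlation (0.8) automates the otherwise manual merging of similar
#' modules; \code{late_fraction} (0.25) defines the trailing window of bins
#' whose peak marks a module as mature; \code{dynamic_padj} is the BH
#' threshold of the per-gene dynamic test.
#'
#' @param n_bins Number of equal-range pseudotime bins.
#' @param min_cells_per_bin A bin is retained iff it has strictly more cells.
#' @param min_deviation Centred-profile deviation floor for dynamic genes.
#' @param k_initial Initial hierarchical clusters (reduced to the gene count
#'   when fewer genes are available).
#' @param merge_r Pearson correlation at or above which module mean profiles
#'   are iteratively merged.
#' @param late_fraction Fraction of trailing bins defining the "mature"
#'   peak window.
#' @param dynamic_padj BH-adjusted p threshold of the dynamic-gene test.
#' @return List of class \code{module_params}.
#' @export
module_params <- function(n_bins = 20L, min_cells_per_bin = 10L,
                          min_deviation = 0.2, k_initial = 50L,
                          merge_r = 0.8, late_fraction = 0.25,
                          dynamic_padj = 0.05) {
  stopifnot(n_bins >= 2, min_deviation >= 0, k_initial >= 1,
            late_fraction > 0, late_fraction < 1)
  structure(as.list(environment()), class = "module_params")
}

#' Depth-normalised log expression for the trajectory analysis
#'
#' Variance-stabilising stand-in used before binning: counts are scaled to
#' the median cell total and log1p-transformed,
#' \code{log1p(count / cell_total * median(cell_total))}.
#'
#' @param counts Genes x cells matrix of raw counts.
#' @return Matrix of the same shape.
#' @export
sc_normalize <- function(counts) {
  tot <- colSums(counts)
  if (any(tot == 0)) stop("cell with zero total counts")
  log1p(sweep(counts, 2, tot, `/`) * stats::median(tot))
}

#' Assign cells to equal-range pseudotime bins
#'
#' Bin width is \code{(max - min) / n_bins}; the bin index is
#' \code{floor((t - min) / width)}, with \code{t = max} assigned to the last
#' bin. Indices are 0-based.
#'
#' @param pseudotime Numeric per-cell pseudotime (names preserved).
#' @param n_bins Number of bins.
#' @return Integer vector of bin indices in \code{[0, n_bins)}.
#' @export
bin_pseudotime <- function(pseudotime, n_bins) {
  rng <- range(pseudotime)
  if (diff(rng) <= 0) stop("pseudotime has no span; all values equal")
  width <- diff(rng) / n_bins
  idx <- pmin(as.integer(floor((pseudotime - rng[1]) / width)),
              n_bins - 1L)
  stats::setNames(idx, names(pseudotime))
}

#' Per-gene dynamic-expression test across pseudotime bins
#'
#' Kruskal-Wallis test (tie-corrected) of normalised expression across the
#' retained bins, BH-adjusted over genes. A bin is retained iff it holds
#' more than \code{min_cells_per_bin} cells.
#'
#' @param expr Genes x cells normalised expression matrix.
#' @param bins 0-based bin index per cell (see [bin_pseudotime()]).
#' @param params [module_params()].
#' @return data.frame: gene_id, pvalue, padj.
#' @export
dynamic_gene_test <- function(expr, bins, params = module_params()) {
  stopifnot(ncol(expr) == length(bins))
  keep <- retained_bins(bins, params)
  if (length(keep) < 2) stop("fewer than 2 retained pseudotime bins")
  sel <- bins %in% keep
  g <- factor(bins[sel])
  p <- apply(expr[, sel, drop = FALSE], 1, function(x) {
    if (all(x == x[1])) return(1)  # constant gene: every ranking tied
    stats::kruskal.test(x, g)$p.value
  })
  data.frame(gene_id = rownames(expr), pvalue = p, padj = bh_adjust(p),
             row.names = NULL, stringsAsFactors = FALSE)
}

retained_bins <- function(bins, params) {
  tab <- table(bins)
  as.integer(names(tab))[tab > params$min_cells_per_bin]
}

#' Mean-centred per-gene bin profiles
#'
#' For each gene, the mean normalised expression per retained bin, centred
#' on the mean over all retained bins (each row sums to zero).
#'
#' @inheritParams dynamic_gene_test
#' @return Genes x retained-bins matrix; column names are the bin indices.
#' @export
bin_mean_profiles <- function(expr, bins, params = module_params()) {
  stopifnot(ncol(expr) == length(bins))
  keep <- retained_bins(bins, params)
  if (length(keep) < 2) stop("fewer than 2 retained pseudotime bins")
  bm <- vapply(keep, function(b)
    rowMeans(expr[, bins == b, drop = FALSE]), numeric(nrow(expr)))
  if (is.null(dim(bm))) bm <- matrix(bm, nrow = 1)
  dimnames(bm) <- list(rownames(expr), keep)
  bm - rowMeans(bm)
}

#' Remove genes with minimal profile deviation
#'
#' A gene is retained iff the maximum absolute value of its centred profile
#' is at least \code{min_deviation} (boundary inclusive).
#'
#' @param profiles Centred profile matrix from [bin_mean_profiles()].
#' @param params [module_params()].
#' @return The retained rows of \code{profiles}.
#' @export
deviation_filter <- function(profiles, params = module_params()) {
  keep <- apply(abs(profiles), 1, max) >= params$min_deviation
  profiles[keep, , drop = FALSE]
}

#' Hierarchical clustering of gene profiles into initial modules
#'
#' Agglomerative clustering of profile rows (Euclidean distance,
#' \code{ward.D2} linkage), cut at \code{k_initial} clusters (reduced to
#' the number of genes when fewer).
#'
#' @param profiles Centred profile matrix.
#' @param params [module_params()].
#' @return List of modules; each has \code{genes} (character) and
#'   \code{profile} (mean of member rows).
#' @export
cluster_modules <- function(profiles, params = module_params()) {
  if (nrow(profiles) == 0) stop("empty profile matrix")
  k <- min(params$k_initial, nrow(profiles))
  cl <- if (nrow(profiles) == 1) 1L else
    stats::cutree(stats::hclust(stats::dist(profiles), method = "ward.D2"),
                  k = k)
  lapply(split(seq_len(nrow(profiles)), cl), function(ix)
    list(genes = rownames(profiles)[ix],
         profile = colMeans(profiles[ix, , drop = FALSE])))
}

#' Iteratively merge modules with correlated mean profiles
#'
#' While the highest pairwise Pearson correlation of module mean profiles is
#' at least \code{merge_r}, the best pair is merged and mean profiles are
#' recomputed. Ties break towards the lexicographically first pair of module
#' positions, and the merged module keeps the lower position, so the result
#' is deterministic.
#'
#' @param modules List of modules from [cluster_modules()].
#' @param profiles The centred profile matrix the modules were built from
#'   (needed to recompute mean profiles after merging).
#' @param params [module_params()].
#' @return Merged list of modules.
#' @export
merge_modules <- function(modules, profiles, params = module_params()) {
  if (length(modules) == 0) stop("no modules to merge")
  mods <- modules
  repeat {
    if (length(mods) < 2) break
    means <- t(vapply(mods, `[[`, numeric(length(mods[[1]]$profile)),
                      "profile"))
    cm <- suppressWarnings(stats::cor(t(means)))
    cm[!is.finite(cm)] <- -Inf
    diag(cm) <- -Inf
    best <- max(cm)
    if (best < params$merge_r) break
    hit <- which(cm == best, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    i <- hit[1, 1]; j <- hit[1, 2]
    genes <- c(mods[[i]]$genes, mods[[j]]$genes)
    mods[[i]] <- list(genes = genes,
                      profile = colMeans(profiles[genes, , drop = FALSE]))
    mods[[j]] <- NULL
  }
  mods
}

#' Label modules as immature- or mature-type
#'
#' A module is mature iff the argmax of its mean profile lies in the last
#' \code{ceiling(late_fraction * b)} of the \code{b} retained bins (the
#' trajectory end); ties at the maximum break towards the later bin.
#'
#' @param modules List of modules with mean profiles.
#' @param params [module_params()].
#' @return The modules, each with an added \code{class} field.
#' @export
classify_modules <- function(modules, params = module_params()) {
  lapply(modules, function(m) {
    b <- length(m$profile)
    late <- (b - ceiling(params$late_fraction * b) + 1):b
    peak <- max(which(m$profile == max(m$profile)))
    m$class <- if (peak %in% late) "mature" else "immature"
    m
  })
}

#' Detect pseudotime gene modules
#'
#' The full procedure: normalise (optional), bin cells, test each gene for
#' dynamic expression, build centred bin profiles, drop low-deviation genes,
#' cluster into initial modules, merge correlated modules, classify each as
#' immature or mature.
#'
#' @param counts Genes x cells matrix (raw counts when
#'   \code{normalize = TRUE}, otherwise already-normalised expression).
#' @param pseudotime Per-cell pseudotime, aligned with the columns.
#' @param params [module_params()].
#' @param normalize Apply [sc_normalize()] first (default TRUE).
#' @return List: \code{modules} (each with genes, profile, class),
#'   \code{immature_genes}, \code{mature_genes}, \code{dynamic}
#'   (the dynamic-test table), \code{profiles} (retained centred profiles).
#' @export
detect_modules <- function(counts, pseudotime, params = module_params(),
                           normalize = TRUE) {
  stopifnot(ncol(counts) == length(pseudotime))
  expr <- if (normalize) sc_normalize(counts) else counts
  bins <- bin_pseudotime(pseudotime, params$n_bins)
  dyn <- dynamic_gene_test(expr, bins, params)
  prof <- bin_mean_profiles(expr, bins, params)
  keep <- dyn$gene_id[!is.na(dyn$padj) & dyn$padj <= params$dynamic_padj]
  prof <- deviation_filter(prof[keep, , drop = FALSE], params)
  if (nrow(prof) == 0)
    return(list(modules = list(), immature_genes = character(0),
                mature_genes = character(0), dynamic = dyn,
                profiles = prof))
  mods <- cluster_modules(prof, params)
  mods <- merge_modules(mods, prof, params)
  mods <- classify_modules(mods, params)
  names(mods) <- sprintf("module_%02d", seq_along(mods))
  cls <- vapply(mods, `[[`, character(1), "class")
  list(modules = mods,
       immature_genes = unlist(lapply(mods[cls == "immature"], `[[`,
                                      "genes"), use.names = FALSE),
       mature_genes = unlist(lapply(mods[cls == "mature"], `[[`, "genes"),
                             use.names = FALSE),
       dynamic = dyn, profiles = prof)
}
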