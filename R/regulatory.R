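# ATAC regulatory-element processing: peak classification by annotation
# overlap, peak-to-gene linking (closest TSS plus long-range interactions),
# frip normalisation and peak-centred signal matrices.

#' Classify peaks as promoter, enhancer or distal
#'
#' Classification is sequential: a peak is a
#' promoter if it overlaps the promoter track or lies within
#' \code{tss_window} bp of a TSS (window 0 disables the rescue); otherwise
#' an enhancer if it overlaps the enhancer track or the H3K4me1 track;
#' otherwise distal. Every peak receives exactly one class.
#'
#' @param peaks Interval data frame of peaks.
#' @param tracks List with interval data frames \code{promoters},
#'   \code{enhancers}, \code{h3k4me1}, and optionally \code{genes} (gene
#'   models, needed when \code{tss_window > 0}).
#' @param tss_window Promoter-rescue distance in bp around annotated TSSs
#'   (default 0: off).
#' @return The peaks with an added \code{class} column.
#' @export
classify_peaks <- function(peaks, tracks, tss_window = 0) {
  validate_intervals(peaks)
  is_prom <- overlaps_any(peaks, tracks$promoters)
  if (tss_window > 0) {
    if (is.null(tracks$genes))
      stop("tss_window > 0 requires gene models in tracks$genes")
    g <- tracks$genes
    tssint <- genomic_intervals(g$chrom, pmax(g$tss - tss_window, 0),
                                g$tss + tss_window)
    is_prom <- is_prom | overlaps_any(peaks, tssint)
  }
  is_enh <- overlaps_any(peaks, tracks$enhancers) |
    overlaps_any(peaks, tracks$h3k4me1)
  peaks$class <- ifelse(is_prom, "promoter",
                        ifelse(is_enh, "enhancer", "distal"))
  peaks
}

#' Link each peak to its closest TSS
#'
#' The linked gene minimises \code{|TSS - peak centre|} on the peak's
#' chromosome (centre = \code{floor((start + end) / 2)}); equidistant TSSs
#' break towards the lexicographically smaller gene id. The distance is
#' signed in gene orientation: negative when the peak lies upstream of the
#' TSS. Peaks on a chromosome without genes get an \code{NA} gene and are
#' flagged.
#'
#' @param peaks Interval data frame (named peaks).
#' @param genes Gene models (gene_id, chrom, tss, strand).
#' @return data.frame: peak_id, gene_id, source ("closest_tss"), distance,
#'   no_gene flag.
#' @export
link_closest_tss <- function(peaks, genes) {
  validate_intervals(peaks)
  centre <- interval_centre(peaks)
  out <- data.frame(peak_id = peaks$name, gene_id = NA_character_,
                    source = "closest_tss", distance = NA_real_,
                    no_gene = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(peaks))) {
    cand <- which(genes$chrom == peaks$chrom[i])
    if (!length(cand)) { out$no_gene[i] <- TRUE; next }
    d <- abs(genes$tss[cand] - centre[i])
    best <- cand[d == min(d)]
    best <- best[order(genes$gene_id[best])][1]
    signed <- centre[i] - genes$tss[best]
    if (genes$strand[best] == "-") signed <- -signed
    out$gene_id[i] <- genes$gene_id[best]
    out$distance[i] <- signed
  }
  out
}

#' Long-range peak-to-gene links
#'
#' Non-promoter peaks overlapping a named link-table region are annotated to
#' that region's gene. Links duplicating the peak's closest-TSS link are
#' dropped.
#'
#' @param peaks Classified peaks (with \code{class} column).
#' @param regions Named interval data frame the link table refers to.
#' @param link_table data.frame (region, gene_id).
#' @param closest Optional closest-TSS link table used to drop duplicates.
#' @return data.frame: peak_id, gene_id, source ("long_range"), distance
#'   (NA).
#' @export
link_long_range <- function(peaks, regions, link_table, closest = NULL) {
  stopifnot(!is.null(peaks$class))
  reg_idx <- match(link_table$region, regions$name)
  if (anyNA(reg_idx))
    stop("link table region not found: ",
         link_table$region[is.na(reg_idx)][1])
  cand <- peaks[peaks$class != "promoter", , drop = FALSE]
  out <- list()
  for (k in seq_len(nrow(link_table))) {
    r <- regions[reg_idx[k], ]
    hit <- cand$chrom == r$chrom & cand$start < r$end & r$start < cand$end
    if (any(hit))
      out[[length(out) + 1L]] <- data.frame(
        peak_id = cand$name[hit], gene_id = link_table$gene_id[k],
        source = "long_range", distance = NA_real_,
        stringsAsFactors = FALSE)
  }
  out <- if (length(out)) unique(do.call(rbind, out)) else
    data.frame(peak_id = character(0), gene_id = character(0),
               source = character(0), distance = numeric(0),
               stringsAsFactors = FALSE)
  if (!is.null(closest) && nrow(out))
    out <- out[!(paste(out$peak_id, out$gene_id) %in%
                   paste(closest$peak_id, closest$gene_id)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter closest-TSS links by distance
#'
#' Closest-TSS links farther than \code{cap} bp from the TSS (absolute,
#' boundary inclusive: exactly \code{cap} is kept) are removed; long-range
#' links are never distance-capped.
#'
#' @param links Combined link table.
#' @param cap Distance cap in bp (default 100 kb); \code{Inf} keeps all.
#' @return Filtered link table.
#' @export
apply_distance_cap <- function(links, cap = 100000) {
  drop <- links$source == "closest_tss" & !is.na(links$distance) &
    abs(links$distance) > cap
  links[!drop, , drop = FALSE]
}

#' Normalise signal by the fraction of reads in peaks
#'
#' Divides each sample's values by its frip score to adjust for differences
#' in sequencing quality.
#'
#' @param values Numeric vector/matrix (samples in columns when a matrix).
#' @param frip Frip score(s) in (0, 1]; one per sample column, or a scalar
#'   for a vector.
#' @return Scaled values.
#' @export
frip_normalize <- function(values, frip) {
  if (any(frip <= 0 | frip > 1)) stop("frip scores must lie in (0, 1]")
  if (is.matrix(values)) {
    stopifnot(ncol(values) == length(frip))
    sweep(values, 2, frip, `/`)
  } else {
    values / frip
  }
}

#' Peak-centred binned signal matrix
#'
#' For each peak the window \code{[centre - half_window, centre +
#' half_window)} is split into consecutive bins of \code{bin} bp; each bin
#' value is the summed coverage over its basepairs, frip-normalised.
#' Coverage is a bedGraph-style table (chrom, start, end, value); positions
#' it does not cover read as zero, and windows clipped at the chromosome
#' start are zero-filled on the left.
#'
#' @param coverage data.frame (chrom, start, end, value).
#' @param peaks Interval data frame.
#' @param half_window Half window in bp (default 1000).
#' @param bin Bin width in bp (default 20); must divide \code{2 *
#'   half_window}.
#' @param frip Frip score applied to the whole track (default 1).
#' @return Peaks x bins numeric matrix.
#' @export
signal_matrix <- function(coverage, peaks, half_window = 1000, bin = 20,
                          frip = 1) {
  stopifnot((2 * half_window) %% bin == 0)
  n_bins <- as.integer(2 * half_window / bin)
  centre <- interval_centre(peaks)
  out <- matrix(0, nrow(peaks), n_bins,
                dimnames = list(peaks$name, NULL))
  for (i in seq_len(nrow(peaks))) {
    w0 <- centre[i] - half_window
    cov_i <- coverage[coverage$chrom == peaks$chrom[i] &
                        coverage$start < w0 + 2 * half_window &
                        coverage$end > w0, , drop = FALSE]
    if (!nrow(cov_i)) next
    for (b in seq_len(n_bins)) {
      b0 <- w0 + (b - 1) * bin
      b1 <- b0 + bin
      if (b1 <= 0) next  # clipped past chromosome start: zero fill
      ov <- pmin(cov_i$end, b1) - pmax(cov_i$start, max(b0, 0))
      out[i, b] <- sum(cov_i$value * pmax(ov, 0))
    }
  }
  frip_normalize(out, rep(frip, n_bins))
}
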