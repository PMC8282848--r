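# Chromatin-expression association statistics: per-gene differential-peak
# tallies, direction concordance, rank-sum contrasts, peak-deficit analysis
# and replicate-consistent ChIP-overlap enrichment.

#' Tally linked differential peaks per signature gene
#'
#' For every gene of the signature, counts the linked peaks by direction
#' (opening / closing / stable). Genes with no links get zero counts. The
#' \code{has_differential} flag is true iff the gene has at least one linked
#' opening or closing peak.
#'
#' @param signature A \code{signature_set} (see [intersect_signatures()]),
#'   or any list with \code{mature} and \code{immature} gene vectors.
#' @param links Link table (peak_id, gene_id).
#' @param peak_direction Named vector: direction per peak id
#'   ("opening"/"closing"/"stable").
#' @return data.frame: gene_id, class, opening, closing, stable,
#'   has_differential.
#' @export
associate_genes_peaks <- function(signature, links, peak_direction) {
  unknown <- setdiff(links$peak_id, names(peak_direction))
  if (length(unknown))
    stop("link to unknown peak: ", unknown[1])
  genes <- data.frame(
    gene_id = c(signature$immature, signature$mature),
    class = rep(c("immature", "mature"),
                c(length(signature$immature), length(signature$mature))),
    stringsAsFactors = FALSE)
  links <- links[links$gene_id %in% genes$gene_id, , drop = FALSE]
  dir <- peak_direction[links$peak_id]
  cnt <- function(d) {
    tab <- table(factor(links$gene_id[dir == d], levels = genes$gene_id))
    as.integer(tab)
  }
  genes$opening <- cnt("opening")
  genes$closing <- cnt("closing")
  genes$stable <- cnt("stable")
  genes$has_differential <- (genes$opening + genes$closing) > 0
  genes
}

#' Direction-concordance fractions per gene class
#'
#' Per class: the fraction of genes with at least one linked differential
#' peak; among those, the fraction whose opening peaks outnumber closing
#' peaks ("predominantly opening") and the converse. Ties (opening ==
#' closing) are excluded from both predominance numerator and denominator.
#'
#' @param associations Output of [associate_genes_peaks()].
#' @return data.frame keyed by class: n_genes, frac_with_differential,
#'   frac_predominantly_opening, frac_predominantly_closing.
#' @export
direction_concordance <- function(associations) {
  cls <- unique(associations$class)
  rows <- lapply(cls, function(cl) {
    a <- associations[associations$class == cl, , drop = FALSE]
    if (nrow(a) == 0) stop("empty gene class: ", cl)
    hd <- a[a$has_differential, , drop = FALSE]
    untied <- hd[hd$opening != hd$closing, , drop = FALSE]
    data.frame(class = cl, n_genes = nrow(a),
               frac_with_differential = nrow(hd) / nrow(a),
               frac_predominantly_opening =
                 if (nrow(untied)) mean(untied$opening > untied$closing)
                 else NA_real_,
               frac_predominantly_closing =
                 if (nrow(untied)) mean(untied$closing > untied$opening)
                 else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Wilcoxon rank-sum test
#'
#' Reports the rank-sum statistic W of the first sample and a two-sided p:
#' exact by complete enumeration of rank assignments when the total sample
#' size is at most 12 and there are no ties (two-sided p doubles the
#' smaller tail, capped at 1), otherwise the normal approximation with tie
#' and continuity correction.
#'
#' @param x,y Numeric samples (non-empty).
#' @return List: \code{W} (rank sum of x), \code{p}, \code{method}.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty input sample")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  ties <- any(duplicated(c(x, y)))
  if (n <= 12 && !ties) {
    combs <- utils::combn(n, n1)
    sums <- colSums(matrix(seq_len(n)[combs], nrow = n1))
    p <- min(1, 2 * min(mean(sums <= W), mean(sums >= W)))
    return(list(W = W, p = p, method = "exact"))
  }
  mu <- n1 * (n + 1) / 2
  tab <- table(r)
  tiecorr <- sum(tab^3 - tab) / ((n) * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tiecorr)
  if (sigma2 <= 0) return(list(W = W, p = 1, method = "normal"))
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
  list(W = W, p = min(1, 2 * stats::pnorm(-abs(z))), method = "normal")
}

#' Per-gene missing-peak counts and group contrast
#'
#' For each gene, counts its linked peaks that are accessible in condition 1
#' but absent from condition 2 (the gene's "peak deficit"); genes without
#' links count zero. The deficits of gene set A are contrasted against gene
#' set B with [wilcoxon_rank_sum()].
#'
#' @param set_a,set_b Gene id vectors.
#' @param links Link table (peak_id, gene_id).
#' @param peaks_cond1,peaks_cond2 Peak ids accessible in each condition.
#' @return List: \code{deficit} (named per-gene counts over A and B),
#'   \code{W}, \code{p}.
#' @export
peak_deficit <- function(set_a, set_b, links, peaks_cond1, peaks_cond2) {
  missing_ids <- setdiff(peaks_cond1, peaks_cond2)
  deficit_of <- function(gene) {
    sum(links$gene_id == gene & links$peak_id %in% missing_ids)
  }
  da <- vapply(set_a, deficit_of, numeric(1))
  db <- vapply(set_b, deficit_of, numeric(1))
  wt <- wilcoxon_rank_sum(da, db)
  list(deficit = c(da, db), W = wt$W, p = wt$p)
}

#' Replicate-consistent ChIP binding flags
#'
#' A region counts as transcription-factor bound iff it overlaps at least
#' one ChIP peak in replicate 1 AND at least one in replicate 2.
#'
#' @param regions Interval data frame.
#' @param chip_rep1,chip_rep2 ChIP peak interval data frames.
#' @return Logical vector, one flag per region.
#' @export
chip_bound_regions <- function(regions, chip_rep1, chip_rep2) {
  overlaps_any(regions, chip_rep1) & overlaps_any(regions, chip_rep2)
}

#' Fisher exact enrichment of binding in a region set
#'
#' Builds the 2x2 table (in set / out of set x bound / unbound) over the
#' universe and computes the two-sided Fisher exact p as the sum of
#' hypergeometric probabilities not exceeding the observed table's
#' (probability-mass definition, with a small relative tolerance), plus the
#' conditional maximum-likelihood odds ratio. Degenerate margins give p = 1
#' and an undefined odds ratio flag.
#'
#' @param in_set Logical vector (TRUE = region belongs to the set of
#'   interest), one per universe region.
#' @param bound Logical vector of binding flags, same length.
#' @return List of class \code{enrichment_result}: \code{table} (2x2),
#'   \code{odds_ratio}, \code{or_undefined}, \code{p}, \code{method}.
#' @export
fisher_enrichment <- function(in_set, bound) {
  stopifnot(length(in_set) == length(bound))
  if (!length(in_set)) stop("empty universe")
  a <- sum(in_set & bound); b <- sum(in_set & !bound)
  c_ <- sum(!in_set & bound); d <- sum(!in_set & !bound)
  tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE,
                dimnames = list(c("in_set", "out_set"),
                                c("bound", "unbound")))
  m1 <- a + b; k <- a + c_; n <- a + b + c_ + d
  lo <- max(0L, k - (n - m1)); hi <- min(m1, k)
  support <- lo:hi
  logp <- stats::dhyper(support, m1, n - m1, k, log = TRUE)
  obs <- logp[support == a]
  p <- if (lo == hi) 1 else
    min(1, sum(exp(logp[logp <= obs + 1e-7])))
  # conditional MLE odds ratio (noncentral hypergeometric)
  or_undef <- (b == 0 && c_ == 0) || (a == 0 && d == 0) ||
    m1 == 0 || m1 == n || k == 0 || k == n
  or <- if (or_undef) {
    if ((b == 0 && c_ == 0) && a > 0 && d > 0) Inf else NA_real_
  } else if (a == lo) 0 else if (a == hi) Inf else {
    loglik <- function(logpsi)
      obs_ll(a, support, logp, logpsi)
    exp(stats::optimize(loglik, c(-25, 25), maximum = TRUE)$maximum)
  }
  structure(list(table = tab, odds_ratio = or, or_undefined = or_undef,
                 p = p, method = "fisher_exact_two_sided"),
            class = "enrichment_result")
}

# noncentral hypergeometric log likelihood of the observed count a
obs_ll <- function(a, support, logp_central, logpsi) {
  w <- logp_central + support * logpsi
  mx <- max(w)
  (logp_central[support == a] + a * logpsi) - (mx + log(sum(exp(w - mx))))
}
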