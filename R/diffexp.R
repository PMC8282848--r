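#' Median-of-ratios size factors
#'
#' The standard count-normalisation used for bulk RNA-seq and ATAC-seq
#' tables: for each unit j, the size factor is the median over features of
#' \code{count_fj / geometric_mean_f}, computed over features with strictly
#' positive counts in every unit. Factors are not rescaled afterwards.
#'
#' @param counts Numeric matrix, features x units, non-negative.
#' @return Named numeric vector of positive size factors, one per unit.
#' @export
size_factors_median_of_ratios <- function(counts) {
  stopifnot(is.matrix(counts))
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("no feature with positive counts in every unit; ",
         "pre-filter the matrix before computing size factors")
  loggeo <- rowMeans(log(counts[pos, , drop = FALSE]))
  sf <- apply(counts[pos, , drop = FALSE], 2, function(col)
    exp(stats::median(log(col) - loggeo)))
  sf
}

#' Normalise a count matrix by size factors
#'
#' @param counts Features x units matrix.
#' @param size_factors Positive factor per unit.
#' @return Matrix of \code{count / factor} values.
#' @export
normalize_counts <- function(counts, size_factors) {
  stopifnot(ncol(counts) == length(size_factors))
  if (any(!is.finite(size_factors) | size_factors <= 0))
    stop("size factors must be positive and finite")
  sweep(counts, 2, size_factors, `/`)
}

#' Drop features below an expression/accessibility floor
#'
#' A feature is retained iff its maximum normalised value over units reaches
#' the floor; i.e. features below the floor in *all* units are removed
#' (floor 10 for RNA expression, 25 for ATAC accessibility).
#'
#' @param normalized Normalised features x units matrix.
#' @param floor Non-negative threshold.
#' @return Character vector of retained feature ids (rownames).
#' @export
filter_low_features <- function(normalized, floor) {
  stopifnot(floor >= 0)
  keep <- apply(normalized, 1, max) >= floor
  rownames(normalized)[keep]
}

#' Benjamini-Hochberg step-up adjustment
#'
#' \code{padj_(i) = min_{j >= i} min(1, m * p_(j) / j)} in sorted order,
#' mapped back to input order.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(pvals)
  if (m == 0L) return(numeric(0))
  o <- order(pvals)
  adj <- pmin(1, m * pvals[o] / seq_len(m))
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Simplified negative-binomial Wald differential test
#'
#' A deliberately small stand-in for a DESeq2-style analysis, applied
#' identically to RNA and ATAC count tables. Model: counts are negative
#' binomial with variance \code{m + alpha * m^2}. The dispersion
#' \code{alpha} is a single common value estimated by method of moments,
#' pooling residual moments across both groups and all features (ratio of
#' summed \code{s^2 - m} to summed \code{m^2}, clamped below at 1e-8). Group
#' means are taken on the normalised scale; \code{log2FC =
#' log2((mB + 0.5) / (mA + 0.5))} with a 0.5 pseudocount so zero counts give
#' finite fold changes; its standard error comes from the delta method on
#' the NB variance of each group mean; the Wald statistic is referred to the
#' standard normal, two-sided, and adjusted over all tested features by
#' Benjamini-Hochberg. No dispersion shrinkage, outlier filtering or
#' independent filtering is applied. Condition A is the reference (first
#' level of \code{factor(condition)}); log2FC is B vs A.
#'
#' @param counts Integer features x units matrix (raw counts).
#' @param condition Vector of two condition labels, one per unit; each
#'   condition needs >= 2 units.
#' @param size_factors Per-unit size factors
#'   (default: [size_factors_median_of_ratios()]).
#' @return \code{data.frame} with one row per feature: \code{feature_id},
#'   \code{base_mean}, \code{log2fc}, \code{se}, \code{stat}, \code{pvalue},
#'   \code{padj}.
#' @export
nb_wald_test <- function(counts, condition,
                         size_factors = size_factors_median_of_ratios(counts)) {
  stopifnot(is.matrix(counts), ncol(counts) == length(condition))
  if (any(counts != floor(counts)))
    stop("nb_wald_test expects integer counts")
  cond <- factor(condition)
  if (nlevels(cond) != 2L)
    stop("exactly two conditions required, got ", nlevels(cond))
  if (any(table(cond) < 2L))
    stop("each condition needs at least 2 units")
  norm <- normalize_counts(counts, size_factors)
  a <- which(cond == levels(cond)[1])
  b <- which(cond == levels(cond)[2])
  mA <- rowMeans(norm[, a, drop = FALSE])
  mB <- rowMeans(norm[, b, drop = FALSE])
  vA <- apply(norm[, a, drop = FALSE], 1, stats::var)
  vB <- apply(norm[, b, drop = FALSE], 1, stats::var)
  nA <- length(a); nB <- length(b)
  # common dispersion: method of moments pooled across groups and features
  num <- (nA - 1) * (vA - mA) + (nB - 1) * (vB - mB)
  den <- (nA - 1) * mA^2 + (nB - 1) * mB^2
  ok <- is.finite(num) & den > 0
  alpha <- if (any(ok)) max(sum(num[ok]) / sum(den[ok]), 1e-8) else 1e-8
  lfc <- log2((mB + 0.5) / (mA + 0.5))
  var_mA <- (mA + alpha * mA^2) / nA
  var_mB <- (mB + alpha * mB^2) / nB
  se <- sqrt(var_mA / (mA + 0.5)^2 + var_mB / (mB + 0.5)^2) / log(2)
  z <- ifelse(se > 0, lfc / se, 0)
  p <- ifelse(se > 0, 2 * stats::pnorm(-abs(z)), 1)
  data.frame(feature_id = rownames(counts),
             base_mean = (mA * nA + mB * nB) / (nA + nB),
             log2fc = lfc, se = se, stat = z, pvalue = p,
             padj = bh_adjust(p),
             dispersion = alpha,
             stringsAsFactors = FALSE)
}

#' Call differential features from a test table
#'
#' Thresholds are inclusive: up = \code{padj <= padj_threshold} and
#' \code{log2fc >= lfc_threshold}; down analogously with
#' \code{log2fc <= -lfc_threshold}.
#'
#' @param table Output of [nb_wald_test()].
#' @param padj_threshold Adjusted-p threshold (default 0.05).
#' @param lfc_threshold Absolute log2 fold-change threshold (default 1).
#' @return List with character vectors \code{up} and \code{down} (disjoint).
#' @export
call_differential <- function(table, padj_threshold = 0.05,
                              lfc_threshold = 1) {
  sig <- !is.na(table$padj) & table$padj <= padj_threshold
  list(up = table$feature_id[sig & table$log2fc >= lfc_threshold],
       down = table$feature_id[sig & table$log2fc <= -lfc_threshold])
}
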