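# Maturation signatures: high-confidence gene sets supported both by
# single-cell module membership and by bulk differential calls.

#' Sum single-cell counts into pseudo-bulk samples
#'
#' @param counts Genes x cells matrix.
#' @param cell_samples Sample label per cell (every cell must be labelled).
#' @return Genes x samples matrix of summed counts.
#' @export
make_pseudobulk <- function(counts, cell_samples) {
  stopifnot(ncol(counts) == length(cell_samples))
  if (any(is.na(cell_samples) | cell_samples == ""))
    stop("every cell must carry a sample label")
  f <- factor(cell_samples)
  out <- vapply(levels(f), function(s)
    rowSums(counts[, f == s, drop = FALSE]), numeric(nrow(counts)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1)
  dimnames(out) <- list(rownames(counts), levels(f))
  out
}

#' Intersect single-cell module genes with bulk differential calls
#'
#' The high-confidence mature signature is the intersection of the
#' single-cell mature module genes with the bulk up-called genes; immature
#' analogously with the down-called genes. Venn counts (sc-only, bulk-only,
#' intersection) are reported per direction.
#'
#' @param sc_mature,sc_immature Module gene sets (must be disjoint).
#' @param bulk_up,bulk_down Bulk differential gene sets.
#' @return List of class \code{signature_set}: \code{mature},
#'   \code{immature}, and \code{venn} (data.frame with direction, sc_only,
#'   bulk_only, intersection).
#' @export
intersect_signatures <- function(sc_mature, sc_immature, bulk_up,
                                 bulk_down) {
  if (length(intersect(sc_mature, sc_immature)))
    stop("sc mature and immature gene sets overlap; modules must partition")
  mature <- intersect(sc_mature, bulk_up)
  immature <- intersect(sc_immature, bulk_down)
  venn <- data.frame(
    direction = c("mature", "immature"),
    sc_only = c(length(setdiff(sc_mature, bulk_up)),
                length(setdiff(sc_immature, bulk_down))),
    bulk_only = c(length(setdiff(bulk_up, sc_mature)),
                  length(setdiff(bulk_down, sc_immature))),
    intersection = c(length(mature), length(immature)),
    stringsAsFactors = FALSE)
  structure(list(mature = mature, immature = immature, venn = venn),
            class = "signature_set")
}

#' Fraction of one gene set contained in another
#'
#' @param set_a Non-empty character vector.
#' @param set_b Character vector.
#' @return \code{|A intersect B| / |A|}.
#' @export
overlap_fraction <- function(set_a, set_b) {
  if (length(set_a) == 0) stop("set A is empty")
  length(intersect(set_a, set_b)) / length(unique(set_a))
}
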