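#' Construct a table of genomic intervals
#'
#' Intervals follow the BED convention throughout the package: 0-based,
#' half-open \code{[start, end)}, so \code{end - start} is the interval
#' length in bp. Any 1-based input dialect must be converted before entry.
#'
#' @param chrom Character vector of chromosome names (non-empty strings).
#' @param start Integer vector, 0-based inclusive start positions.
#' @param end Integer vector, 0-based exclusive end positions; must satisfy
#'   \code{start < end}.
#' @param name Optional identifier per interval; when present, names must be
#'   unique within the set.
#' @param strand Strand per interval: \code{"+"}, \code{"-"} or \code{"*"}
#'   (unstranded).
#' @return A \code{data.frame} with columns \code{chrom}, \code{start},
#'   \code{end}, \code{name}, \code{strand}.
#' @export
genomic_intervals <- function(chrom, start, end, name = NA_character_,
                              strand = "*") {
  n <- max(length(chrom), length(start), length(end))
  df <- data.frame(chrom = rep_len(as.character(chrom), n),
                   start = rep_len(as.numeric(start), n),
                   end = rep_len(as.numeric(end), n),
                   name = rep_len(as.character(name), n),
                   strand = rep_len(as.character(strand), n),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0L) return(invisible(df))
  if (any(is.na(df$chrom) | df$chrom == ""))
    stop("interval with empty chromosome name")
  if (any(!is.finite(df$start) | !is.finite(df$end)))
    stop("interval with non-finite coordinates")
  if (any(df$start < 0))
    stop("interval with negative start")
  if (any(df$start >= df$end))
    stop("interval with start >= end (zero or negative length)")
  nm <- df$name[!is.na(df$name)]
  if (anyDuplicated(nm))
    stop("duplicated interval names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  invisible(df)
}

#' Test whether two genomic intervals overlap
#'
#' Half-open semantics: intervals overlap iff they are on the same chromosome
#' and share at least one basepair, i.e. \code{a.start < b.end} and
#' \code{b.start < a.end}. Abutting intervals do not overlap.
#'
#' @param a,b Single intervals: lists or one-row data.frames with
#'   \code{chrom}, \code{start}, \code{end}.
#' @return \code{TRUE} or \code{FALSE}.
#' @export
overlaps <- function(a, b) {
  a$chrom == b$chrom && a$start < b$end && b$start < a$end
}

# Vectorised: for each row of `query`, TRUE iff it overlaps >= 1 interval of
# `track`. O(n*m) per chromosome; fine at the scales this package runs at.
overlaps_any <- function(query, track) {
  if (nrow(query) == 0L) return(logical(0))
  out <- logical(nrow(query))
  if (nrow(track) == 0L) return(out)
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    ti <- track$chrom == ch
    if (!any(ti)) next
    ts <- track$start[ti]; te <- track$end[ti]
    out[qi] <- vapply(qi, function(i)
      any(query$start[i] < te & ts < query$end[i]), logical(1))
  }
  out
}

interval_centre <- function(df) floor((df$start + df$end) / 2)
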