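#' Read a BED3/BED6 file of genomic intervals
#'
#' Columns 1-3 are parsed as chrom/start/end (0-based, half-open); column 4,
#' when present, as the interval name and column 6 as the strand. Lines with
#' non-integer coordinates or \code{start >= end} raise an error naming the
#' offending line.
#'
#' @param path Path to a tab-separated BED file.
#' @return Interval \code{data.frame} (see [genomic_intervals()]), in file
#'   order; zero rows for an empty file.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(genomic_intervals(character(0), numeric(0), numeric(0) + 1))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- vapply(fields, length, integer(1))
  if (any(n < 3L))
    stop("BED line ", which(n < 3L)[1], ": fewer than 3 fields")
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) |
                 end != floor(end))
  if (length(bad))
    stop("BED line ", bad[1], ": non-integer coordinates")
  bad <- which(start >= end)
  if (length(bad))
    stop("BED line ", bad[1], ": start >= end")
  df <- data.frame(
    chrom = vapply(fields, `[`, "", 1L),
    start = start, end = end,
    name = ifelse(n >= 4L, vapply(fields, function(f) f[4], ""),
                  NA_character_),
    strand = ifelse(n >= 6L, vapply(fields, function(f) f[6], ""), "*"),
    stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

#' Write genomic intervals to a BED file
#'
#' Emits BED6 when any name or strand is set, BED3 otherwise. Round-trips
#' through [read_bed()].
#'
#' @param intervals Interval \code{data.frame}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_bed <- function(intervals, path) {
  validate_intervals(intervals)
  if (nrow(intervals) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  has_extra <- any(!is.na(intervals$name)) || any(intervals$strand != "*")
  if (has_extra) {
    lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                     intervals$chrom, as.integer(intervals$start),
                     as.integer(intervals$end),
                     ifelse(is.na(intervals$name), ".", intervals$name),
                     intervals$strand)
  } else {
    lines <- sprintf("%s\t%d\t%d", intervals$chrom,
                     as.integer(intervals$start), as.integer(intervals$end))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models (TSS table)
#'
#' A gene model is a stranded TSS point: tab-separated file with header
#' \code{gene_id, chrom, tss, strand}; \code{tss} is 0-based. The closest-TSS
#' annotation rule needs only this point, not the transcript span.
#'
#' @param path Path to the 4-column TSV.
#' @return \code{data.frame} with columns \code{gene_id}, \code{chrom},
#'   \code{tss}, \code{strand}.
#' @export
read_gene_models <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "character",
                                         "numeric", "character"))
  if (!identical(names(df), c("gene_id", "chrom", "tss", "strand")))
    stop("gene model header must be: gene_id, chrom, tss, strand")
  if (anyDuplicated(df$gene_id))
    stop("duplicated gene_id: ",
         df$gene_id[duplicated(df$gene_id)][1])
  if (any(is.na(df$tss) | df$tss < 0 | df$tss != floor(df$tss)))
    stop("tss must be a non-negative integer position")
  if (!all(df$strand %in% c("+", "-")))
    stop("gene models must be stranded (+ or -), got: ",
         setdiff(df$strand, c("+", "-"))[1])
  df
}

#' @rdname read_gene_models
#' @param genes Gene-model \code{data.frame} to write.
#' @export
write_gene_models <- function(genes, path) {
  utils::write.table(genes[, c("gene_id", "chrom", "tss", "strand")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count matrix from TSV
#'
#' First column holds feature identifiers, remaining columns one unit (cell
#' or sample) each. Cells must be non-negative numbers; \code{NA} or negative
#' values are parse errors.
#'
#' @param path Path to the TSV.
#' @return Numeric matrix with feature rownames and unit colnames, in file
#'   order.
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("count matrix needs a feature column plus >=1 unit")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicated feature ids")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric cell in count matrix")
  if (anyNA(m)) stop("NA cell in count matrix")
  if (any(m < 0)) stop("negative cell in count matrix")
  rownames(m) <- ids
  if (anyDuplicated(colnames(m))) stop("duplicated unit ids")
  m
}

#' @rdname read_count_matrix
#' @param counts Matrix to write (feature rownames, unit colnames).
#' @param feature_col Header for the feature-id column.
#' @export
write_count_matrix <- function(counts, path, feature_col = "feature_id") {
  df <- data.frame(rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- feature_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a long-range interaction (region-to-gene) table
#'
#' Two-column TSV with header \code{region, gene_id}: each row links a named
#' interval from an accompanying BED file to a target gene. Mirrors external
#' regulatory-region datasets without reproducing their formats.
#'
#' @param path Path to the TSV.
#' @return \code{data.frame} with columns \code{region}, \code{gene_id}.
#' @export
read_links <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "character"))
  if (!identical(names(df), c("region", "gene_id")))
    stop("link table header must be: region, gene_id")
  df
}

#' @rdname read_links
#' @param links Link \code{data.frame} to write.
#' @export
write_links <- function(links, path) {
  utils::write.table(links[, c("region", "gene_id")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_plain <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
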