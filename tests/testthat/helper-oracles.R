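# Brute-force oracles kept deliberately independent of the implementation
# paths they check.

# interval overlap by explicit basepair-set intersection
bp_overlap_oracle <- function(a, b) {
  if (a$chrom != b$chrom) return(FALSE)
  length(intersect(seq(a$start, a$end - 1), seq(b$start, b$end - 1))) > 0
}

# BH step-up by literal evaluation of the definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- sapply(seq_len(m), function(i)
    min(sapply(i:m, function(j) min(1, m * sorted[j] / j))))
  out <- numeric(m)
  out[o] <- adj
  out
}

# exhaustive nearest-TSS search
closest_tss_oracle <- function(peak_chrom, peak_centre, genes) {
  cand <- genes[genes$chrom == peak_chrom, , drop = FALSE]
  if (!nrow(cand)) return(NA_character_)
  d <- abs(cand$tss - peak_centre)
  best <- cand[d == min(d), , drop = FALSE]
  sort(best$gene_id)[1]
}

# exact two-sided Fisher p by enumeration of all tables with the margins
fisher_oracle <- function(a, b, c_, d) {
  m1 <- a + b; k <- a + c_; n <- a + b + c_ + d
  lo <- max(0, k - (n - m1)); hi <- min(m1, k)
  probs <- sapply(lo:hi, function(x)
    choose(m1, x) * choose(n - m1, k - x) / choose(n, k))
  obs <- probs[(lo:hi) == a]
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# exact two-sided Wilcoxon p by full enumeration of rank assignments
wilcoxon_oracle <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  W <- sum(rank(c(x, y))[seq_len(n1)])
  sums <- colSums(matrix(seq_len(n)[utils::combn(n, n1)], nrow = n1))
  min(1, 2 * min(mean(sums <= W), mean(sums >= W)))
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 1000,
                             max_len = 120) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  genomic_intervals(sample(chroms, n, replace = TRUE), start,
                    start + sample.int(max_len, n, replace = TRUE),
                    name = sprintf("iv%03d", seq_len(n)))
}
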