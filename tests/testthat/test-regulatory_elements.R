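test_that("interval overlap matches half-open semantics and the bp oracle", {
  a <- list(chrom = "chr1", start = 0, end = 100)
  expect_true(overlaps(a, list(chrom = "chr1", start = 99, end = 200)))
  expect_false(overlaps(a, list(chrom = "chr1", start = 100, end = 200)))
  expect_false(overlaps(a, list(chrom = "chr2", start = 0, end = 100)))

  set.seed(41)
  for (i in 1:1000) {
    x <- list(chrom = sample(c("chr1", "chr2"), 1),
              start = s1 <- sample(0:50, 1), end = s1 + sample(1:30, 1))
    y <- list(chrom = sample(c("chr1", "chr2"), 1),
              start = s2 <- sample(0:50, 1), end = s2 + sample(1:30, 1))
    expect_equal(overlaps(x, y), bp_overlap_oracle(x, y))
  }
})

test_that("vectorised overlap agrees with IRanges", {
  set.seed(42)
  q <- random_intervals(80)
  tr <- random_intervals(60)
  tr$name <- paste0("t", seq_len(nrow(tr)))
  got <- astromat:::overlaps_any(q, tr)
  want <- vapply(seq_len(nrow(q)), function(i) {
    same <- tr[tr$chrom == q$chrom[i], , drop = FALSE]
    if (!nrow(same)) return(FALSE)
    sum(IRanges::countOverlaps(
      IRanges::IRanges(q$start[i] + 1, q$end[i]),
      IRanges::IRanges(same$start + 1, same$end))) > 0
  }, logical(1))
  expect_equal(got, want)
})

test_that("peak classification applies promoter > enhancer > distal", {
  tracks <- list(
    promoters = genomic_intervals("chr1", 900, 1100, name = "p1"),
    enhancers = genomic_intervals("chr1", c(1000, 5000), c(1200, 5200),
                                  name = c("e1", "e2")),
    h3k4me1 = genomic_intervals("chr1", 8000, 8500, name = "k1"))
  peaks <- genomic_intervals("chr1",
                             c(950, 5050, 8100, 20000),
                             c(1050, 5150, 8200, 20100),
                             name = c("both", "enh_only", "k_only", "none"))
  cls <- classify_peaks(peaks, tracks)$class
  expect_equal(cls, c("promoter", "enhancer", "enhancer", "distal"))
  # every peak gets exactly one class
  expect_true(all(cls %in% c("promoter", "enhancer", "distal")))

  # tss_window rescues unannotated TSS neighbourhoods when enabled
  genes <- data.frame(gene_id = "g", chrom = "chr1", tss = 20050,
                      strand = "+", stringsAsFactors = FALSE)
  cls2 <- classify_peaks(peaks, c(tracks, list(genes = genes)),
                         tss_window = 500)$class
  expect_equal(cls2[4], "promoter")
})

test_that("closest-TSS linking matches exhaustive search with signed distance", {
  genes <- data.frame(gene_id = "geneA", chrom = "chr1", tss = 1000,
                      strand = "+", stringsAsFactors = FALSE)
  pk <- genomic_intervals("chr1", 1400, 1600, name = "pk1")
  link <- link_closest_tss(pk, genes)
  expect_equal(link$gene_id, "geneA")
  expect_equal(link$distance, 500)  # centre 1500, downstream of + TSS
  # minus-strand gene flips the sign
  genes$strand <- "-"
  expect_equal(link_closest_tss(pk, genes)$distance, -500)

  # equidistant TSSs break towards the smaller gene id
  g2 <- data.frame(gene_id = c("gB", "gA"), chrom = "chr1",
                   tss = c(1000, 2000), strand = "+",
                   stringsAsFactors = FALSE)
  mid <- genomic_intervals("chr1", 1450, 1550, name = "pmid")
  expect_equal(link_closest_tss(mid, g2)$gene_id, "gA")

  # chromosome without genes is flagged, not an error
  lonely <- link_closest_tss(genomic_intervals("chr9", 0, 100, name = "px"),
                             g2)
  expect_true(lonely$no_gene)
  expect_true(is.na(lonely$gene_id))

  # 50 random peaks vs 20 random genes equal the brute-force oracle
  set.seed(43)
  rg <- data.frame(gene_id = sprintf("g%02d", 1:20),
                   chrom = sample(c("chr1", "chr2"), 20, replace = TRUE),
                   tss = sample.int(100000, 20), strand = "+",
                   stringsAsFactors = FALSE)
  rp <- genomic_intervals(sample(c("chr1", "chr2"), 50, replace = TRUE),
                          st <- sample.int(100000, 50), st + 200,
                          name = sprintf("p%02d", 1:50))
  links <- link_closest_tss(rp, rg)
  want <- vapply(seq_len(50), function(i)
    closest_tss_oracle(rp$chrom[i], floor((rp$start[i] + rp$end[i]) / 2),
                       rg), character(1))
  expect_equal(links$gene_id, want)
})

test_that("long-range links skip promoter peaks and resolve regions", {
  regions <- genomic_intervals("chr1", c(100, 500), c(300, 700),
                               name = c("r1", "r2"))
  link_table <- data.frame(region = c("r1", "r2", "r2"),
                           gene_id = c("gZ", "gY", "gX"),
                           stringsAsFactors = FALSE)
  peaks <- genomic_intervals("chr1", c(150, 550), c(250, 650),
                             name = c("pkP", "pkE"))
  peaks$class <- c("promoter", "enhancer")
  lr <- link_long_range(peaks, regions, link_table)
  expect_false("pkP" %in% lr$peak_id)           # promoter peaks excluded
  expect_setequal(lr$gene_id[lr$peak_id == "pkE"], c("gY", "gX"))
  expect_error(link_long_range(peaks, regions,
                               data.frame(region = "nope", gene_id = "g")),
               "not found")
  # duplicates with the closest-TSS link are dropped
  closest <- data.frame(peak_id = "pkE", gene_id = "gY",
                        source = "closest_tss", distance = 10,
                        no_gene = FALSE, stringsAsFactors = FALSE)
  lr2 <- link_long_range(peaks, regions, link_table, closest = closest)
  expect_equal(lr2$gene_id, "gX")
})

test_that("the distance cap is inclusive and idempotent", {
  links <- data.frame(peak_id = c("a", "b", "c"),
                      gene_id = c("g1", "g2", "g3"),
                      source = c("closest_tss", "closest_tss", "long_range"),
                      distance = c(100000, -100001, NA),
                      stringsAsFactors = FALSE)
  capped <- apply_distance_cap(links, 100000)
  expect_setequal(capped$peak_id, c("a", "c"))   # exactly 100 kb kept;
  expect_equal(apply_distance_cap(capped, 100000), capped)  # idempotent
  expect_equal(apply_distance_cap(links, Inf), links)
})

test_that("frip normalisation rescales by sequencing quality", {
  expect_equal(frip_normalize(10, 0.25), 40)
  expect_equal(frip_normalize(c(3, 7), 1), c(3, 7))
  m <- matrix(c(10, 10), 1, dimnames = list("pk", c("s1", "s2")))
  norm <- frip_normalize(m, c(0.2, 0.4))
  expect_equal(unname(norm[1, 1] / norm[1, 2]), 2)
  expect_error(frip_normalize(1, 0), "\\(0, 1\\]")
  expect_error(frip_normalize(1, 1.5), "\\(0, 1\\]")
})

test_that("signal matrices bin coverage around peak centres", {
  peaks <- genomic_intervals("chr1", 4900, 5100, name = "pk")  # centre 5000
  uniform <- data.frame(chrom = "chr1", start = 0, end = 10000, value = 1)
  sm <- signal_matrix(uniform, peaks, half_window = 1000, bin = 20)
  expect_equal(ncol(sm), 100)                    # 100 bins x 20 bp = 2 kb
  expect_true(all(sm == 20))                     # uniform coverage 1
  # first bin covers [4000, 4020): a point signal there lands in bin 1 only
  point <- data.frame(chrom = "chr1", start = 4000, end = 4020, value = 2)
  sp <- signal_matrix(point, peaks)
  expect_equal(unname(sp[1, 1]), 40)
  expect_true(all(sp[1, -1] == 0))
  # frip scales every bin
  expect_true(all(signal_matrix(uniform, peaks, frip = 0.5) == 40))
  # window clipped at chromosome start zero-fills on the left
  early_pk <- genomic_intervals("chr1", 0, 400, name = "pe")  # centre 200
  se <- signal_matrix(uniform, early_pk)
  expect_true(all(se[1, 1:40] == 0))   # bins before position 0
  expect_true(all(se[1, 41:100] == 20))
})
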