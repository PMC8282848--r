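test_that("gene-peak association tallies equal a brute-force join", {
  sig <- list(immature = paste0("i", 1:10), mature = paste0("m", 1:10))
  set.seed(51)
  peaks <- paste0("pk", 1:60)
  dir <- setNames(sample(c("opening", "closing", "stable"), 60,
                         replace = TRUE), peaks)
  links <- data.frame(
    peak_id = sample(peaks, 40, replace = TRUE),
    gene_id = sample(c(sig$immature, sig$mature, "other"), 40,
                     replace = TRUE),
    stringsAsFactors = FALSE)
  assoc <- associate_genes_peaks(sig, links, dir)
  for (k in sample(nrow(assoc), 8)) {
    g <- assoc$gene_id[k]
    sub <- links[links$gene_id == g, , drop = FALSE]
    expect_equal(assoc$opening[k], sum(dir[sub$peak_id] == "opening"))
    expect_equal(assoc$closing[k], sum(dir[sub$peak_id] == "closing"))
    expect_equal(assoc$stable[k], sum(dir[sub$peak_id] == "stable"))
  }
  # conservation: summed tallies = number of signature-gene link pairs
  in_sig <- links$gene_id %in% c(sig$immature, sig$mature)
  expect_equal(sum(assoc$opening + assoc$closing + assoc$stable),
               sum(in_sig))
  expect_equal(assoc$has_differential,
               (assoc$opening + assoc$closing) > 0)
  # a gene with no links is present with zero counts
  no_link <- assoc[assoc$gene_id %in%
                     setdiff(c(sig$immature, sig$mature), links$gene_id), ]
  if (nrow(no_link)) expect_true(all(!no_link$has_differential))
  expect_error(associate_genes_peaks(sig,
                                     data.frame(peak_id = "ghost",
                                                gene_id = "i1"), dir),
               "unknown peak")
})

test_that("direction concordance handles predominance and ties", {
  assoc <- data.frame(
    gene_id = c("m1", "m2", "i1", "i2"),
    class = c("mature", "mature", "immature", "immature"),
    opening = c(1, 2, 0, 1), closing = c(0, 0, 2, 1),
    stable = c(0, 1, 0, 0),
    has_differential = c(TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  cc <- direction_concordance(assoc)
  mat <- cc[cc$class == "mature", ]
  expect_equal(mat$frac_with_differential, 1)
  expect_equal(mat$frac_predominantly_opening, 1)
  expect_equal(mat$frac_predominantly_closing, 0)
  imm <- cc[cc$class == "immature", ]
  # i2 ties opening == closing: counted in has_differential, excluded
  # from both predominance fractions
  expect_equal(imm$frac_with_differential, 1)
  expect_equal(imm$frac_predominantly_closing, 1)
})

test_that("rank-sum test matches enumeration and the stock implementation", {
  res <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(res$p, 1 / 3)
  expect_equal(res$method, "exact")
  # symmetry in the arguments
  expect_equal(wilcoxon_rank_sum(c(3, 4), c(1, 2))$p, 1 / 3)
  # identical samples under the approximation give p = 1
  x <- rep(c(1, 2, 3), 5)
  expect_equal(wilcoxon_rank_sum(x, x)$p, 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "empty")

  set.seed(52)
  for (i in 1:200) {
    n1 <- sample(2:10, 1)
    n2 <- min(sample(2:10, 1), 12 - n1)
    if (n2 < 1) n2 <- 1
    v <- sample.int(1000, n1 + n2)  # no ties
    x <- v[seq_len(n1)]; y <- v[-seq_len(n1)]
    got <- wilcoxon_rank_sum(x, y)
    expect_equal(got$method, "exact")
    expect_equal(got$p, wilcoxon_oracle(x, y))
    expect_equal(got$p, wilcox.test(x, y, exact = TRUE)$p.value)
  }
  # exact and normal-approximation p agree within 0.02 at total n = 12
  set.seed(53)
  diffs <- replicate(200, {
    n1 <- sample(3:9, 1)
    v <- sample.int(10000, 12)
    x <- v[seq_len(n1)]; y <- v[-seq_len(n1)]
    exact <- wilcoxon_rank_sum(x, y)$p
    approx <- suppressWarnings(wilcox.test(x, y, exact = FALSE,
                                           correct = TRUE)$p.value)
    abs(exact - approx)
  })
  expect_lt(max(diffs), 0.025)
})

test_that("normal approximation tracks the exact p at the switch point", {
  # compare our tie-corrected normal approximation against wilcox.test's
  set.seed(54)
  for (i in 1:50) {
    x <- sample.int(8, 9, replace = TRUE)  # ties force the approximation
    y <- sample.int(8, 7, replace = TRUE)
    got <- wilcoxon_rank_sum(x, y)
    expect_equal(got$method, "normal")
    want <- suppressWarnings(wilcox.test(x, y, correct = TRUE,
                                         exact = FALSE)$p.value)
    expect_equal(got$p, want, tolerance = 1e-8)
  }
})

test_that("peak deficits count condition-specific peaks and contrast groups", {
  links <- data.frame(peak_id = c("p1", "p2", "p3", "p4"),
                      gene_id = c("gA", "gA", "gA", "gB"),
                      stringsAsFactors = FALSE)
  res <- peak_deficit("gA", "gB", links,
                      peaks_cond1 = c("p1", "p2", "p3", "p4"),
                      peaks_cond2 = c("p2", "p4"))
  expect_equal(unname(res$deficit["gA"]), 2)  # 3 in vivo, 1 shared
  expect_equal(unname(res$deficit["gB"]), 0)
  # identical peak sets: all deficits zero, p = 1
  same <- peak_deficit(c("gA"), c("gB"), links,
                       peaks_cond1 = links$peak_id,
                       peaks_cond2 = links$peak_id)
  expect_true(all(same$deficit == 0))
  expect_equal(same$p, 1)
  # constructed skew at n = 100 genes per group is detected
  set.seed(55)
  genes_a <- sprintf("a%03d", 1:100); genes_b <- sprintf("b%03d", 1:100)
  la <- data.frame(peak_id = sprintf("pa%03d", 1:100), gene_id = genes_a)
  lb <- data.frame(peak_id = sprintf("pb%03d", 1:100), gene_id = genes_b)
  keep_b <- sample(c(TRUE, FALSE), 100, replace = TRUE, prob = c(0.9, 0.1))
  big <- rbind(la, lb)
  cond1 <- big$peak_id
  cond2 <- c(la$peak_id[sample(100, 40)], lb$peak_id[keep_b])
  skew <- peak_deficit(genes_a, genes_b, big, cond1, cond2)
  expect_lt(skew$p, 0.01)
})

test_that("ChIP binding requires both replicates and matches brute force", {
  regions <- genomic_intervals("chr1", c(0, 100, 200), c(50, 150, 250),
                               name = c("r1", "r2", "r3"))
  rep1 <- genomic_intervals("chr1", c(10, 110), c(20, 120),
                            name = c("c1", "c2"))
  rep2 <- genomic_intervals("chr1", 10, 20, name = "d1")
  flags <- chip_bound_regions(regions, rep1, rep2)
  expect_equal(flags, c(TRUE, FALSE, FALSE))  # r2 overlaps rep1 only

  set.seed(56)
  rr <- random_intervals(500)
  c1 <- random_intervals(120); c1$name <- paste0("a", seq_len(120))
  c2 <- random_intervals(120); c2$name <- paste0("b", seq_len(120))
  got <- chip_bound_regions(rr, c1, c2)
  want <- vapply(seq_len(500), function(i) {
    ri <- list(chrom = rr$chrom[i], start = rr$start[i], end = rr$end[i])
    hit <- function(track) any(vapply(seq_len(nrow(track)), function(j)
      bp_overlap_oracle(ri, list(chrom = track$chrom[j],
                                 start = track$start[j],
                                 end = track$end[j])), logical(1)))
    hit(c1) && hit(c2)
  }, logical(1))
  expect_equal(got, want)
})

test_that("Fisher enrichment matches enumeration and fisher.test", {
  # table [[2,0],[0,2]]: p = 1/3 by hypergeometric enumeration
  res <- fisher_enrichment(in_set = c(TRUE, TRUE, FALSE, FALSE),
                           bound = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(res$p, 1 / 3)
  # degenerate margin: all regions bound
  allb <- fisher_enrichment(c(TRUE, FALSE, TRUE), c(TRUE, TRUE, TRUE))
  expect_equal(allb$p, 1)
  expect_true(allb$or_undefined)
  expect_error(fisher_enrichment(logical(0), logical(0)), "empty")

  set.seed(57)
  for (i in 1:120) {
    n <- sample(6:40, 1)
    in_set <- sample(c(TRUE, FALSE), n, replace = TRUE)
    bound <- sample(c(TRUE, FALSE), n, replace = TRUE)
    got <- fisher_enrichment(in_set, bound)
    a <- sum(in_set & bound); b <- sum(in_set & !bound)
    c_ <- sum(!in_set & bound); d <- sum(!in_set & !bound)
    expect_equal(got$p, fisher_oracle(a, b, c_, d), tolerance = 1e-9)
    ft <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))
    expect_equal(got$p, ft$p.value, tolerance = 1e-7)
    if (!got$or_undefined && is.finite(got$odds_ratio) &&
        got$odds_ratio > 0)
      expect_equal(got$odds_ratio, unname(ft$estimate), tolerance = 1e-3)
  }
})

test_that("Fisher p is roughly uniform under a null simulation", {
  set.seed(58)
  ps <- replicate(2000, {
    in_set <- sample(c(TRUE, FALSE), 30, replace = TRUE)
    bound <- sample(c(TRUE, FALSE), 30, replace = TRUE)
    fisher_enrichment(in_set, bound)$p
  })
  # discrete and conservative: check no excess of small p
  expect_lt(mean(ps <= 0.05), 0.06)
  expect_gt(mean(ps <= 0.5), 0.3)
})
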