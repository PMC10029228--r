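# Histone scores, methylation binning, meta-profiles, RPKM expression
# divergence and rank-sum comparisons.

bin_track <- function(values, bin = 1000, chrom = "c1") {
  n <- length(values)
  data.frame(chrom = chrom, start = (0:(n - 1)) * bin, end = (1:n) * bin,
             value = values)
}

test_that("histone scores are zero for chip == input and one for a 2x track", {
  chip <- bin_track(rep(100, 50))
  inp <- bin_track(rep(100, 50))
  expect_true(all(abs(histone_score(chip, inp)$value) < 1e-9))
  # depth scaling first: doubling every bin is no enrichment
  chip2 <- bin_track(rep(200, 50))
  expect_true(all(abs(histone_score(chip2, inp)$value) < 1e-9))
  # a local 2x enrichment scores ~1 after depth scaling
  set.seed(2)
  base <- rpois(400, 200)
  chip3 <- bin_track(base)
  chip3$value[101:200] <- rpois(100, 400)
  inp3 <- bin_track(rpois(400, 200))
  hs <- histone_score(chip3, inp3)
  enr <- mean(hs$value[101:200]) - mean(hs$value[-(101:200)])
  se <- stats::sd(hs$value[-(101:200)]) / sqrt(100) * sqrt(2)
  expect_lt(abs(enr - 1), max(2 * se, 0.1))
  expect_error(histone_score(chip, inp[1:10, ]), "identical binning")
})

test_that("methylation binning applies the coverage filter and weights by depth", {
  sites <- data.frame(chrom = "c1", pos = c(100, 200, 300, 400),
                      context = "CG",
                      meth = c(5, 0, 5, 3), total = c(5, 10, 10, 4))
  tr <- methylation_binned(sites, "CG", min_coverage = 5, bin_size = 1000,
                           chrom_sizes = data.frame(chrom = "c1",
                                                    length = 2000))
  # the 4-read site is excluded; weighted level = (5+0+5)/(5+10+10)
  expect_equal(tr$value[1], 10 / 25)
  expect_true(is.na(tr$value[2]))
  # fully methylated sites give exactly 1
  sites2 <- data.frame(chrom = "c1", pos = c(10, 20), context = "CG",
                       meth = c(8, 6), total = c(8, 6))
  tr2 <- methylation_binned(sites2, "CG", bin_size = 1000,
                            chrom_sizes = data.frame(chrom = "c1",
                                                     length = 1000))
  expect_equal(tr2$value[1], 1)
  # other contexts are ignored
  sites3 <- rbind(sites, data.frame(chrom = "c1", pos = 150,
                                    context = "CHH", meth = 10, total = 10))
  tr3 <- methylation_binned(sites3, "CG", min_coverage = 5, bin_size = 1000,
                            chrom_sizes = data.frame(chrom = "c1",
                                                     length = 2000))
  expect_equal(tr3$value[1], 10 / 25)
})

test_that("meta-profiles are flat on flat tracks and mirror with strand", {
  tr <- bin_track(rep(3, 200))
  anchors <- data.frame(chrom = "c1", pos = c(50000, 100000, 150000))
  mp <- meta_profile(tr, anchors, flank = 20000, n_windows = 20)
  expect_true(all(abs(mp$mean - 3) < 1e-9))
  expect_true(all(mp$se < 1e-9))
  # asymmetric bump mirrors when the anchor is minus-strand
  v <- rep(0, 200)
  v[105:110] <- 1 # right of the anchor at bin 100
  trb <- bin_track(v)
  plus <- meta_profile(trb, data.frame(chrom = "c1", pos = 100000,
                                       strand = "+"), 20000, 40)
  minus <- meta_profile(trb, data.frame(chrom = "c1", pos = 100000,
                                        strand = "-"), 20000, 40)
  expect_equal(plus$mean, rev(minus$mean))
  # anchors too close to an end are trimmed and counted
  mp2 <- meta_profile(tr, data.frame(chrom = "c1", pos = c(5000, 100000)),
                      flank = 20000, n_windows = 20)
  expect_equal(attr(mp2, "trimmed"), 1)
  expect_equal(mp2$n[1], 1)
})

test_that("expression divergence follows log10 RPKM arithmetic", {
  # one gene at RPKM 10 vs 100 with a tiny pseudocount: divergence ~ 1
  mk <- function(rpkm) {
    # library of 1e6 reads over two genes; counts chosen so RPKM is exact
    count <- rpkm * 2000 * 1e6 / 1e9
    data.frame(gene_id = c("g", "filler"), length = c(2000, 2000),
               rep1 = c(count, 1e6 - count))
  }
  t1 <- mk(10); t2 <- mk(100)
  orth <- data.frame(gene1 = "g", gene2 = "g")
  dv <- expression_divergence(t1, t2, orth)
  expect_equal(dv$divergence, 1, tolerance = 0.01)
  # identical tables diverge by zero, symmetric in species order
  dv0 <- expression_divergence(t1, t1, orth)
  expect_equal(dv0$divergence, 0)
  dvr <- expression_divergence(t2, t1, orth)
  expect_equal(dvr$divergence, dv$divergence)
  # missing genes are dropped and counted
  orth2 <- rbind(orth, data.frame(gene1 = "absent", gene2 = "g"))
  dv2 <- expression_divergence(t1, t2, orth2)
  expect_equal(attr(dv2, "dropped"), 1)
})

test_that("divergence is invariant to global count scaling", {
  orth <- data.frame(gene1 = sprintf("a%02d", 1:20),
                     gene2 = sprintf("b%02d", 1:20))
  tabs <- simulate_expression(orth, seed = 5)
  d1 <- expression_divergence(tabs$species1, tabs$species2, orth)
  scaled <- tabs$species1
  for (rc in grep("^rep", names(scaled))) scaled[[rc]] <- scaled[[rc]] * 7
  d2 <- expression_divergence(scaled, tabs$species2, orth)
  expect_equal(d1$divergence, d2$divergence, tolerance = 1e-3)
})

test_that("rank-sum comparisons are exact for small n and match enumeration", {
  r <- group_compare(c(1, 2, 3, 4, 5, 6), rep(c("x", "y"), each = 3))
  expect_equal(r$p, 0.1)
  expect_equal(group_compare(rep(1, 10), rep(c("x", "y"), 5))$p, 1)
  expect_error(group_compare(1:4, rep("x", 4)), "two groups")
  set.seed(8)
  for (rep_i in 1:5) {
    x <- round(rnorm(5), 2)
    y <- round(rnorm(4, 0.5), 2)
    if (anyDuplicated(c(x, y))) next
    got <- group_compare(c(x, y), c(rep("x", 5), rep("y", 4)))$p
    want <- oracle_ranksum_p(x, y)
    expect_equal(got, want, tolerance = 1e-9)
  }
})
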