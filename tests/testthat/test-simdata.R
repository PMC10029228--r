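# Generator: ancestral construction, rearrangement application with exact
# provenance, and the forward models for contacts, expression and tracks.

test_that("ancestral genomes are deterministic identity constructions", {
  g <- simulate_ancestor(2, 100, seed = 1)
  expect_identical(g, simulate_ancestor(2, 100, seed = 1))
  expect_equal(nrow(g$chroms), 2)
  expect_equal(nrow(g$genes), 200)
  expect_equal(g$genes$gene_id, g$genes$ancestral_gene_id)
  # identity origin: one segment per chromosome, own coordinates
  expect_equal(nrow(g$origin), 2)
  expect_equal(g$origin$anc_chrom, g$origin$chrom)
  # genes sorted and within bounds
  for (ch in g$chroms$chrom) {
    gg <- g$genes[g$genes$chrom == ch, ]
    expect_true(all(diff(gg$start) > 0))
    expect_true(all(gg$end <= g$chroms$length[g$chroms$chrom == ch]))
  }
  # a 13-chromosome karyotype comes out with 13 chromosomes
  g13 <- simulate_ancestor(13, 50, seed = 3)
  expect_equal(nrow(g13$chroms), 13)
  expect_equal(nrow(g13$genes), 650)
  expect_error(simulate_ancestor(0, 10), "non-positive")
  expect_error(simulate_ancestor(2, 1), "non-positive")
})

test_that("an empty event list reproduces the input genome with no breakpoints", {
  g <- simulate_ancestor(2, 80, seed = 2)
  d <- apply_rearrangements(g, list(), seed = 5, species_id = "x")
  expect_equal(d$genome$genes[, c("gene_id", "chrom", "start", "end")],
               g$genes[, c("gene_id", "chrom", "start", "end")])
  expect_equal(nrow(d$truth$breakpoints), 0)
})

test_that("a single inversion plants exactly two breakpoints and preserves flanks", {
  g <- simulate_ancestor(1, 100, seed = 4)
  d <- apply_rearrangements(g, list(ev_inversion("chr01", 40, 60)), seed = 6)
  expect_equal(nrow(d$truth$breakpoints), 2)
  go <- g$genes$gene_id
  gn <- d$genome$genes$gene_id
  expect_equal(gn[1:39], go[1:39])
  expect_equal(gn[61:100], go[61:100])
  expect_equal(gn[40:60], rev(go[40:60]))
  # brute-force adjacency disruption count equals planted breakpoints
  pos_new <- match(go, gn)
  disrupted <- sum(abs(diff(pos_new)) != 1)
  expect_equal(disrupted, 2)
  # gene count conserved
  expect_equal(nrow(d$genome$genes), nrow(g$genes))
})

test_that("fusion then fission composes provenance on a toy genome", {
  g <- simulate_ancestor(2, 10, seed = 7, gene_spacing = 5000)
  d1 <- apply_rearrangements(g, list(ev_fusion("chr01", "chr02", "f")),
                             seed = 8, species_id = "s1")
  expect_equal(nrow(d1$genome$chroms), 1)
  expect_equal(nrow(d1$genome$genes), 20)
  d2 <- apply_rearrangements(d1$genome, list(ev_fission("f", 10)),
                             seed = 9, species_id = "s2")
  expect_equal(nrow(d2$genome$chroms), 2)
  # the two fission products carry the original chromosomes' genes in order
  halves <- split(d2$genome$genes$ancestral_gene_id, d2$genome$genes$chrom)
  expect_setequal(vapply(halves, function(h)
    unique(sub("_g.*", "", h)), character(1)), c("chr01", "chr02"))
  # provenance composition: two-step equals direct map to the ancestor
  expect_equal(sort(d2$genome$genes$ancestral_gene_id),
               sort(g$genes$gene_id))
})

test_that("stepwise application equals one-shot application (provenance closure)", {
  g <- simulate_ancestor(1, 30, seed = 11, gene_spacing = 5000)
  evs <- list(ev_inversion("chr01", 5, 12), ev_inversion("chr01", 20, 26))
  one <- apply_rearrangements(g, evs, seed = 1, species_id = "s")
  two_a <- apply_rearrangements(g, evs[1], seed = 1, species_id = "t")
  two <- apply_rearrangements(two_a$genome, evs[2], seed = 1, species_id = "s")
  expect_equal(one$genome$genes$gene_id, two$genome$genes$gene_id)
  expect_equal(one$genome$origin, two$genome$origin)
})

test_that("breakpoint count equals the number of discordant provenance junctions", {
  g <- simulate_ancestor(2, 60, seed = 12)
  d <- apply_rearrangements(g, list(
    ev_inversion("chr01", 10, 25),
    ev_translocation("chr02", 20, 35, "chr01", 45)), seed = 13)
  # recompute junctions straight from the gene table
  njunc <- 0
  for (ch in d$genome$chroms$chrom) {
    t <- d$genome$genes[d$genome$genes$chrom == ch, ]
    n <- nrow(t)
    adj <- t$anc_chrom[-1] == t$anc_chrom[-n] &
      t$orient[-1] == t$orient[-n] &
      (t$anc_idx[-1] - t$anc_idx[-n]) == t$orient[-n]
    njunc <- njunc + sum(!adj)
  }
  expect_equal(nrow(d$truth$breakpoints), njunc)
  expect_gt(njunc, 0)
})

test_that("invalid events are rejected", {
  g <- simulate_ancestor(2, 40, seed = 14)
  expect_error(ev_inversion("chr01", 10, 5), "empty")
  expect_error(ev_translocation("chr01", 1, 5, "chr01", 20), "distinct")
  expect_error(ev_fusion("chr01", "chr01"), "two chromosomes")
  expect_error(apply_rearrangements(g, list(ev_inversion("chr01", 30, 55))),
               "out of bounds")
  expect_error(apply_rearrangements(g, list(ev_inversion("chr01", 5, 15),
                                            ev_inversion("chr01", 10, 20))),
               "overlapping")
})

test_that("simulated contacts are symmetric and follow the decay law", {
  g <- simulate_ancestor(1, 150, seed = 21)
  d <- apply_rearrangements(g, list(), seed = 22)
  m <- simulate_contacts(d$genome, d$truth, 5000, depth = 200,
                         plaid_contrast = 1, tad_enrichment = 1,
                         bias_sd = 0, covariate_bias = FALSE, seed = 23)
  dm <- cm_dense(m)
  expect_identical(dm, t(dm))
  # empirical mean at distance d matches depth * d^-alpha within 3 MC SE
  n <- nrow(dm)
  for (dd in c(1, 3, 10)) {
    idx <- cbind(1:(n - dd), (1:(n - dd)) + dd)
    mu_hat <- mean(dm[idx])
    mu_true <- 200 * dd^-1
    se <- sqrt(mu_true / nrow(idx))
    expect_lt(abs(mu_hat - mu_true), 3 * se)
  }
  expect_error(simulate_contacts(d$genome, d$truth, 5000, alpha = 0),
               "alpha")
  # degenerate depth gives the empty matrix
  m0 <- simulate_contacts(d$genome, d$truth, 5000, depth = 0, seed = 1)
  expect_equal(nrow(m0$pixels), 0)
  # determinism
  m2 <- simulate_contacts(d$genome, d$truth, 5000, depth = 200, seed = 23,
                          plaid_contrast = 1, tad_enrichment = 1,
                          bias_sd = 0, covariate_bias = FALSE)
  expect_identical(m$pixels, m2$pixels)
})

test_that("ancestral-preserving mode dampens cross-origin contacts", {
  g <- simulate_ancestor(2, 120, seed = 31)
  d <- apply_rearrangements(g, list(ev_fusion("chr01", "chr02", "fused")),
                            seed = 32)
  m <- simulate_contacts(d$genome, d$truth, 5000,
                         mode = "ancestral_preserving", dampening = 0.2,
                         bias_sd = 0, covariate_bias = FALSE, seed = 33)
  dec <- cis_decay_by_origin(m, d$genome$origin, chrom = "fused")
  pop <- dec$n_same >= 50 & dec$n_diff >= 50
  expect_true(all(dec$mean_same[pop] > dec$mean_diff[pop]))
})

test_that("expression tables are deterministic and effects raise divergence", {
  orth <- data.frame(gene1 = sprintf("a%03d", 1:200),
                     gene2 = sprintf("b%03d", 1:200))
  t1 <- simulate_expression(orth, seed = 41)
  t2 <- simulate_expression(orth, seed = 41)
  expect_identical(t1, t2)
  expect_error(simulate_expression(orth, replicates = 0), "replicates")
  expect_error(simulate_expression(orth,
    effect_map = stats::setNames(-1, "a001")), "negative")
  eff <- stats::setNames(rep(2, 200), orth$gene1)
  te <- simulate_expression(orth, effect_map = eff, seed = 42)
  d0 <- expression_divergence(t1$species1, t1$species2, orth)
  de <- expression_divergence(te$species1, te$species2, orth)
  expect_gt(mean(de$divergence), mean(d0$divergence) + 0.2)
})

test_that("simulated tracks carry planted bumps and respect the unit interval", {
  g <- simulate_ancestor(1, 100, seed = 51)
  anchors <- data.frame(chrom = "chr01",
                        pos = seq(100000, 900000, length.out = 10))
  tr <- simulate_tracks(g, list(
    list(name = "mCG", kind = "fraction", background = 0.5,
         anchors = anchors, contrast = 0.3),
    list(name = "h3k4", kind = "ratio", background = 0,
         anchors = anchors, contrast = -0.3),
    list(name = "flat", kind = "ratio", background = 0.2,
         anchors = anchors[0, ], contrast = 0)), bin_size = 1000, seed = 52)
  expect_true(all(tr$mCG$value >= 0 & tr$mCG$value <= 1))
  expect_lt(stats::sd(tr$flat$value), 0.05)
  # meta-profile recovers the bump height within 2 SE
  mp <- meta_profile(tr$mCG, anchors, flank = 20000, n_windows = 40)
  peak <- mp$mean[which.min(abs(mp$rel_pos))]
  base <- mean(mp$mean[abs(mp$rel_pos) > 15000])
  expect_lt(abs((peak - base) - 0.3), 2 * mp$se[which.min(abs(mp$rel_pos))] + 0.03)
  # opposite contrasts at the same anchors are anti-correlated
  mp2 <- meta_profile(tr$h3k4, anchors, flank = 20000, n_windows = 40)
  expect_lt(stats::cor(mp$mean, mp2$mean), -0.8)
  # an overshooting methylation contrast clips with a warning
  expect_warning(simulate_tracks(g, list(
    list(name = "hot", kind = "fraction", background = 0.9,
         anchors = anchors, contrast = 0.5)), bin_size = 1000, seed = 53),
    "clipping")
})
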