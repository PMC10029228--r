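# Insulation scoring, TAD calling with null calibration, the disjoint
# partition, conservation classification against a brute-force oracle, size
# grouping and break proximity.

test_that("insulation is scale invariant and flat on pure decay", {
  g <- simulate_ancestor(1, 120, seed = 71)
  d <- apply_rearrangements(g, list(), seed = 72)
  m <- simulate_contacts(d$genome, d$truth, 5000, plaid_contrast = 1,
                         tad_enrichment = 1, bias_sd = 0,
                         covariate_bias = FALSE, seed = 73)
  s1 <- insulation_score(m)
  m5 <- m
  m5$pixels$count <- m5$pixels$count * 5
  s5 <- insulation_score(m5)
  expect_equal(s1$score, s5$score, tolerance = 1e-9)
  expect_lt(stats::sd(s1$score, na.rm = TRUE), 0.05)
  expect_error(insulation_score(m, window = 5000), "at least 2 bins")
})

test_that("two adjacent planted domains produce a shared-edge minimum", {
  n <- 80
  d <- abs(outer(1:n, 1:n, "-"))
  m <- 500 / pmax(d, 1)
  tid <- c(rep(1, 40), rep(2, 40))
  same <- outer(tid, tid, "==")
  m[same] <- m[same] * 2
  cm <- cm_from_dense(round(m), bin_size = 5000)
  ins <- insulation_score(cm)
  mid_region <- 35:45
  expect_equal(which.min(ins$score[mid_region]) + 34, 40, tolerance = 2)
})

test_that("TAD calling recovers planted domains and rejects nulls", {
  r <- experiment_tads(n_sims = 4, seed = 88)
  expect_gte(mean(r$f1), 0.9)
  expect_true(all(r$null_tads == 0))
})

test_that("undersized domains are excluded by min_size", {
  g <- simulate_ancestor(1, 230, seed = 91)
  d <- apply_rearrangements(g, list(), seed = 92)
  m <- simulate_contacts(d$genome, d$truth, 5000, seed = 93)
  ts_all <- call_tads(ice_balance(m), min_size = 25000)
  ts_big <- call_tads(ice_balance(m), min_size = 150000)
  expect_true(all(ts_big$domains$size >= 150000))
  expect_lt(nrow(ts_big$domains), nrow(ts_all$domains))
})

test_that("raising the boundary prominence never increases the TAD count", {
  g <- simulate_ancestor(1, 180, seed = 95)
  d <- apply_rearrangements(g, list(), seed = 96)
  m <- ice_balance(simulate_contacts(d$genome, d$truth, 5000, seed = 97))
  counts <- vapply(c(0.05, 0.2, 0.5, 1),
                   function(md) nrow(call_tads(m, min_depth = md)$domains),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the boundary/body/interval partition is disjoint and tiles the genome", {
  g <- simulate_ancestor(1, 180, seed = 101)
  d <- apply_rearrangements(g, list(), seed = 102)
  m <- ice_balance(simulate_contacts(d$genome, d$truth, 5000, seed = 103))
  ts <- call_tads(m)
  part <- tad_partition(ts)
  all_iv <- rbind(cbind(part$boundaries, cls = "b"),
                  cbind(part$bodies, cls = "d"),
                  cbind(part$intervals, cls = "i"))
  all_iv <- all_iv[order(all_iv$start), ]
  # disjoint: no pairwise bp overlap
  expect_true(all(all_iv$start[-1] >= all_iv$end[-nrow(all_iv)] - 1e-9))
  # covers the analyzed chromosome without holes
  expect_equal(all_iv$start[1], 0)
  merged_ok <- all(all_iv$start[-1] <= all_iv$end[-nrow(all_iv)] + 1e-9)
  expect_true(merged_ok)
})

# deterministic toy: domains on two "species" with controllable gene content
toy_tadset <- function(doms) {
  structure(list(domains = cbind(doms, size = doms$end - doms$start),
                 boundaries = data.frame(chrom = character(),
                                         start = numeric(), end = numeric(),
                                         min_bin_start = numeric()),
                 intervals = data.frame(chrom = character(),
                                        start = numeric(), end = numeric()),
                 resolution = 5000), class = "tad_set")
}

test_that("conservation classification follows the majority-target rule exactly", {
  # species 1: one domain with 10 syntenic genes; species 2: genes split 6/4
  d1 <- toy_tadset(data.frame(chrom = "c1", start = 0, end = 100000))
  d2 <- toy_tadset(data.frame(chrom = c("c2", "c2"),
                              start = c(0, 60000), end = c(50000, 120000)))
  genes1 <- data.frame(gene_id = sprintf("a%02d", 1:10), chrom = "c1",
                       start = seq(1000, 91000, by = 10000),
                       end = seq(3000, 93000, by = 10000))
  starts2 <- c(1000, 9000, 17000, 25000, 33000, 41000,
               61000, 69000, 77000, 85000)
  genes2 <- data.frame(gene_id = sprintf("b%02d", 1:10), chrom = "c2",
                       start = starts2, end = starts2 + 2000)
  orth <- data.frame(gene1 = genes1$gene_id, gene2 = genes2$gene_id)
  res <- classify_conserved(d1, d2, orth, genes1, genes2)
  expect_equal(res$syntenic_genes, 10)
  expect_equal(res$overlap_ratio, 0.6)
  expect_equal(res$status, "conserved")
  # exactly four syntenic genes stays unassessed whatever the overlap
  res4 <- classify_conserved(d1, d2, orth[1:4, ], genes1, genes2)
  expect_equal(res4$status, "unassessed")
})

test_that("conservation agrees with a brute-force gene-counting oracle", {
  set.seed(7)
  for (rep in 1:5) {
    n <- 40
    genes1 <- data.frame(gene_id = sprintf("a%02d", 1:n), chrom = "c1",
                         start = sort(sample(0:499, n)) * 1000,
                         end = sort(sample(0:499, n)) * 1000 + 500)
    genes2 <- data.frame(gene_id = sprintf("b%02d", 1:n), chrom = "c2",
                         start = sort(sample(0:499, n)) * 1000,
                         end = sort(sample(0:499, n)) * 1000 + 500)
    orth <- data.frame(gene1 = genes1$gene_id, gene2 = genes2$gene_id)
    cuts1 <- sort(sample(seq(50000, 450000, 1000), 3))
    cuts2 <- sort(sample(seq(50000, 450000, 1000), 3))
    d1 <- toy_tadset(data.frame(chrom = "c1",
                                start = c(0, cuts1), end = c(cuts1, 500500)))
    d2 <- toy_tadset(data.frame(chrom = "c2",
                                start = c(0, cuts2), end = c(cuts2, 500500)))
    res <- classify_conserved(d1, d2, orth, genes1, genes2)
    # oracle: per species-1 domain, count orthologs per species-2 domain
    for (k in seq_len(nrow(d1$domains))) {
      mid1 <- (genes1$start + genes1$end) / 2
      inside <- mid1 >= d1$domains$start[k] & mid1 < d1$domains$end[k]
      ids <- genes1$gene_id[inside]
      if (length(ids) <= 4) {
        expect_equal(res$status[k], "unassessed")
        next
      }
      mid2 <- (genes2$start + genes2$end) / 2
      tgt <- findInterval(mid2[match(orth$gene2[match(ids, orth$gene1)],
                                     genes2$gene_id)],
                          d2$domains$start)
      best <- max(table(tgt))
      ratio <- best / length(ids)
      expect_equal(res$overlap_ratio[k], ratio)
      expect_equal(res$status[k],
                   if (ratio > 0.5) "conserved" else "rearranged")
    }
  }
})

test_that("size grouping and boundary feature contrasts behave", {
  ts <- toy_tadset(data.frame(chrom = "c1", start = c(0, 100000),
                              end = c(50000, 170000)))
  ts <- group_by_size(ts, 60000)
  expect_equal(ts$domains$size_class, c("small", "large"))
  expect_error(group_by_size(ts, 0), "positive")
  # empty class: comparison skipped with a message
  ts2 <- group_by_size(ts, 10000)
  tr <- data.frame(chrom = "c1", start = seq(0, 199000, 1000),
                   end = seq(1000, 200000, 1000), value = 1)
  expect_message(boundary_feature_contrast(ts2, list(m = tr)), "empty")
})

test_that("a planted boundary mark contrast between size classes is detected", {
  set.seed(31)
  n <- 40
  starts <- seq(0, by = 200000, length.out = n)
  sizes <- rep(c(40000, 120000), n / 2)
  doms <- data.frame(chrom = "c1", start = starts, end = starts + sizes)
  ts <- toy_tadset(doms)
  ts$boundaries <- data.frame(
    chrom = "c1",
    start = pmax(0, c(doms$start - 10000, doms$end - 10000)),
    end = c(doms$start + 10000, doms$end + 10000),
    min_bin_start = c(doms$start, doms$end))
  ts <- group_by_size(ts, 60000)
  len <- max(doms$end) + 50000
  tr <- data.frame(chrom = "c1", start = seq(0, len - 1000, 1000),
                   end = seq(1000, len, 1000))
  tr$value <- rnorm(nrow(tr), 0, 0.05)
  # plant +1 at small-TAD boundaries
  small_b <- c(doms$start[sizes == 40000], doms$end[sizes == 40000])
  for (p in small_b) {
    sel <- tr$start >= p - 10000 & tr$end <= p + 10000
    tr$value[sel] <- tr$value[sel] + 1
  }
  res <- boundary_feature_contrast(ts, list(mark = tr))
  expect_lt(res$p, 0.01)
  expect_gt(res$median_small, res$median_large)
})

test_that("break proximity classes are recovered exactly on a planted design", {
  doms <- data.frame(chrom = "c1", start = seq(0, by = 200000,
                                               length.out = 100),
                     end = seq(0, by = 200000, length.out = 100) + 100000)
  ts <- toy_tadset(doms)
  prox_idx <- 1:20
  breaks <- data.frame(chrom = "c1", start = doms$start[prox_idx] + 50000,
                       end = doms$start[prox_idx] + 50001)
  res <- proximity_to_breaks(ts, breaks, window = 0)
  expect_equal(which(res$proximity == "proximal"), prox_idx)
  # breaks on another chromosome leave everything distal
  res2 <- proximity_to_breaks(ts, data.frame(chrom = "cX", start = 1,
                                             end = 2), window = 0)
  expect_true(all(res2$proximity == "distal"))
})

test_that("conserved-TAD counts fall as rearrangement load rises", {
  counts <- numeric(3)
  loads <- list(
    list(),
    list(ev_inversion("chr01", 40, 69)),
    list(ev_inversion("chr01", 40, 69), ev_inversion("chr01", 90, 119),
         ev_translocation("chr02", 30, 59, "chr01", 150)))
  for (li in seq_along(loads)) {
    g <- simulate_ancestor(2, 160, seed = 300)
    d1 <- apply_rearrangements(g, list(), seed = 301, species_id = "s1")
    d2 <- apply_rearrangements(g, loads[[li]], seed = 302, species_id = "s2")
    orth <- ortholog_pairs(d1$genome, d2$genome)
    t1 <- toy_tadset(d1$truth$tads)
    t2 <- toy_tadset(d2$truth$tads)
    res <- classify_conserved(t1, t2, orth, d1$genome$genes, d2$genome$genes)
    counts[li] <- sum(res$status == "conserved")
  }
  expect_true(all(diff(counts) <= 0))
  expect_lt(counts[3], counts[1])
})
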