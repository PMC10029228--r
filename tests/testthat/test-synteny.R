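# Homolog filtering, collinear chaining against exhaustive enumeration,
# Monte-Carlo block significance, break derivation and the threshold sweep.

test_that("homolog filtering applies the e-value and top-rank rules", {
  hits <- data.frame(
    gene1 = c("a", "a", rep("b", 7), "c"),
    gene2 = c("x", "y", paste0("t", 1:7), "z"),
    score = c(50, 60, 90:84, 70),
    evalue = c(1e-4, 1e-9, rep(1e-10, 7), NA))
  expect_message(out <- filter_homologs(hits), "dropped")
  expect_false(any(out$gene1 == "c"))
  expect_false(out$retained[out$gene1 == "a" & out$gene2 == "x"]) # e too big
  expect_true(out$retained[out$gene1 == "a" & out$gene2 == "y"])
  expect_equal(sum(out$retained[out$gene1 == "b"]), 5) # top 5 of 7
  empty <- filter_homologs(hits[0, ])
  expect_equal(nrow(empty), 0)
})

toy_pair <- function(order2, n = length(order2), spacing = 10000) {
  mk <- function(ids, chrom) data.frame(
    gene_id = ids, chrom = chrom,
    start = seq_len(length(ids)) * spacing,
    end = seq_len(length(ids)) * spacing + 2000)
  g1 <- mk(sprintf("a%03d", 1:n), "c1")
  g2 <- mk(sprintf("a%03d", order2), "c2") # shared ids = homologs
  g2$gene_id <- sprintf("b%03d", order2)
  hom <- data.frame(gene1 = sprintf("a%03d", 1:n),
                    gene2 = sprintf("b%03d", 1:n),
                    score = 100, evalue = 1e-20, retained = TRUE)
  list(g1 = g1, g2 = g2, hom = hom)
}

test_that("identical gene orders chain into one forward block", {
  tp <- toy_pair(1:100)
  blocks <- chain_collinear(tp$g1, tp$g2, tp$hom, n_perm = 200, seed = 1)
  expect_equal(nrow(blocks), 1)
  expect_equal(blocks$n_genes, 100)
  expect_equal(blocks$orientation, "+")
})

test_that("a reversed segment yields three blocks with the planted orientations", {
  tp <- toy_pair(c(1:39, 60:40, 61:100))
  blocks <- chain_collinear(tp$g1, tp$g2, tp$hom, min_genes = 10,
                            n_perm = 200, seed = 1)
  blocks <- blocks[order(blocks$r1_start), ]
  expect_equal(nrow(blocks), 3)
  expect_equal(blocks$orientation, c("+", "-", "+"))
  expect_equal(blocks$n_genes, c(39, 21, 40))
})

test_that("chain length equals exhaustive enumeration on small instances", {
  set.seed(9)
  for (rep in 1:6) {
    n <- sample(8:14, 1)
    r1 <- sort(sample(1:25, n))
    r2 <- sample(1:25, n)
    g1 <- data.frame(gene_id = sprintf("a%02d", 1:25), chrom = "c1",
                     start = (1:25) * 1000, end = (1:25) * 1000 + 500)
    g2 <- data.frame(gene_id = sprintf("b%02d", 1:25), chrom = "c2",
                     start = (1:25) * 1000, end = (1:25) * 1000 + 500)
    hom <- data.frame(gene1 = sprintf("a%02d", r1),
                      gene2 = sprintf("b%02d", r2),
                      score = 100, evalue = 1e-20, retained = TRUE)
    blocks <- chain_collinear(g1, g2, hom, max_gap = 30, min_genes = 2,
                              max_p = 1.01, n_perm = 100, seed = 2,
                              skip_syntenic = 100)
    best <- max(blocks$n_genes)
    expect_equal(best, oracle_best_chain_len(r1, r2, 30))
  }
})

test_that("more than 30 intervening non-syntenic genes split a block", {
  # homologs only for genes 1..40 and 72..111 of 120; gap of 31 non-syntenic
  mk <- function(ids, chrom) data.frame(
    gene_id = ids, chrom = chrom, start = seq_along(ids) * 10000,
    end = seq_along(ids) * 10000 + 2000)
  g1 <- mk(sprintf("a%03d", 1:120), "c1")
  g2 <- mk(sprintf("b%03d", 1:120), "c2")
  syn <- c(1:40, 72:111)
  hom <- data.frame(gene1 = sprintf("a%03d", syn),
                    gene2 = sprintf("b%03d", syn),
                    score = 100, evalue = 1e-20, retained = TRUE)
  blocks <- chain_collinear(g1, g2, hom, max_gap = 30, min_genes = 10,
                            n_perm = 100, seed = 3)
  expect_equal(nrow(blocks), 2)
  # with a 30-gene gap the chain stays whole
  syn2 <- c(1:40, 71:110)
  hom2 <- data.frame(gene1 = sprintf("a%03d", syn2),
                     gene2 = sprintf("b%03d", syn2),
                     score = 100, evalue = 1e-20, retained = TRUE)
  blocks2 <- chain_collinear(g1, g2, hom2, max_gap = 30, min_genes = 10,
                             n_perm = 100, seed = 3)
  expect_equal(nrow(blocks2), 1)
})

test_that("Monte-Carlo block p-values separate real from spurious blocks", {
  p_real <- block_pvalue(k = 10, w1 = 20, w2 = 20, dens = 0.05,
                         n_perm = 1000, seed = 4)
  expect_lt(p_real, 0.001)
  p_junk <- block_pvalue(k = 2, w1 = 200, w2 = 200, dens = 0.9,
                         n_perm = 500, seed = 5)
  expect_gt(p_junk, 0.5)
  expect_identical(block_pvalue(5, 30, 30, 0.2, n_perm = 300, seed = 6),
                   block_pvalue(5, 30, 30, 0.2, n_perm = 300, seed = 6))
})

test_that("break derivation recovers planted rearrangements within one gene", {
  pr <- synteny3d:::sim_rearranged_pair(4242)
  orth <- ortholog_pairs(pr$g1, pr$g2)
  hom <- data.frame(gene1 = orth$gene1, gene2 = orth$gene2,
                    score = 100, evalue = 1e-20, retained = TRUE)
  blocks <- chain_collinear(pr$g1$genes, pr$g2$genes, hom, n_perm = 200,
                            seed = 7)
  brk <- derive_breaks(blocks, min_genes = 10, max_gap = 30, pr$g2$genes)
  truth <- truth_breaks_species1(pr$g1, pr$g2)
  sc <- score_breaks(brk, truth)
  expect_equal(sc$recall, 1)
  expect_gte(sc$precision, 0.95)
  expect_true("inversion" %in% brk$category)
  expect_true("translocation" %in% brk$category)
  # the fused chromosome is seen from the other direction
  orth_r <- data.frame(gene1 = orth$gene2, gene2 = orth$gene1)
  hom_r <- data.frame(gene1 = orth_r$gene1, gene2 = orth_r$gene2,
                      score = 100, evalue = 1e-20, retained = TRUE)
  blocks_r <- chain_collinear(pr$g2$genes, pr$g1$genes, hom_r, n_perm = 200,
                              seed = 8)
  brk_r <- derive_breaks(blocks_r, min_genes = 10, max_gap = 30, pr$g1$genes)
  expect_true("fusion/fission" %in% brk_r$category)
  # near-symmetry of the two directions on clean data
  truth_r <- truth_breaks_species1(pr$g2, pr$g1)
  sc_r <- score_breaks(brk_r, truth_r)
  expect_equal(sc_r$recall, 1)
  # unrearranged toy yields no breaks
  tp <- toy_pair(1:60)
  b0 <- chain_collinear(tp$g1, tp$g2, tp$hom, n_perm = 100, seed = 9)
  expect_equal(nrow(derive_breaks(b0, 10, 30)), 0)
})

test_that("the threshold sweep is monotone and reports the knee by second difference", {
  # arithmetic oracle on the documented example curve
  counts <- c(100, 60, 55, 40, 20)
  th <- c(5, 8, 10, 20, 30)
  d2 <- counts[1:3] - 2 * counts[2:4] + counts[3:5]
  expect_equal(th[-c(1, 5)][which.max(d2)], 8)
  # and through the implementation on a simulated pair
  pr <- synteny3d:::sim_rearranged_pair(777)
  orth <- ortholog_pairs(pr$g1, pr$g2)
  hom <- data.frame(gene1 = orth$gene1, gene2 = orth$gene2,
                    score = 100, evalue = 1e-20, retained = TRUE)
  blocks <- chain_collinear(pr$g1$genes, pr$g2$genes, hom, min_genes = 5,
                            n_perm = 200, seed = 10)
  sw <- threshold_sweep(blocks, genes2 = pr$g2$genes)
  expect_true(all(diff(sw$counts$n_breaks) <= 0))
  expect_true(sw$knee %in% sw$counts$threshold)
})
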