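# Contact-matrix model: I/O round trips, ICE balancing against a Sinkhorn
# oracle, Poisson covariate normalization, O/E, trans enrichment and
# origin-stratified decay.

test_that("matrix write/read round-trips losslessly and validates input", {
  set.seed(1)
  m <- matrix(rpois(100, 4), 10)
  m <- m + t(m)
  cm <- cm_from_dense(m)
  tp <- tempfile(); bp <- tempfile()
  write_matrix(cm, tp, bp)
  cm2 <- read_matrix(tp, bp)
  expect_equal(cm$pixels, cm2$pixels)
  expect_equal(cm$bins, cm2$bins)
  bins <- genome_bins(data.frame(chrom = "c1", length = 10000), 1000)
  expect_error(contact_matrix(bins,
    data.frame(bin1 = 0, bin2 = 99, count = 1), 1000), "outside")
  expect_error(contact_matrix(bins,
    data.frame(bin1 = c(0, 1), bin2 = c(1, 0), count = c(1, 2)), 1000),
    "conflicting")
  # symmetric duplicates with equal values collapse cleanly
  ok <- contact_matrix(bins,
    data.frame(bin1 = c(0, 1), bin2 = c(1, 0), count = c(3, 3)), 1000)
  expect_equal(nrow(ok$pixels), 1)
})

test_that("ICE balancing matches an independent Sinkhorn oracle", {
  # the worked 3x3 example
  m3 <- matrix(c(4, 2, 2, 2, 2, 1, 2, 1, 1), 3, byrow = TRUE)
  cm <- cm_from_dense(m3)
  mb <- ice_balance(cm, tol = 1e-9, max_iter = 1000, mask_quantile = 0)
  dm <- cm_dense(mb)
  rs <- rowSums(dm)
  expect_lt(stats::sd(rs) / mean(rs), 1e-6)
  expect_equal(dm / mean(dm), oracle_sinkhorn(m3), tolerance = 1e-7)
  # random positive matrices: row-sum CV under tol, oracle agreement
  set.seed(7)
  for (k in 1:3) {
    n <- 60
    m <- matrix(rgamma(n * n, 2, 1) + 0.2, n)
    m <- m + t(m)
    cm <- cm_from_dense(m)
    mb <- ice_balance(cm, tol = 1e-12, max_iter = 2000, mask_quantile = 0)
    dm <- cm_dense(mb)
    expect_lt(stats::sd(rowSums(dm)) / mean(rowSums(dm)), 1e-5)
    rel <- abs(dm / mean(dm) - oracle_sinkhorn(m)) / oracle_sinkhorn(m)
    expect_lt(max(rel), 1e-8)
  }
  expect_error(ice_balance(contact_matrix(
    genome_bins(data.frame(chrom = "c1", length = 3000), 1000),
    data.frame(bin1 = integer(), bin2 = integer(), count = numeric()),
    1000)), "all-zero")
})

test_that("ICE is a fixed point on constant matrices and equivariant to bin order", {
  m <- matrix(5, 8, 8)
  cm <- cm_from_dense(m)
  mb <- ice_balance(cm, mask_quantile = 0)
  w <- mb$weights
  expect_lt(diff(range(w)), 1e-6)
  dm <- cm_dense(mb)
  expect_lt(max(abs(dm / mean(dm) - 1)), 1e-6)
  # permuting bins permutes the biases identically
  set.seed(3)
  a <- matrix(rgamma(64, 2) + 0.3, 8)
  a <- a + t(a)
  p <- sample(8)
  wa <- ice_balance(cm_from_dense(a), mask_quantile = 0, tol = 1e-10)$weights
  wp <- ice_balance(cm_from_dense(a[p, p]), mask_quantile = 0,
                    tol = 1e-10)$weights
  expect_equal(wp, wa[p], tolerance = 1e-6)
})

test_that("balancing an already balanced matrix changes values below tolerance", {
  set.seed(11)
  m <- matrix(rgamma(400, 2) + 0.3, 20)
  m <- m + t(m)
  mb <- ice_balance(cm_from_dense(m), tol = 1e-10, mask_quantile = 0)
  mb2 <- ice_balance(mb, tol = 1e-10, mask_quantile = 0)
  expect_equal(mb2$pixels$count / mean(mb2$pixels$count),
               mb$pixels$count / mean(mb$pixels$count), tolerance = 1e-6)
})

test_that("Poisson covariate normalization recovers a planted length effect", {
  set.seed(21)
  n <- 80
  len <- runif(n, 0.5, 1.5)
  mu <- 30 * outer(len, len)
  m <- matrix(rpois(n * n, mu), n)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  cm <- cm_from_dense(m)
  cm$covariates <- data.frame(bin_id = 0:(n - 1), len = len,
                              gc = rep(0.5, n), map = rep(1, n))
  hn <- hicnorm_lite(cm)
  cf <- attr(hn, "hicnorm_coefs")$c1
  # recovered coefficient on log(len_i * len_j) ~ 1 within 2 SE (SE ~ small)
  expect_lt(abs(cf[["llen"]] - 1), 0.1)
  # normalized values no longer track the covariate product
  i <- match(hn$pixels$bin1, cm$bins$bin_id)
  j <- match(hn$pixels$bin2, cm$bins$bin_id)
  rho <- suppressWarnings(stats::cor(hn$pixels$count, len[i] * len[j],
                                     method = "spearman"))
  expect_lt(abs(rho), 0.05)
  # constant covariates fall back to (warned) identity scaling
  cm$covariates$len <- 1
  cm$covariates$gc <- 0.5
  cm$covariates$map <- 1
  expect_warning(hn2 <- hicnorm_lite(cm), "identity")
  expect_equal(stats::cor(hn2$pixels$count, cm$pixels$count), 1,
               tolerance = 1e-9)
})

test_that("observed/expected cancels pure distance dependence exactly", {
  n <- 30
  d <- abs(outer(1:n, 1:n, "-"))
  m <- 100 / (d + 1)
  cm <- cm_from_dense(m)
  oe <- observed_expected(cm)
  expect_true(all(abs(oe$pixels$count - 1) < 1e-9))
  # per-diagonal means of O/E equal 1 for any matrix
  set.seed(5)
  m2 <- matrix(rpois(n * n, 20) + 1, n)
  m2 <- m2 + t(m2)
  oe2 <- observed_expected(cm_from_dense(m2))
  dd <- oe2$pixels$bin2 - oe2$pixels$bin1
  means <- tapply(oe2$pixels$count, dd, mean)
  expect_true(all(abs(means - 1) < 1e-9))
})

test_that("trans enrichment matches hand-computed expectations on a 3-chromosome toy", {
  bins <- genome_bins(data.frame(chrom = c("a", "b", "c"),
                                 length = c(2000, 2000, 2000)), 1000)
  # uniform trans background, then double a-b
  px <- expand.grid(bin1 = 0:5, bin2 = 0:5)
  px <- px[px$bin1 < px$bin2, ]
  chrom_of <- bins$chrom[px$bin1 + 1]
  chrom_of2 <- bins$chrom[px$bin2 + 1]
  px <- px[chrom_of != chrom_of2, ]
  px$count <- 10
  ab <- bins$chrom[px$bin1 + 1] == "a" & bins$chrom[px$bin2 + 1] == "b"
  px$count[ab] <- 20
  cm <- contact_matrix(bins, px, 1000)
  te <- trans_enrichment(cm)
  expect_equal(sum(te$expected), sum(te$observed))
  expect_gt(te$score[te$chrom1 == "a" & te$chrom2 == "b"], 0)
  expect_lt(max(te$score[!(te$chrom1 == "a" & te$chrom2 == "b")]), 0)
  # exactly proportional marginals give zero scores
  px$count <- 10
  te0 <- trans_enrichment(contact_matrix(bins, px, 1000))
  expect_true(all(abs(te0$score) < 1e-9))
  # no trans contacts is an error
  cis_only <- px[0, ]
  expect_error(trans_enrichment(contact_matrix(bins, cis_only, 1000)),
               "trans")
})

test_that("origin-stratified decay flags single-origin chromosomes", {
  g <- simulate_ancestor(1, 80, seed = 61)
  d <- apply_rearrangements(g, list(), seed = 62)
  m <- simulate_contacts(d$genome, d$truth, 5000, seed = 63)
  dec <- cis_decay_by_origin(m, d$genome$origin, chrom = "chr01")
  expect_true(all(dec$n_diff == 0))
  expect_true("chr01" %in% attr(dec, "single_origin"))
})
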