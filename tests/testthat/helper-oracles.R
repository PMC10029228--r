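# Independent oracles used across the suite. These deliberately take the
# slow, obvious route so they share no code with the implementation.

# Sinkhorn balancing of a dense symmetric matrix, run to tight convergence;
# returns the balanced matrix scaled to mean 1 over unmasked cells.
oracle_sinkhorn <- function(m, tol = 1e-14, max_iter = 5000) {
  b <- rep(1, nrow(m))
  for (i in seq_len(max_iter)) {
    s <- rowSums(m / outer(b, b))
    if (stats::sd(s) / mean(s) < tol) break
    b <- b * sqrt(s / mean(s))
  }
  bal <- m / outer(b, b)
  bal / mean(bal)
}

# exact two-sided Fisher p for a 2x2 table by hypergeometric enumeration
oracle_fisher_p <- function(tab) {
  m <- tab[1, 1] + tab[1, 2]
  n <- tab[2, 1] + tab[2, 2]
  k <- tab[1, 1] + tab[2, 1]
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# brute-force overlap check: does interval a overlap any b (half-open)?
oracle_any_overlap <- function(a_start, a_end, b) {
  any(b$start < a_end & b$end > a_start)
}

# exhaustive longest collinear chain on a tiny anchor set (<= 15 anchors):
# depth-first over all chains monotone in r1 and monotone (either direction)
# in r2, with at most max_gap skipped ranks between consecutive anchors.
oracle_best_chain_len <- function(r1, r2, max_gap) {
  n <- length(r1)
  best <- 0
  extend <- function(last, len, dir) {
    best <<- max(best, len)
    for (j in seq_len(n)) {
      if (r1[j] <= r1[last]) next
      if (r1[j] - r1[last] > max_gap + 1) next
      step2 <- r2[j] - r2[last]
      if (dir == 0) {
        if (abs(step2) == 0 || abs(step2) > max_gap + 1) next
        extend(j, len + 1, sign(step2))
      } else {
        if (sign(step2) != dir || abs(step2) > max_gap + 1) next
        extend(j, len + 1, dir)
      }
    }
  }
  for (i in seq_len(n)) extend(i, 1, 0)
  best
}

# exhaustive two-sided rank-sum p by permutation enumeration (small n)
oracle_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pooled), n1)
  obs <- sum(rank(pooled)[seq_len(n1)])
  stats_all <- apply(idx, 2, function(ii) sum(rank(pooled)[ii]))
  mu <- mean(stats_all)
  mean(abs(stats_all - mu) >= abs(obs - mu) - 1e-9)
}

# tiny helper: dense symmetric count matrix -> contact_matrix
cm_from_dense <- function(m, bin_size = 1000, chrom = "c1") {
  bins <- genome_bins(data.frame(chrom = chrom, length = nrow(m) * bin_size),
                      bin_size)
  idx <- which(upper.tri(m, diag = TRUE), arr.ind = TRUE)
  px <- data.frame(bin1 = idx[, 1] - 1L, bin2 = idx[, 2] - 1L,
                   count = m[idx])
  px <- px[px$count != 0, ]
  contact_matrix(bins, px, bin_size)
}
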