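# Interval shuffling nulls, overlap quantification and Fisher exact
# co-localization tests (bedtools-style conventions).

#' Shuffle intervals within chromosomes
#'
#' Re-places each chromosome's intervals uniformly at random among all
#' non-overlapping arrangements that preserve the per-chromosome interval
#' length multiset: n start offsets are drawn uniformly in the chromosome
#' length minus the total interval length, sorted, and offset by the
#' cumulative lengths of the preceding intervals (in random interval
#' order). Deterministic per seed.
#'
#' @param intervals data.frame (`chrom`, `start`, `end`).
#' @param chrom_sizes data.frame (`chrom`, `length`).
#' @param seed RNG seed.
#' @return shuffled data.frame with the same per-chromosome length multiset.
#' @export
shuffle_intervals <- function(intervals, chrom_sizes, seed = NULL) {
  with_seed(seed, {
    out <- intervals
    for (ch in unique(intervals$chrom)) {
      sel <- which(intervals$chrom == ch)
      len <- intervals$end[sel] - intervals$start[sel]
      L <- chrom_sizes$length[chrom_sizes$chrom == ch]
      if (!length(L)) stop("chromosome ", ch, " missing from chrom_sizes")
      free <- L - sum(len)
      if (free < 0)
        stop("cannot place intervals without overlap on ", ch)
      ord <- sample(seq_along(sel))
      u <- sort(stats::runif(length(sel), 0, free))
      starts <- u + cumsum(c(0, len[ord][-length(ord)]))
      out$start[sel[ord]] <- round(starts)
      out$end[sel[ord]] <- round(starts) + len[ord]
    }
    out
  })
}

#' Fraction of A intervals overlapping B
#'
#' Overlap means a non-empty intersection under half-open semantics
#' (touching intervals do not overlap).
#'
#' @param a,b interval data.frames (`chrom`, `start`, `end`).
#' @return list with `fraction`, `n_overlap`, `n_total`.
#' @export
overlap_fraction <- function(a, b) {
  if (!nrow(a)) stop("empty query interval set")
  if (!nrow(b)) return(list(fraction = 0, n_overlap = 0L, n_total = nrow(a)))
  hit <- logical(nrow(a))
  for (ch in unique(a$chrom)) {
    bi <- b[b$chrom == ch, , drop = FALSE]
    ai <- which(a$chrom == ch)
    if (!nrow(bi) || !length(ai)) next
    # merge b intervals, then a query overlaps iff the merged interval at or
    # before its start reaches past it, or the next one begins before its end
    o <- order(bi$start)
    bs <- bi$start[o]; be <- cummax(bi$end[o])
    if (length(bs) == 1L || all(bs[-1] >= be[-length(be)])) {
      ms <- bs; me <- be # already disjoint (the common case post-shuffle)
    } else {
      grp <- cumsum(c(TRUE, bs[-1] > be[-length(be)]))
      ms <- as.numeric(tapply(bs, grp, min))
      me <- as.numeric(tapply(be, grp, max))
    }
    idx <- findInterval(a$start[ai], ms)
    nxt <- idx + 1L
    hit[ai] <- (idx >= 1L & me[pmax(idx, 1L)] > a$start[ai]) |
      (nxt <= length(ms) & ms[pmin(nxt, length(ms))] < a$end[ai])
  }
  n <- sum(hit)
  list(fraction = n / nrow(a), n_overlap = as.integer(n), n_total = nrow(a))
}

#' Fisher exact co-localization test
#'
#' Builds the bedtools-fisher style 2x2 table: n11 = A intervals overlapping
#' B, n12 = |A| - n11, n21 = |B| - n11, n22 = floor(genome length / mean
#' interval length) - n11 - n12 - n21 (clamped at 0 with a warning), and
#' applies the two-tailed exact test. The n22 cell is a modeling convention
#' for "placeable non-events"; the permutation test
#' ([empirical_enrichment()]) is the recommended primary statistic.
#'
#' @param a,b non-empty interval sets.
#' @param chrom_sizes data.frame (`chrom`, `length`).
#' @return list: `table`, `odds_ratio`, `p`.
#' @export
fisher_colocalization <- function(a, b, chrom_sizes) {
  if (!nrow(a) || !nrow(b)) stop("empty interval set")
  ov <- overlap_fraction(a, b)
  n11 <- ov$n_overlap
  n12 <- nrow(a) - n11
  n21 <- nrow(b) - n11
  mlen <- mean(c(a$end - a$start, b$end - b$start))
  slots <- floor(sum(chrom_sizes$length) / mlen)
  n22 <- slots - n11 - n12 - n21
  if (n22 < 0) {
    warning("n22 underflow clamped to 0")
    n22 <- 0
  }
  tab <- matrix(c(n11, n12, n21, n22), 2, byrow = TRUE)
  ft <- stats::fisher.test(tab)
  list(table = tab, odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Permutation co-localization test
#'
#' Null distribution of the overlap fraction of A in B under per-chromosome
#' interval shuffling of A, B, or both; empirical p uses the +1 correction
#' and is never 0.
#'
#' @param a,b interval sets.
#' @param chrom_sizes data.frame (`chrom`, `length`).
#' @param n_perm permutations (>= 100).
#' @param mode `"shuffle_A"`, `"shuffle_B"` or `"shuffle_both"`.
#' @param seed RNG seed.
#' @return list: `observed`, `null_mean`, `null_sd`, `p`, `mode`, `n_perm`,
#'   `seed`, and the Fisher result under `fisher`.
#' @export
empirical_enrichment <- function(a, b, chrom_sizes, n_perm = 1000,
                                 mode = c("shuffle_both", "shuffle_A",
                                          "shuffle_B"),
                                 seed = 1) {
  mode <- match.arg(mode)
  if (n_perm < 100) stop("n_perm must be >= 100")
  obs <- overlap_fraction(a, b)$fraction
  null <- numeric(n_perm)
  with_seed(seed, {
    for (k in seq_len(n_perm)) {
      aa <- if (mode %in% c("shuffle_A", "shuffle_both"))
        shuffle_intervals(a, chrom_sizes) else a
      bb <- if (mode %in% c("shuffle_B", "shuffle_both"))
        shuffle_intervals(b, chrom_sizes) else b
      null[k] <- overlap_fraction(aa, bb)$fraction
    }
  })
  list(observed = obs, null_mean = mean(null), null_sd = stats::sd(null),
       p = (1 + sum(null >= obs)) / (n_perm + 1), mode = mode,
       n_perm = n_perm, seed = seed,
       fisher = fisher_colocalization(a, b, chrom_sizes))
}
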