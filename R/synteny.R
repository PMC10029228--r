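# Homolog filtering, collinear-block chaining, block significance, synteny
# break derivation and the minimal-gene threshold sweep.

#' Filter raw homolog hits
#'
#' Retains hits with e-value <= `max_evalue` that rank within the top
#' `top_n` matches of their query gene, applied in both directions (the hit
#' must be a top match of gene1 and, among hits sharing gene2, a top match
#' of gene2). Rows without an e-value are dropped with a message.
#'
#' @param hits data.frame `gene1`, `gene2`, `score`, `evalue`.
#' @param max_evalue e-value ceiling.
#' @param top_n per-query rank ceiling.
#' @return the table with a logical `retained` column.
#' @export
filter_homologs <- function(hits, max_evalue = 1e-5, top_n = 5) {
  if (!nrow(hits)) {
    hits$retained <- logical(0)
    return(hits)
  }
  bad <- is.na(hits$evalue)
  if (any(bad)) {
    message(sum(bad), " hits without e-value dropped")
    hits <- hits[!bad, , drop = FALSE]
  }
  rank_within <- function(key) {
    ord <- order(key, hits$evalue, -hits$score)
    r <- integer(nrow(hits))
    r[ord] <- stats::ave(seq_along(ord), key[ord], FUN = seq_along)
    r
  }
  r1 <- rank_within(hits$gene1)
  r2 <- rank_within(hits$gene2)
  hits$retained <- hits$evalue <= max_evalue & r1 <= top_n & r2 <= top_n
  rownames(hits) <- NULL
  hits
}

#' Chain homolog anchors into collinear syntenic blocks
#'
#' Anchors (retained homolog pairs placed at gene-rank coordinates on each
#' chromosome) are chained per chromosome pair by dynamic programming:
#' maximal anchor-count monotone chains, strictly increasing in species 1
#' and strictly monotone (increasing for `+`, decreasing for `-`) in
#' species 2. Between consecutive anchors a chain may skip at most `max_gap`
#' non-syntenic genes (genes without a retained homolog) and at most
#' `skip_syntenic` homolog-bearing genes on each side — so a chain cannot
#' bridge a rearranged segment that belongs in its own block. Consecutive
#' anchors hitting the same target gene are collapsed beforehand. Chains are
#' extracted best-first; each anchor joins at most one block; blocks with
#' fewer than `min_genes` anchors are discarded. Block p-values come from
#' [block_pvalue()]; blocks with p >= `max_p` are discarded.
#'
#' @param genes1,genes2 gene tables (`gene_id`, `chrom`, `start`, `end`);
#'   gene rank is the order within each chromosome by start.
#' @param homologs homolog table (rows with `retained == FALSE` ignored).
#' @param max_gap maximum intervening non-syntenic genes.
#' @param min_genes minimum anchors per block.
#' @param max_p block p-value ceiling.
#' @param n_perm,seed Monte-Carlo settings for [block_pvalue()].
#' @param skip_syntenic maximum homolog-bearing genes a chain may skip.
#' @return data.frame of blocks (`block_id`, `chrom1`, `chrom2`,
#'   `orientation`, `n_genes`, rank and bp extents, `p`) with per-anchor
#'   rows in attribute `anchors`.
#' @export
chain_collinear <- function(genes1, genes2, homologs, max_gap = 30,
                            min_genes = 10, max_p = 0.05, n_perm = 1000,
                            seed = 1, skip_syntenic = 5) {
  if (!is.null(homologs$retained)) homologs <- homologs[homologs$retained, ]
  rank_tab <- function(genes) {
    genes <- genes[order(genes$chrom, genes$start), ]
    genes$rank <- stats::ave(genes$start, genes$chrom, FUN = seq_along)
    genes
  }
  g1 <- rank_tab(genes1); g2 <- rank_tab(genes2)
  i1 <- match(homologs$gene1, g1$gene_id)
  i2 <- match(homologs$gene2, g2$gene_id)
  ok <- !is.na(i1) & !is.na(i2)
  anch <- data.frame(gene1 = homologs$gene1[ok], gene2 = homologs$gene2[ok],
                     chrom1 = g1$chrom[i1[ok]], r1 = g1$rank[i1[ok]],
                     chrom2 = g2$chrom[i2[ok]], r2 = g2$rank[i2[ok]],
                     s1 = g1$start[i1[ok]], e1 = g1$end[i1[ok]],
                     s2 = g2$start[i2[ok]], e2 = g2$end[i2[ok]])
  # genes carrying any retained homolog ("syntenic"): chains must not skip
  # more than a few of these
  syn_gene1 <- unique(homologs$gene1)
  syn_gene2 <- unique(homologs$gene2)
  blocks <- list(); anchors_out <- list(); bid <- 0L
  for (key in unique(paste(anch$chrom1, anch$chrom2))) {
    a <- anch[paste(anch$chrom1, anch$chrom2) == key, ]
    a <- a[order(a$r1, a$r2), ]
    # tandem collapse: consecutive anchors (by r1) on the same target gene
    dup <- c(FALSE, a$gene2[-1] == a$gene2[-nrow(a)] &
               (a$r1[-1] - a$r1[-nrow(a)]) <= 1)
    a <- a[!dup, , drop = FALSE]
    n1 <- max(g1$rank[g1$chrom == a$chrom1[1]])
    n2 <- max(g2$rank[g2$chrom == a$chrom2[1]])
    t1 <- g1[g1$chrom == a$chrom1[1], ]
    cum1 <- cumsum(t1$gene_id[order(t1$rank)] %in% syn_gene1)
    t2 <- g2[g2$chrom == a$chrom2[1], ]
    cum2 <- cumsum(t2$gene_id[order(t2$rank)] %in% syn_gene2)
    dens <- nrow(a) / n1
    avail <- rep(TRUE, nrow(a))
    repeat {
      best <- best_chain(a, avail, max_gap, cum1, cum2, skip_syntenic)
      if (length(best) < min_genes) break
      bid <- bid + 1L
      ch <- a[best, ]
      orient <- if (nrow(ch) >= 2 && ch$r2[2] < ch$r2[1]) "-" else "+"
      p <- block_pvalue(nrow(ch), diff(range(ch$r1)) + 1,
                        diff(range(ch$r2)) + 1, dens, max_gap = max_gap,
                        n_perm = n_perm, seed = seed + bid)
      blocks[[bid]] <- data.frame(
        block_id = bid, chrom1 = ch$chrom1[1], chrom2 = ch$chrom2[1],
        orientation = orient, n_genes = nrow(ch),
        r1_start = min(ch$r1), r1_end = max(ch$r1),
        r2_start = min(ch$r2), r2_end = max(ch$r2),
        bp1_start = min(ch$s1), bp1_end = max(ch$e1),
        bp2_start = min(ch$s2), bp2_end = max(ch$e2), p = p)
      anchors_out[[bid]] <- cbind(block_id = bid, ch)
      avail[best] <- FALSE
    }
  }
  empty <- data.frame(block_id = integer(), chrom1 = character(),
                      chrom2 = character(), orientation = character(),
                      n_genes = integer(), r1_start = integer(),
                      r1_end = integer(), r2_start = integer(),
                      r2_end = integer(), bp1_start = numeric(),
                      bp1_end = numeric(), bp2_start = numeric(),
                      bp2_end = numeric(), p = numeric())
  res <- if (length(blocks)) do.call(rbind, blocks) else empty
  res <- res[is.na(res$p) | res$p < max_p, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "anchors") <- if (length(anchors_out))
    do.call(rbind, anchors_out) else NULL
  res
}

# best (longest) chain over available anchors, both orientations; returns
# row indices into `a` in chain order. cum1/cum2: cumulative counts of
# homolog-bearing genes by rank, used to limit skips over syntenic genes.
best_chain <- function(a, avail, max_gap, cum1, cum2, skip_syntenic) {
  idx <- which(avail)
  if (!length(idx)) return(integer(0))
  r1 <- a$r1[idx]; r2 <- a$r2[idx]
  n <- length(idx)
  syn_between <- function(cum, lo, hi) { # syntenic genes strictly between
    if (hi - lo < 2) return(0)
    cum[hi - 1] - cum[lo]
  }
  allowed <- function(k, b, sign2) {
    s1 <- syn_between(cum1, r1[k], r1[b])
    if (s1 > skip_syntenic) return(FALSE)
    if ((r1[b] - r1[k] - 1) - s1 > max_gap) return(FALSE)
    lo2 <- min(r2[k], r2[b]); hi2 <- max(r2[k], r2[b])
    s2 <- syn_between(cum2, lo2, hi2)
    if (s2 > skip_syntenic) return(FALSE)
    if ((hi2 - lo2 - 1) - s2 > max_gap) return(FALSE)
    TRUE
  }
  gm <- max_gap + skip_syntenic + 1
  run <- function(sign2) {
    score <- rep(1L, n); prev <- rep(0L, n)
    for (b in seq_len(n)) {
      cand <- which(r1 < r1[b] & r1 >= r1[b] - gm)
      if (sign2 > 0) cand <- cand[r2[cand] < r2[b] & r2[cand] >= r2[b] - gm]
      else cand <- cand[r2[cand] > r2[b] & r2[cand] <= r2[b] + gm]
      if (length(cand)) {
        ok <- vapply(cand, allowed, logical(1), b = b, sign2 = sign2)
        cand <- cand[ok]
      }
      if (length(cand)) {
        k <- cand[which.max(score[cand])]
        score[b] <- score[k] + 1L
        prev[b] <- k
      }
    }
    list(score = score, prev = prev)
  }
  fw <- run(1); rv <- run(-1)
  use_fw <- max(fw$score) >= max(rv$score)
  dp <- if (use_fw) fw else rv
  b <- which.max(dp$score)
  chain <- integer(0)
  while (b != 0L) {
    chain <- c(b, chain)
    b <- dp$prev[b]
  }
  idx[chain]
}

#' Monte-Carlo block p-value
#'
#' Probability, under random anchor placement at the chromosome pair's
#' anchor density, of observing a monotone chain of at least `k` anchors
#' within a `w1`-by-`w2` gene-rank window: permutation draws scatter
#' `round(dens * w1)` anchors uniformly in the window and measure the
#' longest strictly monotone (either orientation) subsequence. Deterministic
#' per seed.
#'
#' @param k observed anchor count of the block (>= 2).
#' @param w1,w2 gene-rank window spans on the two species.
#' @param dens genome-wide anchors per species-1 gene on the chromosome pair.
#' @param max_gap unused placeholder kept for interface symmetry.
#' @param n_perm permutation count (>= 100 recommended).
#' @param seed RNG seed.
#' @return MC p-value with +1 correction; 1 for degenerate windows.
#' @export
block_pvalue <- function(k, w1, w2, dens, max_gap = 30, n_perm = 1000,
                         seed = 1) {
  if (k < 2 || w1 < 1 || w2 < 1) return(1)
  m <- round(dens * w1)
  if (m < 1) m <- 1
  with_seed(seed, {
    hits <- 0L
    for (p in seq_len(n_perm)) {
      x <- sample.int(w1, m, replace = TRUE)
      y <- sample.int(w2, m, replace = TRUE)
      o <- order(x, y)
      L <- max(lis_length(y[o]), lis_length(-y[o]))
      if (L >= k) hits <- hits + 1L
    }
    (1 + hits) / (n_perm + 1)
  })
}

# longest strictly increasing subsequence length (patience algorithm)
lis_length <- function(v) {
  tails <- numeric(0)
  for (x in v) {
    pos <- findInterval(x - 0.5, tails) + 1L
    if (pos > length(tails)) tails <- c(tails, x) else tails[pos] <- x
  }
  length(tails)
}

#' Derive synteny breaks from chained blocks
#'
#' Walks retained blocks along each species-1 chromosome in gene-rank order
#' and emits a break between consecutive blocks whose species-2 side is
#' discontiguous: different species-2 chromosome (translocation, or
#' fusion/fission when both block ends are terminal on their species-2
#' chromosomes), flipped orientation (inversion), a same-chromosome
#' displacement beyond `max_gap` genes or against the running direction
#' (unclassified), or a species-2 rank gap occupied by another retained
#' block (an inserted segment of different origin; translocation when that
#' block comes from another species-1 chromosome). The break interval on
#' each species is the half-open gap between the adjacent block ends (a
#' 1-bp point when empty). Category assignment is heuristic.
#'
#' @param blocks block table from [chain_collinear()].
#' @param min_genes only blocks with at least this many anchors delimit
#'   breaks.
#' @param max_gap same-chromosome rank gap tolerated as contiguity.
#' @param genes2 optional species-2 gene table used to judge terminal blocks
#'   for the fusion/fission call.
#' @return data.frame of breaks: species-1 and species-2 intervals, flanking
#'   block ids, `category`.
#' @export
derive_breaks <- function(blocks, min_genes = 10, max_gap = 30,
                          genes2 = NULL) {
  b <- blocks[blocks$n_genes >= min_genes, , drop = FALSE]
  out <- list()
  n2_of <- NULL
  if (!is.null(genes2))
    n2_of <- tapply(genes2$gene_id, genes2$chrom, length)
  for (ch in unique(b$chrom1)) {
    bb <- b[b$chrom1 == ch, ]
    bb <- bb[order(bb$r1_start), ]
    if (nrow(bb) < 2) next
    for (k in seq_len(nrow(bb) - 1)) {
      up <- bb[k, ]; dn <- bb[k + 1, ]
      cat <- NULL
      if (up$chrom2 != dn$chrom2) {
        cat <- "translocation"
        if (!is.null(n2_of)) {
          term <- function(blk) {
            blk$r2_start <= max_gap ||
              blk$r2_end >= n2_of[[blk$chrom2]] - max_gap
          }
          if (term(up) && term(dn)) cat <- "fusion/fission"
        }
      } else if (up$orientation != dn$orientation) {
        cat <- "inversion"
      } else {
        gap2 <- if (up$orientation == "+") dn$r2_start - up$r2_end
                else up$r2_start - dn$r2_end
        if (gap2 < 0 || gap2 > max_gap + 1) {
          cat <- "unclassified"
        } else if (gap2 > 1) {
          # an intervening retained block occupying the species-2 gap marks
          # an inserted segment of different origin
          glo <- min(up$r2_end, dn$r2_start, up$r2_start, dn$r2_end)
          ghi <- max(up$r2_end, dn$r2_start)
          occ <- b[b$block_id != up$block_id & b$block_id != dn$block_id &
                     b$chrom2 == up$chrom2 &
                     b$r2_start < ghi & b$r2_end > glo, , drop = FALSE]
          if (nrow(occ))
            cat <- if (any(occ$chrom1 != ch)) "translocation" else "unclassified"
        }
      }
      if (is.null(cat)) next
      s1 <- up$bp1_end; e1 <- dn$bp1_start
      if (e1 <= s1) { s1 <- round((s1 + e1) / 2); e1 <- s1 + 1 }
      if (up$chrom2 == dn$chrom2) {
        ends2 <- sort(c(up$bp2_start, up$bp2_end, dn$bp2_start, dn$bp2_end))
        s2 <- ends2[2]; e2 <- max(ends2[3], ends2[2] + 1)
      } else s2 <- e2 <- NA_real_
      out[[length(out) + 1]] <- data.frame(
        chrom1 = ch, start1 = s1, end1 = e1,
        chrom2_up = up$chrom2, chrom2_dn = dn$chrom2,
        start2 = s2, end2 = e2,
        block_up = up$block_id, block_dn = dn$block_id, category = cat)
    }
  }
  res <- do.call(rbind, out) %||%
    data.frame(chrom1 = character(), start1 = numeric(), end1 = numeric(),
               chrom2_up = character(), chrom2_dn = character(),
               start2 = numeric(), end2 = numeric(),
               block_up = integer(), block_dn = integer(),
               category = character())
  rownames(res) <- NULL
  res
}

#' Sweep the minimal-gene threshold
#'
#' Re-derives breaks at each threshold and reports the count curve plus the
#' knee (threshold of maximum second difference of the counts; reported, not
#' applied).
#'
#' @param blocks block table from [chain_collinear()].
#' @param thresholds minimal-gene values to sweep.
#' @param max_gap,genes2 passed to [derive_breaks()].
#' @return list with `counts` (data.frame `threshold`, `n_breaks`) and
#'   `knee`.
#' @export
threshold_sweep <- function(blocks, thresholds = c(5, 8, 10, 20, 30),
                            max_gap = 30, genes2 = NULL) {
  thresholds <- sort(thresholds)
  n <- vapply(thresholds, function(t)
    nrow(derive_breaks(blocks, min_genes = t, max_gap = max_gap,
                       genes2 = genes2)), numeric(1))
  counts <- data.frame(threshold = thresholds, n_breaks = n)
  knee <- NA_real_
  if (length(n) >= 3) {
    d2 <- n[-c(length(n) - 1, length(n))] - 2 * n[-c(1, length(n))] +
      n[-c(1, 2)]
    knee <- thresholds[-c(1, length(thresholds))][which.max(d2)]
  }
  list(counts = counts, knee = knee)
}
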