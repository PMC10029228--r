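# Insulation-score TAD detection with boundary/body/interval partitioning,
# cross-species conservation, size grouping and break proximity.

#' Insulation score track
#'
#' For bin i, the mean contact in the `window`-by-`window` square spanning
#' the upstream and downstream flanks of i is computed from the balanced cis
#' matrix; the score is the log2 ratio of that statistic to its
#' chromosome-wide mean. Missing near chromosome ends and at masked bins.
#'
#' @param x balanced `contact_matrix` at TAD resolution (default 5 kb).
#' @param window window size in bp (must span >= 2 bins).
#' @return data.frame (`chrom`, `start`, `end`, `score`).
#' @export
insulation_score <- function(x, window = 50000) {
  w <- as.integer(round(window / x$resolution))
  if (w < 2) stop("window must span at least 2 bins")
  bins <- x$bins
  score <- rep(NA_real_, nrow(bins))
  for (ch in unique(bins$chrom)) {
    ids <- chrom_bin_ids(x, ch)
    rows <- match(ids, bins$bin_id)
    m <- cm_dense(x, ch)
    n <- nrow(m)
    if (n < 2 * w + 1) next
    raw <- rep(NA_real_, n)
    for (i in (w + 1):(n - w)) {
      sq <- m[(i - w):(i - 1), (i + 1):(i + w)]
      raw[i] <- mean(sq, na.rm = TRUE)
    }
    # balancing distorts bins near chromosome ends (truncated decay inflates
    # their biases); scores touching that zone are unreliable and dropped
    if (n > 4 * w) raw[c(seq_len(2 * w), (n - 2 * w + 1):n)] <- NA_real_
    mu <- mean(raw, na.rm = TRUE)
    if (is.finite(mu) && mu > 0) score[rows] <- log2(raw / mu)
  }
  data.frame(chrom = bins$chrom, start = bins$start, end = bins$end,
             score = score)
}

#' Call TADs from an insulation track
#'
#' Local insulation minima with a two-sided score rise of at least
#' `min_depth` mark the inter-domain valleys (the "bottom points" of the
#' domain interaction triangles); a chromosome without such minima yields no
#' TADs. Domains are then delimited on the raw-scale O/E map (reconstructed
#' through the balancing weights, with each bin's long-range O/E level
#' divided out as its bias): a bin belongs to a domain when its mean O/E
#' with its `edge_k` nearest neighbours on at least one side exceeds an
#' adaptive threshold (the geometric midpoint of the 10th/90th percentile
#' levels), maximal runs of such bins (after filling 1-bin holes and
#' dropping runs of up to 3 bins) are candidates, and each candidate's two
#' edges are refined to the corner positions maximizing inside-minus-
#' crossing mean O/E. A candidate is retained as a TAD only if its mean
#' intra-domain O/E exceeds `intra_flank_ratio` times the mean O/E of pairs
#' crossing its edges and its span is at least `min_size`; rejected spans
#' become inter-TAD intervals — the non-side-by-side convention of plant
#' genomes. Boundary regions are the domain corner +-10 kb.
#'
#' @param x balanced `contact_matrix` at TAD resolution.
#' @param insulation insulation track from [insulation_score()] (recomputed
#'   when NULL).
#' @param window insulation window bp (also the prominence search span).
#' @param min_depth minimum two-sided insulation rise at a valley.
#' @param min_size minimum TAD size bp.
#' @param intra_flank_ratio minimum intra-domain / cross-edge O/E ratio.
#' @param boundary_flank half-width of emitted boundary regions (bp).
#' @param edge_k neighbour span (bins) of the membership statistic.
#' @param corner_w corner-refinement window (bins).
#' @return a `tad_set`: list of `domains`, `boundaries`, `intervals`
#'   data.frames, `resolution`; domains carry `size` bp.
#' @export
call_tads <- function(x, insulation = NULL, window = 50000, min_depth = 0.1,
                      min_size = 25000, intra_flank_ratio = 1.2,
                      boundary_flank = 10000, edge_k = 4, corner_w = 8) {
  res <- x$resolution
  w <- as.integer(round(window / res))
  doms <- list(); bounds <- list(); ivals <- list()
  for (ch in unique(x$bins$chrom)) {
    b <- x$bins[x$bins$chrom == ch, ]
    n <- nrow(b)
    oec <- bias_corrected_oe(x, ch)
    if (!is.null(insulation)) {
      s <- insulation$score[insulation$chrom == ch]
    } else {
      # insulation on the bias/plaid-corrected O/E map: the distance decay
      # and compartment structure cancel, leaving crisp domain valleys
      sq <- rep(NA_real_, n)
      if (n > 2 * w) for (i in (w + 1):(n - w))
        sq[i] <- mean(oec[(i - w):(i - 1), (i + 1):(i + w)], na.rm = TRUE)
      mu <- mean(sq, na.rm = TRUE)
      s <- if (is.finite(mu) && mu > 0) log2(sq / mu) else rep(NA_real_, n)
    }
    # local minima with classic (unbounded) prominence: walk outward until
    # the score rises by min_depth or a lower point is reached — wide
    # valleys (large inter-TAD holes) stay detectable
    mins <- integer(0)
    for (i in seq_len(n)) {
      if (!is.finite(s[i])) next
      if (i > 1 && is.finite(s[i - 1]) && s[i - 1] < s[i]) next
      if (i < n && is.finite(s[i + 1]) && s[i + 1] <= s[i]) next
      ok_l <- FALSE
      for (j in rev(seq_len(i - 1))) {
        if (!is.finite(s[j])) next
        if (s[j] < s[i]) break
        if (s[j] - s[i] >= min_depth) { ok_l <- TRUE; break }
      }
      ok_r <- FALSE
      if (i < n) for (j in (i + 1):n) {
        if (!is.finite(s[j])) next
        if (s[j] < s[i]) break
        if (s[j] - s[i] >= min_depth) { ok_r <- TRUE; break }
      }
      if (ok_l && ok_r) mins <- c(mins, i)
    }
    chrom_len <- max(b$end)
    if (!length(mins)) {
      warning(sprintf("chromosome %s: no insulation minima", ch))
      ivals[[ch]] <- complement_intervals(ch, chrom_len, NULL)
      next
    }
    # short-range O/E membership: a bin inside a domain is enriched against
    # its immediate neighbours on at least one side; valley/gap bins are not
    memb <- vapply(seq_len(n), function(i) {
      r <- if (i < n) mean(oec[i, (i + 1):min(i + edge_k, n)], na.rm = TRUE)
           else NA_real_
      l <- if (i > 1) mean(oec[max(i - edge_k, 1):(i - 1), i], na.rm = TRUE)
           else NA_real_
      suppressWarnings(max(r, l, na.rm = TRUE))
    }, numeric(1))
    if (sum(is.finite(memb) & memb > 0) < 10) {
      ivals[[ch]] <- complement_intervals(ch, chrom_len, NULL)
      next
    }
    # a bin is domain-like when its membership exceeds the chromosome-wide
    # threshold: the geometric midpoint of the 10th/90th percentile levels
    fin <- memb[is.finite(memb) & memb > 0]
    q <- stats::quantile(fin, c(0.1, 0.9))
    thr <- sqrt(q[1] * q[2])
    good <- is.finite(memb) & memb >= thr
    # fill 1-bin holes, then drop islands of up to 3 bins
    for (pass in 1:2) {
      r <- rle(good)
      nr <- length(r$lengths)
      if (nr > 2) for (j in 2:(nr - 1))
        if (!r$values[j] && r$lengths[j] <= 1 && r$values[j - 1] &&
              r$values[j + 1]) r$values[j] <- TRUE
      good <- inverse.rle(r)
    }
    r <- rle(good)
    r$values[r$lengths <= 3 & r$values] <- FALSE
    good <- inverse.rle(r)
    runs <- rle(good)
    rends <- cumsum(runs$lengths)
    rstarts <- rends - runs$lengths + 1
    cand <- cbind(rstarts[runs$values], rends[runs$values])
    # a prominent insulation minimum strictly inside a run marks side-by-side
    # domains (e.g. remnants abutting at a rearrangement junction): split
    if (nrow(cand)) {
      split_cand <- list()
      for (k in seq_len(nrow(cand))) {
        pieces <- cand[k, , drop = FALSE]
        inner <- sort(mins[mins > cand[k, 1] + 2 & mins < cand[k, 2] - 2])
        if (length(inner)) {
          cuts <- c(cand[k, 1] - 1, inner, cand[k, 2] + 1)
          pieces <- cbind(head(cuts, -1) + 1, tail(cuts, -1) - 1)
        }
        split_cand[[k]] <- pieces
      }
      cand <- do.call(rbind, split_cand)
    }
    if (nrow(cand)) for (k in seq_len(nrow(cand))) {
      edges <- refine_corners(oec, cand[k, 1], cand[k, 2], corner_w)
      i1 <- edges[1]; i2 <- edges[2]
      size <- b$end[i2] - b$start[i1]
      if (size < min_size || i2 - i1 < 1) next
      # each edge must face an insulation valley (or the unscored chromosome
      # end) — the "bottom point" evidence that a domain triangle ends here
      gate_l <- i1 <= 2 * w + 2 || any(mins >= i1 - 2 * w - 5 & mins < i1 + 3)
      gate_r <- i2 >= n - 2 * w - 1 || any(mins > i2 - 3 & mins <= i2 + 2 * w + 5)
      if (!gate_l || !gate_r) next
      inner <- i1:i2
      intra <- oec[inner, inner]
      intra <- mean(intra[upper.tri(intra)], na.rm = TRUE)
      fl <- if (i1 > 1) max(1, i1 - corner_w):(i1 - 1) else integer(0)
      fr <- if (i2 < n) (i2 + 1):min(n, i2 + corner_w) else integer(0)
      cross <- c(if (length(fl)) oec[fl, inner], if (length(fr)) oec[inner, fr])
      cross <- mean(cross, na.rm = TRUE)
      if (!is.finite(intra) || !is.finite(cross) || cross <= 0 ||
          intra / cross < intra_flank_ratio) next
      doms[[length(doms) + 1]] <- data.frame(
        chrom = ch, start = b$start[i1], end = b$end[i2])
      for (edge_bp in c(b$start[i1], b$end[i2]))
        bounds[[length(bounds) + 1]] <- data.frame(
          chrom = ch, start = max(0, edge_bp - boundary_flank),
          end = min(chrom_len, edge_bp + boundary_flank),
          min_bin_start = edge_bp)
    }
    # intervals: the chromosome minus domains and boundary regions
    occ <- rbind(
      if (length(doms)) {
        dd <- do.call(rbind, doms); dd[dd$chrom == ch, c("chrom", "start", "end")]
      },
      if (length(bounds)) {
        bb <- do.call(rbind, bounds); bb[bb$chrom == ch, c("chrom", "start", "end")]
      })
    ivals[[ch]] <- complement_intervals(ch, chrom_len, occ)
  }
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric())
  out <- list(domains = if (length(doms)) do.call(rbind, doms) else empty,
              boundaries = if (length(bounds)) do.call(rbind, bounds) else
                cbind(empty, data.frame(min_bin_start = numeric())),
              intervals = do.call(rbind, ivals) %||% empty,
              resolution = res)
  if (nrow(out$domains)) out$domains$size <- out$domains$end - out$domains$start
  rownames(out$domains) <- rownames(out$boundaries) <- rownames(out$intervals) <- NULL
  class(out) <- "tad_set"
  out
}

# Raw-scale O/E of one chromosome with per-bin long-range O/E level divided
# out. Balancing weights (when present) reconstruct raw counts; masked bins
# stay missing. Long-range level (pairs > `far` bins apart) estimates the
# multiplicative bin bias without absorbing domain-scale structure.
bias_corrected_oe <- function(x, ch, far = 20) {
  m <- cm_dense(x, ch)
  ids <- chrom_bin_ids(x, ch)
  n <- nrow(m)
  if (!is.null(x$weights)) {
    wt <- x$weights[ids + 1L]
    m <- m * outer(wt, wt)
    m[is.na(wt), ] <- NA
    m[, is.na(wt)] <- NA
  }
  oe <- matrix(NA_real_, n, n)
  for (d in 0:(n - 1)) {
    idx <- cbind(1:(n - d), (1:(n - d)) + d)
    mu <- mean(m[idx], na.rm = TRUE)
    if (is.finite(mu) && mu > 0) oe[idx] <- m[idx] / mu
  }
  oe[lower.tri(oe)] <- t(oe)[lower.tri(oe)]
  if (n > far + 2) {
    off <- abs(outer(seq_len(n), seq_len(n), "-"))
    far_oe <- oe
    far_oe[off <= far] <- NA
    bl <- rowMeans(far_oe, na.rm = TRUE)
    bl[!is.finite(bl) | bl <= 0] <- NA
    oe <- oe / outer(bl, bl)
    # estimate and divide out long-range block structure (same-sign pairs of
    # the far-O/E correlation eigenvector are uniformly elevated): one pass
    # removes the compartment plaid; on mosaic chromosomes whose leading
    # structure is ancestral-origin preservation, a second pass removes the
    # plaid after the origin factor — so domain membership contrast is
    # homogeneous along the chromosome
    far_oe <- far_oe / outer(bl, bl)
    for (pass in 1:3) {
      cc <- suppressWarnings(stats::cor(far_oe, use = "pairwise.complete.obs"))
      cc[!is.finite(cc)] <- 0
      sgn <- eigen(cc, symmetric = TRUE)$vectors[, 1] > 0
      same_sign <- outer(sgn, sgn, "==")
      r_same <- mean(far_oe[same_sign], na.rm = TRUE)
      r_diff <- mean(far_oe[!same_sign], na.rm = TRUE)
      if (!is.finite(r_same) || !is.finite(r_diff) || r_diff <= 0) break
      ratio <- r_same / r_diff
      if (ratio <= 1.05) break
      oe[same_sign] <- oe[same_sign] / ratio
      far_oe[same_sign] <- far_oe[same_sign] / ratio
    }
  }
  oe
}

refine_corners <- function(oec, a, b, w) {
  n <- nrow(oec)
  corner <- function(i1, i2, side) {
    lo <- if (side == "start") i1 else max(i2 - w, i1, 1)
    hi <- if (side == "start") min(i1 + w, i2, n) else i2
    inside <- oec[lo:hi, lo:hi]
    inside <- mean(inside[upper.tri(inside)], na.rm = TRUE)
    cross <- if (side == "start") {
      if (i1 > 1) mean(oec[max(1, i1 - w):(i1 - 1), lo:hi], na.rm = TRUE)
      else NA_real_
    } else {
      if (i2 < n) mean(oec[lo:hi, (i2 + 1):min(n, i2 + w)], na.rm = TRUE)
      else NA_real_
    }
    if (!is.finite(inside) || !is.finite(cross)) return(NA_real_)
    inside - cross
  }
  rng1 <- max(2, a - 3):max(min(a + 3, b - 4), max(2, a - 3))
  cs <- vapply(rng1, function(x) corner(x, b, "start"), numeric(1))
  a2 <- if (all(is.na(cs))) a else rng1[which.max(cs)]
  rng2 <- min(max(a2 + 4, b - 3), n - 1):min(b + 3, n - 1)
  ce <- vapply(rng2, function(x) corner(a2, x, "end"), numeric(1))
  b2 <- if (all(is.na(ce))) b else rng2[which.max(ce)]
  c(a2, b2)
}

complement_intervals <- function(chrom, len, occ) {
  if (is.null(occ) || !nrow(occ))
    return(data.frame(chrom = chrom, start = 0, end = len))
  occ <- occ[order(occ$start), ]
  st <- c(0, occ$end)
  en <- c(occ$start, len)
  keep <- en > st
  data.frame(chrom = chrom, start = st[keep], end = en[keep])
}

#' Disjoint boundary / body / interval partition
#'
#' Converts a `tad_set` into the three mutually disjoint region classes used
#' for co-localization testing: boundary regions (domain corner +-10 kb),
#' domain bodies (domains minus their boundary overlap) and inter-TAD
#' intervals (everything else), which together tile each analyzed
#' chromosome.
#'
#' @param tadset a `tad_set`.
#' @return list of data.frames `boundaries`, `bodies`, `intervals`.
#' @export
tad_partition <- function(tadset) {
  b <- tadset$boundaries
  # merge overlapping boundary regions (corners closer than two flanks)
  if (nrow(b) > 1) {
    merged <- list()
    for (ch in unique(b$chrom)) {
      bb <- b[b$chrom == ch, , drop = FALSE]
      bb <- bb[order(bb$start), ]
      en <- cummax(bb$end)
      grp <- cumsum(c(TRUE, bb$start[-1] > en[-length(en)]))
      merged[[ch]] <- data.frame(chrom = ch,
                                 start = tapply(bb$start, grp, min),
                                 end = tapply(bb$end, grp, max))
    }
    b <- do.call(rbind, merged)
    rownames(b) <- NULL
  }
  d <- tadset$domains
  bodies <- list()
  if (nrow(d)) for (k in seq_len(nrow(d))) {
    cuts <- b[b$chrom == d$chrom[k] & b$start < d$end[k] &
                b$end > d$start[k], , drop = FALSE]
    occ <- cuts[order(cuts$start), , drop = FALSE]
    lo <- d$start[k]
    for (j in seq_len(nrow(occ))) {
      if (occ$start[j] > lo)
        bodies[[length(bodies) + 1]] <- data.frame(
          chrom = d$chrom[k], start = lo, end = occ$start[j])
      lo <- max(lo, occ$end[j])
    }
    if (lo < d$end[k])
      bodies[[length(bodies) + 1]] <- data.frame(
        chrom = d$chrom[k], start = lo, end = d$end[k])
  }
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric())
  bodies <- do.call(rbind, bodies) %||% empty
  # intervals: complement of boundaries and bodies
  ivals <- list()
  chroms <- unique(c(b$chrom, d$chrom, tadset$intervals$chrom))
  for (ch in chroms) {
    len <- max(tadset$intervals$end[tadset$intervals$chrom == ch],
               d$end[d$chrom == ch], b$end[b$chrom == ch])
    occ <- rbind(b[b$chrom == ch, c("chrom", "start", "end")],
                 bodies[bodies$chrom == ch, , drop = FALSE])
    occ <- occ[order(occ$start), , drop = FALSE]
    # merge before complementing (boundaries of adjacent domains may touch)
    if (nrow(occ) > 1) {
      keep_s <- occ$start
      keep_e <- cummax(occ$end)
      grp <- cumsum(c(TRUE, keep_s[-1] > keep_e[-length(keep_e)]))
      occ <- data.frame(chrom = ch,
                        start = tapply(occ$start, grp, min),
                        end = tapply(occ$end, grp, max))
    }
    ivals[[ch]] <- complement_intervals(ch, len, occ)
  }
  list(boundaries = b[, c("chrom", "start", "end")], bodies = bodies,
       intervals = do.call(rbind, ivals) %||% empty)
}

#' @export
print.tad_set <- function(x, ...) {
  cat(sprintf("tad_set: %d domains, %d boundaries, %d intervals @ %d bp\n",
              nrow(x$domains), nrow(x$boundaries), nrow(x$intervals),
              x$resolution))
  invisible(x)
}

#' Classify TADs as conserved or rearranged across species
#'
#' For each species-1 domain, the syntenic genes it contains are mapped to
#' species-2 domains through the ortholog table; the overlap ratio is the
#' fraction falling in the single best-covered target domain. A domain is
#' conserved when it holds more than `min_syntenic` syntenic genes and the
#' ratio exceeds `overlap_threshold`; domains at or below `min_syntenic`
#' genes are unassessed. With `mode = "any"` the ratio counts orthologs
#' falling in any species-2 domain instead.
#'
#' @param tads1,tads2 `tad_set`s for the two species.
#' @param orthologs data.frame `gene1`, `gene2`.
#' @param genes1,genes2 gene coordinate tables.
#' @param min_syntenic retain domains with strictly more syntenic genes.
#' @param overlap_threshold conservation requires ratio strictly above this.
#' @param mode `"best"` (single best-covered target domain) or `"any"`.
#' @return data.frame per species-1 domain: `syntenic_genes`, `best_target`,
#'   `overlap_ratio`, `status` in {conserved, rearranged, unassessed}.
#' @export
classify_conserved <- function(tads1, tads2, orthologs, genes1, genes2,
                               min_syntenic = 4, overlap_threshold = 0.5,
                               mode = c("best", "any")) {
  mode <- match.arg(mode)
  d1 <- tads1$domains; d2 <- tads2$domains
  syn1 <- genes1[genes1$gene_id %in% orthologs$gene1, ]
  g2 <- genes2[match(orthologs$gene2, genes2$gene_id), ]
  mid2 <- (g2$start + g2$end) / 2
  dom2_of <- rep(NA_integer_, nrow(orthologs))
  if (nrow(d2)) for (k in seq_len(nrow(d2))) {
    sel <- g2$chrom == d2$chrom[k] & mid2 >= d2$start[k] & mid2 < d2$end[k]
    dom2_of[sel] <- k
  }
  names(dom2_of) <- orthologs$gene1
  out <- list()
  for (k in seq_len(nrow(d1))) {
    mid1 <- (syn1$start + syn1$end) / 2
    inside <- syn1$chrom == d1$chrom[k] & mid1 >= d1$start[k] & mid1 < d1$end[k]
    ids <- syn1$gene_id[inside]
    ntot <- length(ids)
    if (ntot <= min_syntenic) {
      out[[k]] <- data.frame(domain = k, chrom = d1$chrom[k],
                             start = d1$start[k], end = d1$end[k],
                             syntenic_genes = ntot, best_target = NA_integer_,
                             overlap_ratio = NA_real_, status = "unassessed")
      next
    }
    targets <- dom2_of[ids]
    tt <- table(targets[!is.na(targets)])
    if (mode == "any") {
      ratio <- sum(!is.na(targets)) / ntot
      best <- if (length(tt)) as.integer(names(tt)[which.max(tt)]) else NA_integer_
    } else if (length(tt)) {
      mx <- max(tt)
      cand <- as.integer(names(tt)[tt == mx])
      if (length(cand) > 1) { # tie-break: larger reciprocal overlap, then leftmost
        recip <- vapply(cand, function(j) {
          injm <- names(dom2_of)[!is.na(dom2_of) & dom2_of == j]
          if (!length(injm)) return(0)
          sum(injm %in% ids) / length(injm)
        }, numeric(1))
        cand <- cand[order(-recip, d2$start[cand])]
      }
      best <- cand[1]
      ratio <- mx / ntot
    } else {
      best <- NA_integer_; ratio <- 0
    }
    out[[k]] <- data.frame(domain = k, chrom = d1$chrom[k],
                           start = d1$start[k], end = d1$end[k],
                           syntenic_genes = ntot, best_target = best,
                           overlap_ratio = ratio,
                           status = if (ratio > overlap_threshold) "conserved"
                                    else "rearranged")
  }
  res <- do.call(rbind, out) %||%
    data.frame(domain = integer(), chrom = character(), start = numeric(),
               end = numeric(), syntenic_genes = integer(),
               best_target = integer(), overlap_ratio = numeric(),
               status = character())
  rownames(res) <- NULL
  res
}

#' Group TADs by size
#'
#' @param tadset a `tad_set`.
#' @param threshold size threshold in bp: `small` below, `large` at or above.
#' @return the `tad_set` with a `size_class` column on domains.
#' @export
group_by_size <- function(tadset, threshold) {
  if (threshold <= 0) stop("threshold must be positive")
  if (nrow(tadset$domains))
    tadset$domains$size_class <-
      ifelse(tadset$domains$size < threshold, "small", "large")
  tadset
}

#' Compare a mark at boundaries of small vs large TADs
#'
#' Mean track signal over each TAD's boundary regions is compared between
#' size classes with a two-sided Wilcoxon rank-sum test per mark.
#'
#' @param tadset a size-grouped `tad_set` (see [group_by_size()]).
#' @param tracks named list of signal tracks (`chrom`, `start`, `end`,
#'   `value`).
#' @return data.frame per mark: class medians, `n_small`, `n_large`, `p`
#'   (NA with a message when a class is empty).
#' @export
boundary_feature_contrast <- function(tadset, tracks) {
  d <- tadset$domains
  if (is.null(d$size_class)) stop("run group_by_size() first")
  bgr <- as_granges(tadset$boundaries)
  # boundary value per domain: mean over the two flanking boundary regions
  dval <- function(track) {
    tg <- as_granges(track)
    hits <- GenomicRanges::findOverlaps(bgr, tg)
    bv <- tapply(track$value[S4Vectors::subjectHits(hits)],
                 S4Vectors::queryHits(hits), mean)
    bvals <- rep(NA_real_, nrow(tadset$boundaries))
    bvals[as.integer(names(bv))] <- bv
    vapply(seq_len(nrow(d)), function(k) {
      sel <- tadset$boundaries$chrom == d$chrom[k] &
        (abs(tadset$boundaries$min_bin_start - d$start[k]) <= tadset$resolution * 3 |
         abs(tadset$boundaries$min_bin_start - d$end[k]) <= tadset$resolution * 3)
      mean(bvals[sel], na.rm = TRUE)
    }, numeric(1))
  }
  out <- lapply(names(tracks), function(nm) {
    v <- dval(tracks[[nm]])
    sm <- v[d$size_class == "small" & is.finite(v)]
    lg <- v[d$size_class == "large" & is.finite(v)]
    if (!length(sm) || !length(lg)) {
      message("boundary_feature_contrast: empty size class for ", nm)
      return(data.frame(mark = nm, median_small = NA, median_large = NA,
                        n_small = length(sm), n_large = length(lg), p = NA))
    }
    p <- suppressWarnings(stats::wilcox.test(sm, lg)$p.value)
    data.frame(mark = nm, median_small = stats::median(sm),
               median_large = stats::median(lg), n_small = length(sm),
               n_large = length(lg), p = p)
  })
  do.call(rbind, out)
}

#' Classify TADs by proximity to synteny breaks
#'
#' A domain (including its boundary regions) is proximal when it lies within
#' `window` bp of any break.
#'
#' @param tadset a `tad_set`.
#' @param breaks data.frame (`chrom`, `start`, `end`).
#' @param window proximity window bp.
#' @return the domain table with a `proximity` column in
#'   {proximal, distal}.
#' @export
proximity_to_breaks <- function(tadset, breaks, window = 10000) {
  d <- tadset$domains
  if (!nrow(d)) return(d)
  ext <- data.frame(chrom = d$chrom,
                    start = pmax(0, d$start - 10000 - window),
                    end = d$end + 10000 + window)
  hit <- suppressWarnings(
    GenomicRanges::countOverlaps(as_granges(ext), as_granges(breaks))) > 0
  d$proximity <- ifelse(hit, "proximal", "distal")
  d
}
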