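# Signal-track utilities and expression statistics: histone scores,
# methylation binning, meta-profiles around anchors, RPKM and orthologous
# expression divergence, rank-sum group comparisons.

#' Histone signal score from ChIP and input counts
#'
#' Counts are depth-scaled to counts-per-million, then
#' `log2((chip + c) / (input + c))` per bin.
#'
#' @param chip,input binned count tracks (`chrom`, `start`, `end`, `value`)
#'   with identical binning.
#' @param pseudocount added after depth scaling.
#' @return a ratio-kind signal track.
#' @export
histone_score <- function(chip, input, pseudocount = 0.5) {
  if (nrow(chip) != nrow(input) ||
      any(chip$chrom != input$chrom | chip$start != input$start))
    stop("chip and input tracks must share identical binning")
  cpm <- function(v) v * 1e6 / max(sum(v), 1)
  v <- log2((cpm(chip$value) + pseudocount) / (cpm(input$value) + pseudocount))
  out <- chip
  out$value <- v
  attr(out, "kind") <- "ratio"
  out
}

#' Weighted methylation level per bin
#'
#' Cytosine sites with coverage below `min_coverage` are excluded; the bin
#' value is the coverage-weighted level sum(meth)/sum(total) over passing
#' sites of the requested context. Bins without passing sites are missing.
#'
#' @param sites data.frame (`chrom`, `pos`, `context`, `meth`, `total`).
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @param min_coverage minimum mapped reads per site.
#' @param bin_size bin width bp.
#' @param chrom_sizes data.frame (`chrom`, `length`).
#' @return fraction-kind signal track (value NA for empty bins).
#' @export
methylation_binned <- function(sites, context = c("CG", "CHG", "CHH"),
                               min_coverage = 5, bin_size = 1000,
                               chrom_sizes = NULL) {
  context <- match.arg(context)
  s <- sites[sites$context == context & sites$total >= min_coverage, ]
  if (is.null(chrom_sizes)) {
    chrom_sizes <- stats::aggregate(pos ~ chrom, sites, max)
    names(chrom_sizes) <- c("chrom", "length")
    chrom_sizes$length <- chrom_sizes$length + 1
  }
  bins <- genome_bins(chrom_sizes, bin_size)
  key <- paste(bins$chrom, bins$start %/% bin_size)
  q <- paste(s$chrom, s$pos %/% bin_size)
  idx <- match(q, key)
  msum <- tapply_sum(s$meth, idx[!is.na(idx)], nrow(bins))
  tsum <- tapply_sum(s$total, idx[!is.na(idx)], nrow(bins))
  out <- data.frame(chrom = bins$chrom, start = bins$start, end = bins$end,
                    value = ifelse(tsum > 0, msum / tsum, NA_real_))
  attr(out, "kind") <- "fraction"
  out
}

#' Aggregate meta-profile of a track around anchors
#'
#' Extracts the track in `flank` bp on both sides of each anchor, resampled
#' to `n_windows` relative-position windows, flipping minus-strand anchors,
#' and averages across anchors. Anchors too close to a chromosome end are
#' trimmed out and counted.
#'
#' @param track signal track (`chrom`, `start`, `end`, `value`).
#' @param anchors data.frame (`chrom`, `pos`, optional `strand`).
#' @param flank half-width bp (default +-20 kb).
#' @param n_windows number of relative windows across the 2*flank span.
#' @return data.frame (`window`, `rel_pos`, `mean`, `se`, `n`) with the
#'   trimmed-anchor count as attribute `trimmed`.
#' @export
meta_profile <- function(track, anchors, flank = 20000, n_windows = 40) {
  res <- max(track$end - track$start)
  win_bp <- 2 * flank / n_windows
  prof <- matrix(NA_real_, nrow(anchors), n_windows)
  trimmed <- 0L
  for (k in seq_len(nrow(anchors))) {
    ch <- anchors$chrom[k]
    tv <- track[track$chrom == ch, ]
    lo <- anchors$pos[k] - flank
    hi <- anchors$pos[k] + flank
    if (lo < 0 || hi > max(tv$end)) {
      trimmed <- trimmed + 1L
      next
    }
    centers <- lo + (seq_len(n_windows) - 0.5) * win_bp
    v <- tv$value[findInterval(centers, tv$start)]
    if (identical(anchors$strand[k], "-")) v <- rev(v)
    prof[k, ] <- v
  }
  used <- stats::complete.cases(prof)
  m <- colMeans(prof[used, , drop = FALSE])
  se <- apply(prof[used, , drop = FALSE], 2, stats::sd) / sqrt(max(sum(used), 1))
  out <- data.frame(window = seq_len(n_windows),
                    rel_pos = (seq_len(n_windows) - 0.5) * win_bp - flank,
                    mean = m, se = se, n = sum(used))
  attr(out, "trimmed") <- trimmed
  out
}

#' RPKM expression summary of a replicate count table
#'
#' RPKM = count * 1e9 / (length * library size) per replicate with library
#' size the table's total counts; e = log10(mean RPKM + pseudocount).
#'
#' @param counts data.frame `gene_id`, `length`, `rep1..repN`.
#' @param pseudocount added before log10.
#' @return the table with per-replicate RPKM columns, `mean_rpkm` and `e`.
#' @export
expression_table <- function(counts, pseudocount = 0.01) {
  repcols <- grep("^rep", names(counts), value = TRUE)
  rpkm <- sapply(repcols, function(rc) {
    lib <- sum(counts[[rc]])
    counts[[rc]] * 1e9 / (counts$length * lib)
  })
  if (is.null(dim(rpkm))) rpkm <- matrix(rpkm, nrow = 1)
  out <- counts
  for (i in seq_along(repcols)) out[[paste0("rpkm", i)]] <- rpkm[, i]
  out$mean_rpkm <- rowMeans(rpkm)
  out$e <- log10(out$mean_rpkm + pseudocount)
  out
}

#' Absolute orthologous expression divergence
#'
#' |e1 - e2| per ortholog pair, with e the log10 mean RPKM from
#' [expression_table()]. Pairs missing from either table are dropped and
#' counted.
#'
#' @param tab1,tab2 expression tables (raw count tables are summarized
#'   automatically).
#' @param orthologs data.frame `gene1`, `gene2`.
#' @param pseudocount passed to [expression_table()].
#' @return data.frame (`gene1`, `gene2`, `e1`, `e2`, `divergence`) with
#'   attribute `dropped`.
#' @export
expression_divergence <- function(tab1, tab2, orthologs, pseudocount = 0.01) {
  if (is.null(tab1$e)) tab1 <- expression_table(tab1, pseudocount)
  if (is.null(tab2$e)) tab2 <- expression_table(tab2, pseudocount)
  e1 <- tab1$e[match(orthologs$gene1, tab1$gene_id)]
  e2 <- tab2$e[match(orthologs$gene2, tab2$gene_id)]
  ok <- !is.na(e1) & !is.na(e2)
  out <- data.frame(gene1 = orthologs$gene1[ok], gene2 = orthologs$gene2[ok],
                    e1 = e1[ok], e2 = e2[ok],
                    divergence = abs(e1[ok] - e2[ok]))
  attr(out, "dropped") <- sum(!ok)
  out
}

#' Two-group rank-sum comparison
#'
#' Wilcoxon rank-sum test: exact for combined n <= 20 without ties, normal
#' approximation with tie correction otherwise. Constant pooled values give
#' p = 1.
#'
#' @param values numeric vector.
#' @param groups two-level factor/vector of the same length.
#' @param alternative passed to [stats::wilcox.test()].
#' @return list: `statistic`, `p`, `n1`, `n2`.
#' @export
group_compare <- function(values, groups, alternative = "two.sided") {
  g <- if (is.factor(groups)) groups else factor(groups)
  if (nlevels(g) != 2) stop("exactly two groups required")
  x <- values[g == levels(g)[1]]
  y <- values[g == levels(g)[2]]
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  if (stats::sd(values) == 0)
    return(list(statistic = NA_real_, p = 1, n1 = length(x), n2 = length(y)))
  exact <- length(x) + length(y) <= 20 && !anyDuplicated(values)
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = alternative,
                                            exact = exact, correct = !exact))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       n1 = length(x), n2 = length(y))
}

#' Write a signal track as bedGraph / read one back
#'
#' @param track signal track data.frame.
#' @param path file path.
#' @export
write_bedgraph <- function(track, path) {
  utils::write.table(track[, c("chrom", "start", "end", "value")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path) {
  utils::read.table(path, sep = "\t", header = FALSE,
                    col.names = c("chrom", "start", "end", "value"))
}
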