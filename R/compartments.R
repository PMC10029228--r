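# A/B compartment calling and cross-species switch analysis.

#' Call A/B compartments from a balanced contact matrix
#'
#' Per chromosome: observed/expected transform, Pearson correlation matrix of
#' O/E rows, leading eigenvector; the sign is oriented so that the
#' correlation between the eigenvector and per-bin gene density is
#' non-negative (A compartments are gene dense). Bins with positive oriented
#' loading are labelled A, negative B; masked/degenerate bins are NA.
#' Chromosomes whose |orientation correlation| falls below `flag_threshold`
#' are flagged for review (labels are still emitted).
#'
#' @param x a balanced `contact_matrix` (typically 50-kb resolution).
#' @param gene_density numeric vector of per-bin gene counts (bin order).
#' @param flag_threshold orientation-correlation magnitude below which a
#'   chromosome is flagged.
#' @return a `compartment_profile`: data.frame (`chrom`, `start`, `end`,
#'   `pc1`, `label`) with per-chromosome orientation correlations in
#'   attribute `orientation` and flagged chromosomes in attribute `flagged`.
#' @export
call_compartments <- function(x, gene_density, flag_threshold = 0.3) {
  oe <- observed_expected(x)
  bins <- x$bins
  pc1 <- rep(NA_real_, nrow(bins))
  lab <- rep(NA_character_, nrow(bins))
  orient <- c()
  flagged <- character(0)
  for (ch in unique(bins$chrom)) {
    ids <- chrom_bin_ids(x, ch)
    rows <- match(ids, bins$bin_id)
    m <- cm_dense(oe, ch)
    ok <- apply(m, 1, function(r) sum(is.finite(r)) > 2) &
      apply(m, 1, function(r) stats::sd(r[is.finite(r)]) > 0)
    if (sum(ok) < 10) {
      warning(sprintf("chromosome %s: too few usable bins; labels NA", ch))
      next
    }
    mm <- m[ok, ok, drop = FALSE]
    mm[!is.finite(mm)] <- 0
    cc <- suppressWarnings(stats::cor(mm))
    if (any(!is.finite(cc))) {
      warning(sprintf("chromosome %s: degenerate correlation matrix; labels NA", ch))
      next
    }
    ev <- eigen(cc, symmetric = TRUE)$vectors[, 1]
    gd <- gene_density[rows][ok]
    r <- suppressWarnings(stats::cor(ev, gd))
    if (!is.finite(r)) r <- 0
    if (r < 0) ev <- -ev
    orient[ch] <- abs(r)
    if (abs(r) < flag_threshold) flagged <- c(flagged, ch)
    pc1[rows[ok]] <- ev
    lab[rows[ok]] <- ifelse(ev > 0, "A", "B")
  }
  prof <- data.frame(chrom = bins$chrom, start = bins$start, end = bins$end,
                     pc1 = pc1, label = lab)
  attr(prof, "orientation") <- orient
  attr(prof, "flagged") <- flagged
  class(prof) <- c("compartment_profile", "data.frame")
  prof
}

#' Genome fraction in A and B compartments
#'
#' @param profile a `compartment_profile`.
#' @return named numeric `c(A=, B=)` percentages of the labelled genome
#'   length (summing to 100).
#' @export
compartment_fractions <- function(profile) {
  ok <- !is.na(profile$label)
  if (!any(ok)) return(c(A = NA_real_, B = NA_real_))
  w <- profile$end[ok] - profile$start[ok]
  a <- sum(w[profile$label[ok] == "A"])
  c(A = 100 * a / sum(w), B = 100 * (sum(w) - a) / sum(w))
}

#' Classify cross-species compartment switches on syntenic gene pairs
#'
#' Each syntenic ortholog pair is assigned the state implied by the
#' compartment labels of the bins containing the two genes' midpoints:
#' stableA, stableB, AtoB or BtoA (species1 -> species2). Pairs falling in
#' NA bins (or outside the bin tables) are dropped and counted.
#'
#' @param profile1,profile2 `compartment_profile`s of the two species.
#' @param orthologs data.frame `gene1`, `gene2`.
#' @param genes1,genes2 gene tables (`gene_id`, `chrom`, `start`, `end`).
#' @return a `switch_call` data.frame (`gene1`, `gene2`, `chrom`, `start`,
#'   `end`, `state`) with the 4-state count table in attribute `counts` and
#'   the dropped-pair count in attribute `dropped`.
#' @export
classify_switches <- function(profile1, profile2, orthologs, genes1, genes2) {
  lab_at <- function(profile, genes, ids) {
    res <- max(profile$end - profile$start)
    g <- genes[match(ids, genes$gene_id), ]
    mids <- (g$start + g$end) / 2
    key <- paste(profile$chrom, profile$start %/% res)
    q <- paste(g$chrom, mids %/% res)
    list(label = profile$label[match(q, key)], g = g)
  }
  l1 <- lab_at(profile1, genes1, orthologs$gene1)
  l2 <- lab_at(profile2, genes2, orthologs$gene2)
  state <- ifelse(l1$label == "A" & l2$label == "A", "stableA",
           ifelse(l1$label == "B" & l2$label == "B", "stableB",
           ifelse(l1$label == "A" & l2$label == "B", "AtoB", "BtoA")))
  ok <- !is.na(l1$label) & !is.na(l2$label)
  out <- data.frame(gene1 = orthologs$gene1[ok], gene2 = orthologs$gene2[ok],
                    chrom = l1$g$chrom[ok], start = l1$g$start[ok],
                    end = l1$g$end[ok], state = state[ok])
  attr(out, "counts") <- table(factor(out$state,
    levels = c("stableA", "stableB", "AtoB", "BtoA")))
  attr(out, "dropped") <- sum(!ok)
  class(out) <- c("switch_call", "data.frame")
  out
}

#' Break-adjacent compartment-switch enrichment
#'
#' Partitions syntenic genes into break-adjacent (within `window` bp of a
#' synteny break on species-1 coordinates) versus background, and tests each
#' switch state with a two-tailed Fisher exact test on the 2x2 table
#' {adjacent, background} x {state, other}. Raw p-values are emitted
#' alongside Benjamini-Hochberg adjusted ones.
#'
#' @param switches a `switch_call` table (species-1 coordinates).
#' @param breaks data.frame (`chrom`, `start`, `end`) of break intervals.
#' @param window adjacency window in bp (default +-10 kb).
#' @return data.frame per state: counts, odds ratio, `p`, `p_adj`.
#' @export
break_adjacent_switch_enrichment <- function(switches, breaks, window = 10000) {
  gr_g <- as_granges(switches)
  exp_b <- data.frame(chrom = breaks$chrom,
                      start = pmax(breaks$start - window, 0),
                      end = breaks$end + window)
  hit <- GenomicRanges::countOverlaps(gr_g, as_granges(exp_b)) > 0
  if (!any(hit)) stop("no break-adjacent syntenic genes in window")
  states <- c("stableA", "stableB", "AtoB", "BtoA")
  out <- do.call(rbind, lapply(states, function(s) {
    a <- sum(hit & switches$state == s)
    b <- sum(hit & switches$state != s)
    c <- sum(!hit & switches$state == s)
    d <- sum(!hit & switches$state != s)
    ft <- stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))
    data.frame(state = s, adj_state = a, adj_other = b, bg_state = c,
               bg_other = d, odds_ratio = unname(ft$estimate), p = ft$p.value)
  }))
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}
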