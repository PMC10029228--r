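# Synthetic multi-species data generator. An ancestral genome is laid out
# with gene-density-coupled A/B compartment structure; rearrangement events
# (inversion, translocation, fusion, fission) derive descendant genomes whose
# provenance, breakpoints, compartments and TADs are known exactly, so every
# downstream caller can be scored against planted truth.

#' Simulate an ancestral genome
#'
#' Chromosomes are tiled with alternating A/B compartment blocks; genes are
#' placed sequentially with shorter spacing inside A blocks than B blocks
#' (A compartments are gene-dense, which later orients compartment calls).
#' Gene lengths are fixed (expression contrasts, not length effects, are
#' under test downstream).
#'
#' @param n_chrom number of chromosomes (>= 1).
#' @param genes_per_chrom genes per chromosome (>= 2).
#' @param gene_spacing mean intergenic gap in bp.
#' @param bin_size compartment bin size in bp (block structure is drawn on
#'   this grid).
#' @param seed RNG seed; the construction is deterministic per seed.
#' @param gene_length fixed gene length in bp.
#' @param comp_block_bins range of compartment block lengths, in bins.
#' @param density_ratio B-compartment spacing multiplier (>1 means A is
#'   gene-dense).
#' @return a `sim_genome`: list with `species_id`, `chroms`
#'   (chrom, length), `genes` (gene_id, chrom, start, end, strand,
#'   ancestral_gene_id), `origin` segments, and the ancestral compartment
#'   block table as attribute `comp`.
#' @export
simulate_ancestor <- function(n_chrom, genes_per_chrom, gene_spacing = 10000,
                              bin_size = 50000, seed = NULL,
                              gene_length = 2000, comp_block_bins = c(6, 14),
                              density_ratio = 2.5, tad_bin_size = 5000,
                              tad_size_range = c(80000, 200000),
                              tad_gap_range = c(10000, 40000)) {
  if (n_chrom < 1 || genes_per_chrom < 2 || gene_spacing <= 0 || bin_size <= 0)
    stop("non-positive or undersized simulation parameters")
  with_seed(seed, {
    genes <- list(); comps <- list(); chroms <- list()
    sp_a <- gene_spacing * 2 / (1 + density_ratio)
    sp_b <- sp_a * density_ratio
    for (c in seq_len(n_chrom)) {
      chrom <- sprintf("chr%02d", c)
      # enough A/B blocks to cover the expected chromosome length
      need <- genes_per_chrom * (gene_length + gene_spacing) * 2 + 10 * bin_size
      lab <- character(0); lens <- integer(0); cur <- sample(c("A", "B"), 1)
      while (sum(lens) * bin_size < need) {
        lens <- c(lens, sample(comp_block_bins[1]:comp_block_bins[2], 1))
        lab <- c(lab, cur)
        cur <- if (cur == "A") "B" else "A"
      }
      bstart <- cumsum(c(0, lens[-length(lens)])) * bin_size
      bend <- cumsum(lens) * bin_size
      labfun <- function(pos) lab[findInterval(pos, bstart)]
      pos <- 0
      st <- en <- numeric(genes_per_chrom)
      for (g in seq_len(genes_per_chrom)) {
        base <- if (labfun(pos) == "A") sp_a else sp_b
        pos <- pos + base * stats::runif(1, 0.5, 1.5)
        st[g] <- round(pos)
        en[g] <- st[g] + gene_length
        pos <- en[g]
      }
      len <- en[genes_per_chrom] + round(gene_spacing)
      gid <- sprintf("%s_g%04d", chrom, seq_len(genes_per_chrom))
      genes[[c]] <- data.frame(
        gene_id = gid, chrom = chrom, start = st, end = en,
        strand = "+", ancestral_gene_id = gid,
        anc_chrom = chrom, anc_idx = seq_len(genes_per_chrom),
        anc_start = st, anc_end = en, orient = 1L,
        gap_prev = c(st[1], st[-1] - en[-genes_per_chrom]),
        stringsAsFactors = FALSE)
      chroms[[c]] <- data.frame(chrom = chrom, length = len)
      keep <- bstart < len
      comps[[c]] <- data.frame(chrom = chrom, start = bstart[keep],
                               end = pmin(bend[keep], len), label = lab[keep])
    }
    g <- structure(list(species_id = "ancestor",
                        chroms = do.call(rbind, chroms),
                        genes = do.call(rbind, genes),
                        origin = NULL),
                   class = "sim_genome")
    g$origin <- origin_segments(g)
    attr(g, "comp") <- do.call(rbind, comps)
    attr(g, "tads") <- make_tad_truth(g$chroms,
                                      data.frame(chrom = character(),
                                                 pos = numeric()),
                                      tad_bin_size, 0, tad_size_range,
                                      tad_gap_range)
    attr(g, "gene_spacing") <- gene_spacing
    attr(g, "gene_length") <- gene_length
    rownames(g$genes) <- NULL
    g
  })
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("sim_genome '%s': %d chromosomes, %d genes, %d origin segments\n",
              x$species_id, nrow(x$chroms), nrow(x$genes), nrow(x$origin)))
  invisible(x)
}

#' Rearrangement event constructors
#'
#' Events are expressed in 1-based gene-index coordinates on the genome they
#' are applied to; they are applied sequentially by
#' [apply_rearrangements()].
#'
#' @param chrom,chrom_a,chrom_b chromosome names.
#' @param start,end inclusive gene-index interval of the source segment.
#' @param dest_chrom destination chromosome (translocation; must differ from
#'   `chrom`).
#' @param dest_after destination insertion point: gene index after which the
#'   segment is inserted (0 = chromosome start).
#' @param invert whether a translocated segment is inserted flipped.
#' @param after gene index after which a fission splits the chromosome.
#' @param name,names new chromosome name(s) for fusion/fission.
#' @return a `rearrangement_event` list.
#' @export
ev_inversion <- function(chrom, start, end) {
  if (end < start) stop("empty inversion interval")
  structure(list(kind = "inversion", chrom = chrom, start = start, end = end),
            class = "rearrangement_event")
}

#' @rdname ev_inversion
#' @export
ev_translocation <- function(chrom, start, end, dest_chrom, dest_after,
                             invert = FALSE) {
  if (end < start) stop("empty translocation interval")
  if (identical(chrom, dest_chrom))
    stop("translocation source and destination must be distinct chromosomes")
  structure(list(kind = "translocation", chrom = chrom, start = start,
                 end = end, dest_chrom = dest_chrom, dest_after = dest_after,
                 invert = invert), class = "rearrangement_event")
}

#' @rdname ev_inversion
#' @export
ev_fusion <- function(chrom_a, chrom_b, name = NULL) {
  if (identical(chrom_a, chrom_b)) stop("fusion requires two chromosomes")
  structure(list(kind = "fusion", chrom_a = chrom_a, chrom_b = chrom_b,
                 name = name %||% paste0(chrom_a, "_", chrom_b)),
            class = "rearrangement_event")
}

#' @rdname ev_inversion
#' @export
ev_fission <- function(chrom, after, names = NULL) {
  structure(list(kind = "fission", chrom = chrom, after = after,
                 names = names %||% paste0(chrom, c("a", "b"))),
            class = "rearrangement_event")
}

#' Apply rearrangement events and derive ground truth
#'
#' Events are applied sequentially in gene-index coordinates. The derived
#' genome is re-laid out preserving each gene's ancestral intergenic gap
#' (junctions get the mean gene spacing), so local gene density — and with it
#' the compartment structure — travels with the DNA. Origin segments record
#' provenance exactly; planted breakpoints sit at every junction between
#' segments of discordant ancestry or orientation.
#'
#' Compartment truth is the ancestral A/B block structure mapped through the
#' origin segments; optionally, B bins within `switch_window` of a junction
#' are flipped to A (`switch_near_breaks`), emulating rearrangement-induced
#' B-to-A switches. TAD truth is the ancestral domain tiling mapped through
#' the origin segments: domains fully inside one origin segment travel with
#' the DNA, while domains straddling a junction are destroyed (their span
#' becomes inter-TAD interval) and recorded in `destroyed_tads` — so TAD
#' structure is conserved across species except where rearrangement broke a
#' domain. Genomes without an ancestral domain tiling fall back to an
#' independent per-species tiling with a fraction of edges snapped to
#' junctions (`tad_at_break_prob`).
#'
#' @param genome a `sim_genome`.
#' @param events list of `rearrangement_event`s (possibly empty).
#' @param seed RNG seed for the truth layout draws.
#' @param species_id id for the derived genome.
#' @param comp_bin_size compartment truth bin size (bp).
#' @param tad_bin_size grid to which TAD truth edges are snapped (bp).
#' @param switch_near_breaks probability that a B bin adjacent to a junction
#'   is flipped to A in the derived truth.
#' @param switch_window bp window around junctions for such flips.
#' @param tad_at_break_prob probability that a junction inside a drawn
#'   domain truncates it (placing a domain edge at the break).
#' @param tad_size_range,tad_gap_range domain and inter-domain interval
#'   sizes, bp.
#' @return list with elements `genome` (derived `sim_genome`) and `truth`
#'   (`sim_truth`: `breakpoints`, `compartments`, `tads`, `destroyed_tads`,
#'   `params`).
#' @export
apply_rearrangements <- function(genome, events, seed = NULL,
                                 species_id = "derived",
                                 comp_bin_size = 50000, tad_bin_size = 5000,
                                 switch_near_breaks = 0, switch_window = 10000,
                                 tad_at_break_prob = 0.7,
                                 tad_size_range = c(80000, 200000),
                                 tad_gap_range = c(10000, 40000)) {
  check_event_overlap(events)
  tabs <- split(genome$genes, genome$genes$chrom)
  tabs <- tabs[unique(genome$genes$chrom)]
  for (ev in events) tabs <- apply_event(tabs, ev)
  spacing <- attr(genome, "gene_spacing") %||% 10000
  derived <- layout_genome(tabs, species_id, spacing)
  attr(derived, "comp") <- attr(genome, "comp")
  attr(derived, "tads") <- attr(genome, "tads")
  attr(derived, "gene_spacing") <- spacing
  attr(derived, "gene_length") <- attr(genome, "gene_length")
  with_seed(seed, {
    bp <- derived_breakpoints(derived)
    comp <- map_compartments(derived, comp_bin_size)
    if (switch_near_breaks > 0 && nrow(bp)) {
      mid <- (comp$start + comp$end) / 2
      for (k in seq_len(nrow(bp))) {
        near <- comp$chrom == bp$chrom[k] &
          pmax(comp$start, bp$pos[k] - switch_window) <
            pmin(comp$end, bp$pos[k] + switch_window)
        flip <- near & comp$label == "B" &
          stats::runif(nrow(comp)) < switch_near_breaks
        comp$label[flip] <- "A"
      }
    }
    anc_tads <- attr(genome, "tads")
    if (!is.null(anc_tads)) {
      mt <- map_tads(derived, anc_tads, tad_bin_size)
      tads <- mt$tads
      destroyed <- mt$destroyed
    } else {
      tads <- make_tad_truth(derived$chroms, bp, tad_bin_size,
                             tad_at_break_prob, tad_size_range,
                             tad_gap_range)
      destroyed <- tads[0, ]
    }
    truth <- structure(list(
      breakpoints = bp, compartments = comp, tads = tads,
      destroyed_tads = destroyed,
      params = list(comp_bin_size = comp_bin_size,
                    tad_bin_size = tad_bin_size,
                    switch_near_breaks = switch_near_breaks,
                    switch_window = switch_window,
                    tad_at_break_prob = tad_at_break_prob)),
      class = "sim_truth")
    list(genome = derived, truth = truth)
  })
}

# Map ancestral TAD truth through origin segments. Domains fully contained
# in one segment's ancestral interval are transferred (orientation-aware,
# snapped to the bin grid); domains cut by a segment edge are destroyed in
# the derived species: the region loses its domain (becomes interval) and
# the full ancestral extent is recorded in `destroyed` — its genes are the
# ones whose insulated context the rearrangement broke.
map_tads <- function(genome, anc_tads, bin) {
  seg <- genome$origin
  out <- list(); destroyed <- list()
  snap <- function(x) round(x / bin) * bin
  for (k in seq_len(nrow(seg))) {
    s <- seg[k, ]
    scale <- (s$end - s$start) / max(s$anc_end - s$anc_start, 1)
    td <- anc_tads[anc_tads$chrom == s$anc_chrom, , drop = FALSE]
    inside <- td$start >= s$anc_start & td$end <= s$anc_end
    if (any(inside)) {
      ti <- td[inside, , drop = FALSE]
      if (s$orientation == "+") {
        st <- s$start + (ti$start - s$anc_start) * scale
        en <- s$start + (ti$end - s$anc_start) * scale
      } else {
        st <- s$start + (s$anc_end - ti$end) * scale
        en <- s$start + (s$anc_end - ti$start) * scale
      }
      out[[length(out) + 1]] <- data.frame(chrom = s$chrom,
                                           start = snap(st), end = snap(en))
    }
  }
  # domains cut by segment edges (split across >= 2 segments) are destroyed
  for (j in seq_len(nrow(anc_tads))) {
    td <- anc_tads[j, ]
    sg <- seg[seg$anc_chrom == td$chrom &
                seg$anc_start < td$end & seg$anc_end > td$start, , drop = FALSE]
    if (nrow(sg) < 2) next # intact within one segment (possibly relocated)
    pieces <- data.frame(start = pmax(td$start, sg$anc_start),
                         end = pmin(td$end, sg$anc_end))
    if (sum(pieces$end > pieces$start) < 2) next
    destroyed[[length(destroyed) + 1]] <- td[, c("chrom", "start", "end")]
  }
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric())
  tads <- if (length(out)) do.call(rbind, out) else empty
  tads <- tads[order(tads$chrom, tads$start), , drop = FALSE]
  rownames(tads) <- NULL
  dst <- if (length(destroyed)) unique(do.call(rbind, destroyed)) else empty
  rownames(dst) <- NULL
  list(tads = tads, destroyed = dst)
}

#' Snap rearrangement cut points to ancestral inter-TAD gaps
#'
#' For each interval endpoint of each event, nearby alternative gene-index
#' cuts (within `max_shift` genes) are examined and, with probability
#' `prob`, the cut is moved so that the junction midpoint falls in an
#' ancestral inter-TAD gap within `snap_tol` bp of a domain corner —
#' emulating the preferential occurrence of rearrangement breakpoints at
#' domain boundaries. Events keep their kind and approximate position;
#' fusions are untouched (chromosome ends are already domain-free).
#'
#' @param genome the ancestral `sim_genome` (with TAD truth attached).
#' @param events list of `rearrangement_event`s in this genome's gene-index
#'   coordinates.
#' @param prob per-endpoint snapping probability.
#' @param max_shift search radius in genes.
#' @param snap_tol maximum distance (bp) from a domain corner.
#' @param min_genes minimum genes an interval event must retain after
#'   snapping.
#' @param seed RNG seed.
#' @return the adjusted event list.
#' @export
snap_events_to_boundaries <- function(genome, events, prob = 0.8,
                                      max_shift = 15, snap_tol = 10000,
                                      min_genes = 15, seed = NULL) {
  tads <- attr(genome, "tads")
  if (is.null(tads)) return(events)
  with_seed(seed, {
    in_gap <- function(chrom, pos) {
      td <- tads[tads$chrom == chrom, ]
      !any(pos >= td$start & pos < td$end) &&
        any(abs(pos - c(td$start, td$end)) <= snap_tol)
    }
    cut_pos <- function(tab, i) { # junction bp of the cut between i and i+1
      if (i < 1 || i >= nrow(tab)) return(NA_real_)
      (tab$end[i] + tab$start[i + 1]) / 2
    }
    snap_cut <- function(chrom, i) {
      tab <- genome$genes[genome$genes$chrom == chrom, ]
      if (stats::runif(1) >= prob) return(i)
      for (delta in order(abs(seq(-max_shift, max_shift)))) {
        j <- i + seq(-max_shift, max_shift)[delta]
        pp <- cut_pos(tab, j)
        if (is.finite(pp) && in_gap(chrom, pp)) return(j)
      }
      i
    }
    lapply(events, function(ev) {
      if (ev$kind %in% c("inversion", "translocation")) {
        s <- snap_cut(ev$chrom, ev$start - 1) + 1
        e <- snap_cut(ev$chrom, ev$end)
        # the snapped interval must stay large enough to chain as a block
        if (e - s + 1 >= min_genes) { ev$start <- s; ev$end <- e }
      }
      if (ev$kind == "translocation") {
        d <- snap_cut(ev$dest_chrom, max(ev$dest_after, 1))
        if (d >= 1) ev$dest_after <- d
      } else if (ev$kind == "fission") {
        a <- snap_cut(ev$chrom, ev$after)
        if (a >= 1) ev$after <- a
      }
      ev
    })
  })
}

check_event_overlap <- function(events) {
  iv <- Filter(function(e) e$kind %in% c("inversion", "translocation"), events)
  if (length(iv) < 2) return(invisible(TRUE))
  for (a in seq_len(length(iv) - 1)) for (b in (a + 1):length(iv)) {
    if (identical(iv[[a]]$chrom, iv[[b]]$chrom) &&
        iv[[a]]$start <= iv[[b]]$end && iv[[b]]$start <= iv[[a]]$end)
      stop("overlapping event intervals on ", iv[[a]]$chrom)
  }
  invisible(TRUE)
}

apply_event <- function(tabs, ev) {
  get <- function(ch) {
    if (is.null(tabs[[ch]])) stop("unknown chromosome ", ch)
    tabs[[ch]]
  }
  if (ev$kind == "inversion") {
    t <- get(ev$chrom)
    if (ev$start < 1 || ev$end > nrow(t)) stop("inversion interval out of bounds")
    seg <- t[ev$end:ev$start, ]
    seg$orient <- -seg$orient
    seg$strand <- ifelse(seg$strand == "+", "-", "+")
    tabs[[ev$chrom]] <- rbind(
      if (ev$start > 1) t[1:(ev$start - 1), ] else t[0, ], seg,
      if (ev$end < nrow(t)) t[(ev$end + 1):nrow(t), ] else t[0, ])
  } else if (ev$kind == "translocation") {
    t <- get(ev$chrom); d <- get(ev$dest_chrom)
    if (ev$start < 1 || ev$end > nrow(t)) stop("translocation interval out of bounds")
    if (ev$dest_after < 0 || ev$dest_after > nrow(d)) stop("destination out of bounds")
    seg <- t[ev$start:ev$end, ]
    if (isTRUE(ev$invert)) {
      seg <- seg[rev(seq_len(nrow(seg))), ]
      seg$orient <- -seg$orient
      seg$strand <- ifelse(seg$strand == "+", "-", "+")
    }
    tabs[[ev$chrom]] <- t[-(ev$start:ev$end), ]
    tabs[[ev$dest_chrom]] <- rbind(
      if (ev$dest_after > 0) d[1:ev$dest_after, ] else d[0, ], seg,
      if (ev$dest_after < nrow(d)) d[(ev$dest_after + 1):nrow(d), ] else d[0, ])
  } else if (ev$kind == "fusion") {
    a <- get(ev$chrom_a); b <- get(ev$chrom_b)
    tabs[[ev$chrom_a]] <- NULL
    tabs[[ev$chrom_b]] <- NULL
    tabs[[ev$name]] <- rbind(a, b)
  } else if (ev$kind == "fission") {
    t <- get(ev$chrom)
    if (ev$after < 1 || ev$after >= nrow(t)) stop("fission point out of bounds")
    tabs[[ev$chrom]] <- NULL
    tabs[[ev$names[1]]] <- t[1:ev$after, ]
    tabs[[ev$names[2]]] <- t[(ev$after + 1):nrow(t), ]
  } else stop("unknown event kind: ", ev$kind)
  tabs
}

# Re-lay genes along each derived chromosome using ancestral gaps; compute
# origin segments from maximal runs of ancestrally adjacent genes.
layout_genome <- function(tabs, species_id, spacing) {
  genes <- list(); chroms <- list()
  for (ch in names(tabs)) {
    t <- tabs[[ch]]
    if (!nrow(t)) next
    n <- nrow(t)
    prev_adj <- c(FALSE, t$anc_chrom[-1] == t$anc_chrom[-n] &
                    t$orient[-1] == t$orient[-n] &
                    (t$anc_idx[-1] - t$anc_idx[-n]) == t$orient[-n])
    glen <- t$end - t$start
    gap <- ifelse(prev_adj, pmax(t$gap_prev, 1), round(spacing))
    gap[1] <- pmax(t$gap_prev[1], 1)
    st <- cumsum(gap + c(0, glen[-n]))
    t$chrom <- ch
    t$start <- st
    t$end <- st + glen
    genes[[ch]] <- t
    chroms[[ch]] <- data.frame(chrom = ch,
                               length = t$end[n] + round(spacing))
  }
  g <- structure(list(species_id = species_id,
                      chroms = do.call(rbind, chroms),
                      genes = do.call(rbind, genes), origin = NULL),
                 class = "sim_genome")
  rownames(g$genes) <- rownames(g$chroms) <- NULL
  g$origin <- origin_segments(g)
  g
}

# Maximal runs of ancestrally adjacent, consistently oriented genes ->
# bp segments tiling each chromosome; ancestral extent from member genes.
origin_segments <- function(genome) {
  out <- list()
  for (ch in genome$chroms$chrom) {
    t <- genome$genes[genome$genes$chrom == ch, ]
    n <- nrow(t)
    if (!n) next
    brk <- which(!(t$anc_chrom[-1] == t$anc_chrom[-n] &
                     t$orient[-1] == t$orient[-n] &
                     (t$anc_idx[-1] - t$anc_idx[-n]) == t$orient[-n]))
    starts_i <- c(1, brk + 1)
    ends_i <- c(brk, n)
    junc <- if (length(brk))
      round((t$end[brk] + t$start[brk + 1]) / 2) else numeric(0)
    seg_start <- c(0, junc)
    seg_end <- c(junc, genome$chroms$length[genome$chroms$chrom == ch])
    out[[ch]] <- data.frame(
      chrom = ch, start = seg_start, end = seg_end,
      anc_chrom = t$anc_chrom[starts_i],
      anc_start = pmin(t$anc_start[starts_i], t$anc_start[ends_i]),
      anc_end = pmax(t$anc_end[starts_i], t$anc_end[ends_i]),
      orientation = ifelse(t$orient[starts_i] > 0, "+", "-"))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

derived_breakpoints <- function(genome) {
  seg <- genome$origin
  out <- list()
  for (ch in unique(seg$chrom)) {
    s <- seg[seg$chrom == ch, ]
    if (nrow(s) > 1)
      out[[ch]] <- data.frame(chrom = ch, pos = s$start[-1])
  }
  if (!length(out)) return(data.frame(chrom = character(), pos = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# ancestral compartment labels mapped through origin segments onto the
# derived genome, binned at comp_bin_size
map_compartments <- function(genome, comp_bin_size) {
  comp <- attr(genome, "comp")
  bins <- genome_bins(genome$chroms, comp_bin_size)
  seg <- genome$origin
  mid <- (bins$start + bins$end) / 2
  lab <- rep(NA_character_, nrow(bins))
  for (k in seq_len(nrow(seg))) {
    sel <- bins$chrom == seg$chrom[k] & mid >= seg$start[k] & mid < seg$end[k]
    if (!any(sel)) next
    frac <- (mid[sel] - seg$start[k]) / max(seg$end[k] - seg$start[k], 1)
    anc_pos <- if (seg$orientation[k] == "+")
      seg$anc_start[k] + frac * (seg$anc_end[k] - seg$anc_start[k])
    else seg$anc_end[k] - frac * (seg$anc_end[k] - seg$anc_start[k])
    cc <- comp[comp$chrom == seg$anc_chrom[k], ]
    idx <- findInterval(anc_pos, cc$start)
    lab[sel] <- cc$label[pmax(pmin(idx, nrow(cc)), 1)]
  }
  data.frame(chrom = bins$chrom, start = bins$start, end = bins$end,
             label = lab)
}

# Tile each chromosome with TAD truth; junctions may truncate domains so a
# domain edge coincides with the break.
make_tad_truth <- function(chroms, breakpoints, bin, at_break_prob,
                           size_range, gap_range, min_tad = 25000) {
  out <- list()
  snap <- function(x) round(x / bin) * bin
  for (i in seq_len(nrow(chroms))) {
    ch <- chroms$chrom[i]
    len <- chroms$length[i]
    js <- sort(snap(breakpoints$pos[breakpoints$chrom == ch]))
    pos <- snap(stats::runif(1, gap_range[1], gap_range[2]))
    st <- en <- numeric(0)
    while (pos + min_tad <= len) {
      size <- snap(stats::runif(1, size_range[1], size_range[2]))
      jin <- js[js > pos + min_tad & js < pos + size]
      if (length(jin) && stats::runif(1) < at_break_prob) size <- jin[1] - pos
      if (pos + size > len) break
      st <- c(st, pos); en <- c(en, pos + size)
      pos <- pos + size + snap(stats::runif(1, gap_range[1], gap_range[2]))
    }
    if (length(st))
      out[[ch]] <- data.frame(chrom = ch, start = st, end = en)
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-bin gene density
#'
#' @param genome a `sim_genome`.
#' @param bins bin table as from [genome_bins()].
#' @return integer vector of gene-midpoint counts per bin (bin table order).
#' @export
gene_density <- function(genome, bins) {
  res <- max(bins$end - bins$start)
  mids <- (genome$genes$start + genome$genes$end) / 2
  ids <- bin_of(bins, genome$genes$chrom, mids, res)
  tabulate(ids + 1L, nbins = nrow(bins))
}

#' Simulate a Hi-C contact matrix from planted truth
#'
#' Expected cis count for bins i, j at distance d bins is
#' `depth * max(d,1)^(-alpha) * P_ij * T_ij * b_i * b_j`, where `P` is the
#' compartment plaid factor (`plaid_contrast` when both bins share a truth
#' label), `T` the TAD factor (`tad_enrichment` when both bins lie in one
#' true domain), and `b` multiplicative bin biases built from synthetic
#' covariates (effective length, GC, mappability) times log-normal noise.
#' Counts are Poisson; the matrix is exactly symmetric. In
#' `mode = "ancestral_preserving"`, cis pairs whose bins descend from
#' different ancestral chromosomes (within a fused/mosaic chromosome) are
#' dampened by `dampening`; in `mode = "mixed"` they are not.
#'
#' @param genome a `sim_genome`.
#' @param truth matching `sim_truth` (compartments/TADs binned consistently).
#' @param bin_size bin size in bp.
#' @param depth expected count at one-bin distance (before modifiers).
#' @param alpha power-law distance-decay exponent (> 0).
#' @param plaid_contrast,tad_enrichment,bias_sd forward-model magnitudes.
#' @param mode `"mixed"` or `"ancestral_preserving"`.
#' @param dampening cross-origin multiplier (< 1) for ancestral_preserving.
#' @param trans_depth expected trans count per bin pair (0 disables trans).
#' @param covariate_bias include covariate-driven biases (otherwise biases
#'   are pure log-normal noise of sd `bias_sd`).
#' @param seed RNG seed.
#' @return a raw `contact_matrix` with covariates attached.
#' @export
simulate_contacts <- function(genome, truth, bin_size, depth = 500,
                              alpha = 1, plaid_contrast = 1.6,
                              tad_enrichment = 2, bias_sd = 0.25,
                              mode = c("mixed", "ancestral_preserving"),
                              dampening = 0.3, trans_depth = 0,
                              covariate_bias = TRUE, seed = NULL) {
  if (alpha <= 0) stop("alpha must be > 0")
  mode <- match.arg(mode)
  with_seed(seed, {
    bins <- genome_bins(genome$chroms, bin_size)
    n <- nrow(bins)
    covariates <- data.frame(bin_id = bins$bin_id,
                             len = stats::runif(n, 0.6, 1),
                             gc = stats::runif(n, 0.3, 0.7),
                             map = stats::runif(n, 0.7, 1))
    b <- exp(stats::rnorm(n, 0, bias_sd))
    if (covariate_bias)
      b <- b * covariates$len * covariates$map * (covariates$gc / 0.5)
    b <- b / mean(b)
    mid <- (bins$start + bins$end) / 2
    # per-bin truth lookups
    comp <- truth$compartments
    lab <- comp$label[match(paste(bins$chrom, bins$start %/% comp_res(comp)),
                            paste(comp$chrom, comp$start %/% comp_res(comp)))]
    if (all(is.na(lab)) && nrow(comp)) { # resolutions differ: match by midpoint
      lab <- rep(NA_character_, n)
      for (k in seq_len(nrow(comp))) {
        sel <- bins$chrom == comp$chrom[k] & mid >= comp$start[k] & mid < comp$end[k]
        lab[sel] <- comp$label[k]
      }
    }
    tid <- rep(NA_integer_, n)
    if (nrow(truth$tads)) for (k in seq_len(nrow(truth$tads))) {
      sel <- bins$chrom == truth$tads$chrom[k] &
        mid >= truth$tads$start[k] & mid < truth$tads$end[k]
      tid[sel] <- k
    }
    anc <- rep(NA_character_, n)
    for (k in seq_len(nrow(genome$origin))) {
      s <- genome$origin[k, ]
      sel <- bins$chrom == s$chrom & mid >= s$start & mid < s$end
      anc[sel] <- s$anc_chrom
    }
    px <- list()
    for (ch in genome$chroms$chrom) {
      ids <- bins$bin_id[bins$chrom == ch]
      m <- length(ids)
      iu <- which(upper.tri(matrix(0, m, m), diag = TRUE), arr.ind = TRUE)
      i <- ids[iu[, 1]] + 1L
      j <- ids[iu[, 2]] + 1L
      d <- pmax(iu[, 2] - iu[, 1], 1)
      mu <- depth * d^(-alpha) * b[i] * b[j]
      same_lab <- !is.na(lab[i]) & !is.na(lab[j]) & lab[i] == lab[j]
      mu[same_lab] <- mu[same_lab] * plaid_contrast
      same_tad <- !is.na(tid[i]) & !is.na(tid[j]) & tid[i] == tid[j]
      mu[same_tad] <- mu[same_tad] * tad_enrichment
      if (mode == "ancestral_preserving") {
        cross <- !is.na(anc[i]) & !is.na(anc[j]) & anc[i] != anc[j]
        mu[cross] <- mu[cross] * dampening
      }
      cnt <- stats::rpois(length(mu), mu)
      keep <- cnt > 0
      px[[ch]] <- data.frame(bin1 = i[keep] - 1L, bin2 = j[keep] - 1L,
                             count = cnt[keep])
    }
    if (trans_depth > 0 && nrow(genome$chroms) > 1) {
      cidx <- match(bins$chrom, genome$chroms$chrom)
      allp <- which(outer(cidx, cidx, "<"), arr.ind = TRUE)
      mu <- trans_depth * b[allp[, 1]] * b[allp[, 2]]
      cnt <- stats::rpois(length(mu), mu)
      keep <- cnt > 0
      px[["trans"]] <- data.frame(bin1 = allp[keep, 1] - 1L,
                                  bin2 = allp[keep, 2] - 1L,
                                  count = cnt[keep])
    }
    contact_matrix(bins, do.call(rbind, px), bin_size,
                   covariates = covariates)
  })
}

comp_res <- function(comp) {
  if (!nrow(comp)) return(1L)
  max(comp$end - comp$start)
}

#' Simulate replicate expression tables for an ortholog set
#'
#' True log10 RPKM is drawn per ortholog; the second species' value is offset
#' by `log10(effect)` with random sign, so the expected absolute divergence
#' |e1 - e2| increases with the planted effect factor. Replicate read counts
#' are Poisson at the implied RPKM.
#'
#' @param orthologs data.frame with columns `gene1`, `gene2`.
#' @param base_log10_mean,base_sd distribution of true log10 RPKM.
#' @param effect_map named numeric vector of multiplicative divergence
#'   factors keyed by `gene1` (missing genes get 1; factors must be > 0).
#' @param replicates replicate count (>= 1).
#' @param gene_length fixed transcript length bp.
#' @param lib_size library size used to convert RPKM to expected counts.
#' @param seed RNG seed.
#' @return list of two expression data.frames (`gene_id`, `length`,
#'   `rep1..repN`).
#' @export
simulate_expression <- function(orthologs, base_log10_mean = 1.2,
                                base_sd = 0.6, effect_map = NULL,
                                replicates = 3, gene_length = 2000,
                                lib_size = 2e7, seed = NULL) {
  if (replicates < 1) stop("replicates must be >= 1")
  eff <- rep(1, nrow(orthologs))
  if (!is.null(effect_map)) {
    if (any(effect_map < 0)) stop("negative effect factors rejected")
    hit <- match(orthologs$gene1, names(effect_map))
    eff[!is.na(hit)] <- effect_map[hit[!is.na(hit)]]
  }
  with_seed(seed, {
    n <- nrow(orthologs)
    t1 <- stats::rnorm(n, base_log10_mean, base_sd)
    s <- sample(c(-1, 1), n, replace = TRUE)
    t2 <- t1 + s * log10(pmax(eff, 1e-12))
    draw <- function(t, ids) {
      mu <- 10^t * gene_length * lib_size / 1e9
      reps <- vapply(seq_len(replicates),
                     function(r) stats::rpois(n, mu), numeric(n))
      df <- data.frame(gene_id = ids, length = gene_length)
      colnames_reps <- paste0("rep", seq_len(replicates))
      for (r in seq_len(replicates)) df[[colnames_reps[r]]] <-
          if (n == 1) reps[r] else reps[, r]
      df
    }
    list(species1 = draw(t1, orthologs$gene1),
         species2 = draw(t2, orthologs$gene2))
  })
}

#' Simulate binned epigenetic signal tracks with planted anchor contrasts
#'
#' Each mark is a flat background plus Gaussian bumps of height `contrast`
#' centered on its anchors, plus Gaussian noise. Fraction-kind marks
#' (methylation) are clipped to [0, 1] with a warning if the contrast pushes
#' values outside.
#'
#' @param genome a `sim_genome`.
#' @param mark_specs list of specs: `list(name, kind, background, anchors
#'   (data.frame chrom,pos), contrast, width = 5000, noise_sd = 0.02)`.
#' @param bin_size track bin size in bp.
#' @param seed RNG seed.
#' @return named list of signal tracks (data.frame `chrom`, `start`, `end`,
#'   `value`; attributes `mark` and `kind`).
#' @export
simulate_tracks <- function(genome, mark_specs, bin_size = 1000, seed = NULL) {
  with_seed(seed, {
    bins <- genome_bins(genome$chroms, bin_size)
    mid <- (bins$start + bins$end) / 2
    out <- list()
    for (sp in mark_specs) {
      width <- sp$width %||% 5000
      noise <- sp$noise_sd %||% 0.02
      v <- rep(sp$background, nrow(bins))
      a <- sp$anchors
      if (!is.null(a) && nrow(a)) for (k in seq_len(nrow(a))) {
        sel <- bins$chrom == a$chrom[k]
        v[sel] <- v[sel] +
          sp$contrast * exp(-((mid[sel] - a$pos[k])^2) / (2 * width^2))
      }
      v <- v + stats::rnorm(length(v), 0, noise)
      if (identical(sp$kind, "fraction")) {
        if (any(v < -0.02 | v > 1.02))
          warning(sprintf("mark %s: contrast leaves [0,1]; clipping", sp$name))
        v <- pmin(pmax(v, 0), 1)
      } else if (!identical(sp$kind, "ratio")) {
        v <- pmax(v, 0)
      }
      tr <- data.frame(chrom = bins$chrom, start = bins$start,
                       end = bins$end, value = v)
      attr(tr, "mark") <- sp$name
      attr(tr, "kind") <- sp$kind %||% "density"
      out[[sp$name]] <- tr
    }
    out
  })
}

#' Simulate syntenic-gene switch calls with a planted break-adjacent effect
#'
#' Generates gene positions and break points on a single-chromosome genome
#' sized like one species-pair comparison (thousands of syntenic genes,
#' ~1000 breaks) and draws each gene's compartment-switch state from a
#' background multinomial, with the B-to-A probability multiplied by
#' `btoa_factor` (renormalized) for genes within `window` of a break. Used
#' to calibrate and power-test [break_adjacent_switch_enrichment()].
#'
#' @param n_genes,n_breaks counts.
#' @param chrom_len chromosome length bp.
#' @param window adjacency window bp.
#' @param base_probs named background probabilities over
#'   stableA/stableB/AtoB/BtoA.
#' @param btoa_factor planted fold-change of the B-to-A rate near breaks.
#' @param seed RNG seed.
#' @return list with `switches` (gene table with `state`) and `breaks`
#'   (data.frame `chrom`, `start`, `end`).
#' @export
sim_switch_calls <- function(n_genes = 20000, n_breaks = 1000,
                             chrom_len = 6e8, window = 10000,
                             base_probs = c(stableA = 0.44, stableB = 0.44,
                                            AtoB = 0.06, BtoA = 0.06),
                             btoa_factor = 1, seed = NULL) {
  with_seed(seed, {
    pos <- sort(round(stats::runif(n_genes, 0, chrom_len - 2000)))
    bpos <- sort(round(stats::runif(n_breaks, 0, chrom_len)))
    near <- findInterval(pos + 1000, bpos)
    adj <- (near >= 1 & (pos + 1000) - bpos[pmax(near, 1)] <= window) |
      (near < n_breaks & bpos[pmin(near + 1, n_breaks)] - (pos + 1000) <= window)
    pr_bg <- base_probs / sum(base_probs)
    pr_ad <- base_probs
    pr_ad["BtoA"] <- pr_ad["BtoA"] * btoa_factor
    pr_ad <- pr_ad / sum(pr_ad)
    states <- character(n_genes)
    nm <- names(base_probs)
    states[!adj] <- sample(nm, sum(!adj), replace = TRUE, prob = pr_bg)
    if (any(adj))
      states[adj] <- sample(nm, sum(adj), replace = TRUE, prob = pr_ad)
    sw <- data.frame(gene1 = sprintf("g%05d", seq_len(n_genes)),
                     gene2 = sprintf("h%05d", seq_len(n_genes)),
                     chrom = "chr01", start = pos, end = pos + 2000,
                     state = states)
    breaks <- data.frame(chrom = "chr01", start = bpos, end = bpos + 1)
    list(switches = sw, breaks = breaks)
  })
}

#' Write a simulated genome to plain-text files
#'
#' Emits a BED6 gene file, a chrom.sizes file and a BED of origin segments
#' with ancestry columns.
#'
#' @param genome a `sim_genome`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_sim_genome <- function(genome, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pre <- file.path(dir, genome$species_id)
  g <- genome$genes
  bed <- data.frame(g$chrom, g$start, g$end, g$gene_id, 0, g$strand)
  utils::write.table(bed, paste0(pre, ".genes.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(genome$chroms, paste0(pre, ".chrom.sizes"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(genome$origin, paste0(pre, ".origins.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(paste0(pre, c(".genes.bed", ".chrom.sizes", ".origins.bed")))
}

#' Ortholog pairs between two derived genomes
#'
#' Pairs genes by shared ancestral gene id.
#'
#' @param g1,g2 `sim_genome`s descending from a common ancestor.
#' @return data.frame `gene1`, `gene2`, `ancestral_gene_id`.
#' @export
ortholog_pairs <- function(g1, g2) {
  m <- match(g1$genes$ancestral_gene_id, g2$genes$ancestral_gene_id)
  keep <- !is.na(m)
  data.frame(gene1 = g1$genes$gene_id[keep],
             gene2 = g2$genes$gene_id[m[keep]],
             ancestral_gene_id = g1$genes$ancestral_gene_id[keep])
}
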