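# End-to-end orchestration: simulate (or load) a multi-species system, run
# normalization, compartments, TADs, synteny, co-localization, switches,
# conservation and expression stages, and emit a machine-readable report.

#' Default pipeline configuration
#'
#' A three-species demo system (~8 Mb haploid genomes) derived from a common
#' ancestor: species A carries one inversion, species B an inversion plus an
#' inter-chromosomal translocation, species C a whole-chromosome fusion plus
#' an inversion (its contacts are simulated in ancestral-preserving mode so
#' the fused chromosome retains stronger same-origin interactions). All
#' thresholds carry their standard values: 50-kb compartments, 5-kb TADs,
#' min 10 syntenic genes, max gap 30, conservation ratio 0.5 over >4
#' syntenic genes, +-10 kb adjacency windows.
#'
#' @param seed master seed; per-stage seeds are derived from it.
#' @return a named config list; see the package vignette for the full
#'   parameter glossary.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    ancestor = list(n_chrom = 5, genes_per_chrom = 240, gene_spacing = 10000,
                    bin_size = 50000),
    resolutions = list(matrix = 5000, compartments = 50000, tads = 5000),
    contacts = list(depth = 500, alpha = 1, plaid_contrast = 1.6,
                    tad_enrichment = 2, bias_sd = 0.25, dampening = 0.3,
                    trans_depth = 0.02),
    thresholds = list(min_genes = 10, max_gap = 30, overlap = 0.5,
                      min_syntenic = 4, tad_size_threshold = 65000,
                      min_depth = 0.1, intra_flank_ratio = 1.2,
                      min_tad_size = 25000),
    windows = list(switch = 10000, meta = 20000, insulation = 50000),
    permutations = 200,
    block_perm = 200,
    switch_near_breaks = 0.9,
    expression = list(replicates = 3, base_log10_mean = 1.2, base_sd = 0.6,
                      effect = 2, lib_size = 2e7)
  )
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config a config list.
#' @return [read_run_config()] returns the config list with defaults filled
#'   in for unspecified entries.
#' @export
read_run_config <- function(path) {
  usr <- yaml::read_yaml(path)
  cfg <- default_config(seed = usr$seed %||% 1)
  deep_merge <- function(base, over) {
    for (nm in names(over))
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
        deep_merge(base[[nm]], over[[nm]]) else over[[nm]]
    base
  }
  validate_config(deep_merge(cfg, usr))
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Validate a pipeline configuration
#'
#' @param config a config list as from [default_config()].
#' @return the config, invisibly; stops on an invalid setting.
#' @export
validate_config <- function(config) {
  r <- config$resolutions
  if (r$compartments %% r$matrix != 0 || r$tads %% r$matrix != 0)
    stop("analysis resolutions must be multiples of the matrix resolution")
  th <- unlist(config$thresholds)
  if (any(th <= 0)) stop("all thresholds must be positive")
  if (config$permutations < 100) stop("permutations must be >= 100")
  invisible(config)
}

# Demo rearrangement sets. Event intervals are laid out so that no event of
# a derived species overlaps (or closely abuts) an event of the reference
# species spA on the same chromosome — every junction is then flanked by
# chainable blocks in both scored comparisons (spA-spB, spA-spC).
demo_events <- function(config) {
  gpc <- config$ancestor$genes_per_chrom
  at <- function(f) round(gpc * f)
  list(
    spA = list(ev_inversion("chr01", at(0.66), at(0.66) + 29),
               ev_inversion("chr02", at(0.40), at(0.40) + 24),
               ev_inversion("chr03", at(0.24), at(0.24) + 29),
               ev_inversion("chr04", at(0.50), at(0.50) + 24),
               ev_inversion("chr05", at(0.28), at(0.28) + 29),
               ev_inversion("chr05", at(0.68), at(0.68) + 24)),
    spB = list(ev_inversion("chr01", at(0.18), at(0.18) + 34),
               ev_inversion("chr02", at(0.58), at(0.58) + 29),
               ev_inversion("chr04", at(0.70), at(0.70) + 29),
               ev_inversion("chr05", at(0.08), at(0.08) + 24),
               ev_translocation("chr02", at(0.10), at(0.10) + 24, "chr03",
                                at(0.52)),
               ev_translocation("chr05", at(0.48), at(0.48) + 24, "chr03",
                                at(0.79))),
    spC = list(ev_inversion("chr02", at(0.62), at(0.62) + 24),
               ev_inversion("chr03", at(0.60), at(0.60) + 29),
               ev_inversion("chr04", at(0.25), at(0.25) + 24),
               ev_translocation("chr01", at(0.08), at(0.08) + 24, "chr03",
                                at(0.425)),
               ev_translocation("chr05", at(0.50), at(0.50) + 24, "chr04",
                                at(0.83)),
               ev_fusion("chr01", "chr02", name = "chr01_02"))
  )
}

#' Run the comparative pipeline end to end
#'
#' Stages: simulate the multi-species system; ICE-balance matrices at the
#' compartment and TAD resolutions (plus Poisson-covariate normalization for
#' the origin-decay analysis); call compartments and TADs per species; chain
#' synteny and derive breaks per species pair (both directions); test
#' break/boundary co-localization with all three shuffle modes plus Fisher;
#' classify compartment switches and their break adjacency; classify
#' conserved TADs and their break proximity; simulate expression with the
#' planted near-break divergence effect and run the divergence contrasts;
#' run the origin-stratified cis-decay analysis on the fused chromosome.
#' Identical (config, seed) gives an identical report.
#'
#' @param config configuration list (see [default_config()]).
#' @param outdir optional directory for intermediate files (TSV/BED/JSON);
#'   nothing is written when NULL.
#' @return a `run_report` list: per-stage outputs, counts, simulation truth
#'   and the config hash.
#' @export
run_pipeline <- function(config = default_config(), outdir = NULL) {
  validate_config(config)
  seed <- config$seed
  t0 <- Sys.time()
  log_stage <- function(...) message(sprintf("[%5.1fs] ", as.numeric(
    difftime(Sys.time(), t0, units = "secs"))), sprintf(...))

  log_stage("simulate: ancestor + 3 derived species")
  anc <- simulate_ancestor(config$ancestor$n_chrom,
                           config$ancestor$genes_per_chrom,
                           config$ancestor$gene_spacing,
                           config$ancestor$bin_size,
                           seed = derive_seed(seed, "ancestor"))
  evs <- demo_events(config)
  species <- list()
  for (sp in names(evs)) {
    ev <- snap_events_to_boundaries(anc, evs[[sp]],
                                    prob = config$tad_at_break_prob %||% 0.7,
                                    max_shift = 10,
                                    seed = derive_seed(seed, paste0("snap_", sp)))
    species[[sp]] <- apply_rearrangements(
      anc, ev, seed = derive_seed(seed, paste0("derive_", sp)),
      species_id = sp, comp_bin_size = config$resolutions$compartments,
      tad_bin_size = config$resolutions$tads,
      switch_near_breaks = if (sp == "spA") 0 else config$switch_near_breaks,
      switch_window = config$resolutions$compartments)
  }

  log_stage("simulate + balance contact matrices")
  cc <- config$contacts
  mats <- list()
  for (sp in names(species)) {
    g <- species[[sp]]$genome
    tr <- species[[sp]]$truth
    for (res_name in c("compartments", "tads")) {
      # ancestral in-cis preservation is a fine-scale phenomenon: it shapes
      # the TAD-resolution map of the fused species, while compartment-scale
      # maps are simulated without origin dampening
      mode <- if (sp == "spC" && res_name == "tads")
        "ancestral_preserving" else "mixed"
      res <- config$resolutions[[res_name]]
      m <- simulate_contacts(g, tr, res, depth = cc$depth, alpha = cc$alpha,
                             plaid_contrast = cc$plaid_contrast,
                             tad_enrichment = cc$tad_enrichment,
                             bias_sd = cc$bias_sd, mode = mode,
                             dampening = cc$dampening,
                             trans_depth = if (res_name == "compartments")
                               cc$trans_depth else 0,
                             seed = derive_seed(seed, paste(sp, res_name)))
      mats[[sp]][[res_name]] <- ice_balance(m)
    }
  }

  log_stage("compartments at %d bp", config$resolutions$compartments)
  profiles <- list(); fractions <- list()
  for (sp in names(species)) {
    m <- mats[[sp]]$compartments
    gd <- gene_density(species[[sp]]$genome, m$bins)
    profiles[[sp]] <- call_compartments(m, gd)
    fractions[[sp]] <- compartment_fractions(profiles[[sp]])
  }

  log_stage("TADs at %d bp", config$resolutions$tads)
  tadsets <- list()
  for (sp in names(species)) {
    tadsets[[sp]] <- call_tads(mats[[sp]]$tads,
                               window = config$windows$insulation,
                               min_depth = config$thresholds$min_depth,
                               min_size = config$thresholds$min_tad_size,
                               intra_flank_ratio = config$thresholds$intra_flank_ratio)
    tadsets[[sp]] <- group_by_size(tadsets[[sp]],
                                   config$thresholds$tad_size_threshold)
  }

  log_stage("synteny: chain blocks + derive breaks per pair")
  pairs <- list(c("spA", "spB"), c("spA", "spC"))
  synteny <- list()
  for (pr in pairs) {
    key <- paste(pr, collapse = "_")
    g1 <- species[[pr[1]]]$genome; g2 <- species[[pr[2]]]$genome
    orth <- ortholog_pairs(g1, g2)
    hits <- data.frame(gene1 = orth$gene1, gene2 = orth$gene2,
                       score = 100, evalue = 1e-30, retained = TRUE)
    blocks <- chain_collinear(g1$genes, g2$genes, hits,
                              max_gap = config$thresholds$max_gap,
                              min_genes = config$thresholds$min_genes,
                              n_perm = config$block_perm,
                              seed = derive_seed(seed, paste0("blocks_", key)))
    breaks1 <- derive_breaks(blocks, config$thresholds$min_genes,
                             config$thresholds$max_gap, g2$genes)
    hits_r <- data.frame(gene1 = orth$gene2, gene2 = orth$gene1,
                         score = 100, evalue = 1e-30, retained = TRUE)
    blocks_r <- chain_collinear(g2$genes, g1$genes, hits_r,
                                max_gap = config$thresholds$max_gap,
                                min_genes = config$thresholds$min_genes,
                                n_perm = config$block_perm,
                                seed = derive_seed(seed, paste0("blocksr_", key)))
    breaks2 <- derive_breaks(blocks_r, config$thresholds$min_genes,
                             config$thresholds$max_gap, g1$genes)
    sweep <- threshold_sweep(blocks, genes2 = g2$genes)
    synteny[[key]] <- list(orthologs = orth, blocks = blocks,
                           breaks1 = breaks1, breaks2 = breaks2,
                           sweep = sweep)
  }

  log_stage("co-localization of breaks with TAD structure")
  coloc <- list()
  for (key in names(synteny)) {
    sp1 <- strsplit(key, "_")[[1]][1]
    brk <- synteny[[key]]$breaks1
    if (!nrow(brk)) next
    a <- data.frame(chrom = brk$chrom1, start = brk$start1, end = brk$end1)
    sizes <- species[[sp1]]$genome$chroms
    part <- tad_partition(tadsets[[sp1]])
    coloc[[key]] <- list(
      boundaries = lapply(c("shuffle_A", "shuffle_B", "shuffle_both"),
        function(md) empirical_enrichment(
          a, part$boundaries, sizes,
          n_perm = config$permutations, mode = md,
          seed = derive_seed(seed, paste0("coloc_", key, md)))),
      bodies = empirical_enrichment(
        a, part$bodies, sizes, n_perm = config$permutations,
        seed = derive_seed(seed, paste0("colocb_", key))),
      intervals = empirical_enrichment(
        a, part$intervals, sizes, n_perm = config$permutations,
        seed = derive_seed(seed, paste0("coloci_", key))))
  }

  log_stage("compartment switches + break adjacency")
  switches <- list()
  for (key in names(synteny)) {
    pr <- strsplit(key, "_")[[1]]
    sw <- classify_switches(profiles[[pr[1]]], profiles[[pr[2]]],
                            synteny[[key]]$orthologs,
                            species[[pr[1]]]$genome$genes,
                            species[[pr[2]]]$genome$genes)
    brk <- synteny[[key]]$breaks1
    enr <- if (nrow(brk))
      break_adjacent_switch_enrichment(
        sw, data.frame(chrom = brk$chrom1, start = brk$start1,
                       end = brk$end1), config$windows$switch) else NULL
    switches[[key]] <- list(calls = sw, counts = attr(sw, "counts"),
                            enrichment = enr)
  }

  log_stage("conserved TADs + proximity")
  conservation <- list()
  for (key in names(synteny)) {
    pr <- strsplit(key, "_")[[1]]
    cons <- classify_conserved(tadsets[[pr[1]]], tadsets[[pr[2]]],
                               synteny[[key]]$orthologs,
                               species[[pr[1]]]$genome$genes,
                               species[[pr[2]]]$genome$genes,
                               min_syntenic = config$thresholds$min_syntenic,
                               overlap_threshold = config$thresholds$overlap)
    brk <- synteny[[key]]$breaks1
    prox <- if (nrow(brk)) {
      td1 <- tadsets[[pr[1]]]
      pt <- proximity_to_breaks(td1,
        data.frame(chrom = brk$chrom1, start = brk$start1, end = brk$end1),
        window = 10 * config$resolutions$tads)
      pt$status <- cons$status[match(paste(pt$chrom, pt$start),
                                     paste(cons$chrom, cons$start))]
      pt
    } else NULL
    conservation[[key]] <- list(table = cons, proximity = prox)
  }

  log_stage("expression divergence contrasts")
  expr <- list()
  for (key in names(synteny)) {
    pr <- strsplit(key, "_")[[1]]
    orth <- synteny[[key]]$orthologs
    g1 <- species[[pr[1]]]$genome$genes
    brk <- synteny[[key]]$breaks1
    gg <- g1[match(orth$gene1, g1$gene_id), ]
    near <- rep(FALSE, nrow(orth))
    if (nrow(brk)) {
      bw <- data.frame(chrom = brk$chrom1,
                       start = pmax(0, brk$start1 - config$windows$switch),
                       end = brk$end1 + config$windows$switch)
      near <- overlap_hits(gg, bw)
    }
    # genes whose ancestral TAD was destroyed by rearrangement in either
    # species also carry the planted divergence effect (domain disruption
    # perturbs regulation beyond the immediate break window), while genes
    # inside a surviving domain are insulated from the near-break effect —
    # domain stabilization dominates mere break proximity
    dst <- rbind(species[[pr[1]]]$truth$destroyed_tads,
                 species[[pr[2]]]$truth$destroyed_tads)
    in_dst <- rep(FALSE, nrow(orth))
    if (nrow(dst)) {
      anc_genes <- anc$genes[match(orth$ancestral_gene_id,
                                   anc$genes$gene_id), ]
      in_dst <- overlap_hits(anc_genes, unique(dst))
    }
    protected <- overlap_hits(gg, species[[pr[1]]]$truth$tads)
    eff <- stats::setNames(ifelse((near & !protected) | in_dst,
                                  config$expression$effect, 1), orth$gene1)
    tabs <- simulate_expression(orth,
      base_log10_mean = config$expression$base_log10_mean,
      base_sd = config$expression$base_sd, effect_map = eff,
      replicates = config$expression$replicates,
      lib_size = config$expression$lib_size,
      seed = derive_seed(seed, paste0("expr_", key)))
    div <- expression_divergence(tabs$species1, tabs$species2, orth)
    div$near_break <- near[match(div$gene1, orth$gene1)]
    cons <- conservation[[key]]$table
    div$tad_status <- tad_status_of_genes(div$gene1, g1, cons)
    prox <- conservation[[key]]$proximity
    div$tad_proximity <- if (!is.null(prox))
      domain_field_of_genes(div$gene1, g1, prox, "proximity") else NA
    tests <- list(
      near_vs_distal = group_compare(div$divergence,
        factor(ifelse(div$near_break, "near", "distal"),
               levels = c("near", "distal")), alternative = "greater"))
    cs <- div$tad_status
    if (length(unique(stats::na.omit(cs))) == 2)
      tests$conserved_vs_rearranged <- group_compare(
        div$divergence[!is.na(cs)], cs[!is.na(cs)], alternative = "less")
    px <- div$tad_proximity[!is.na(div$tad_proximity) &
                              !is.na(cs) & cs == "conserved"]
    dv <- div$divergence[!is.na(div$tad_proximity) &
                           !is.na(cs) & cs == "conserved"]
    if (length(unique(px)) == 2)
      tests$proximal_vs_distal_conserved <- group_compare(dv, px)
    expr[[key]] <- list(divergence = div, tests = tests)
  }

  log_stage("origin-stratified cis decay on the fused chromosome")
  mC <- hicnorm_lite(mats$spC$tads)
  decay <- cis_decay_by_origin(mC, species$spC$genome$origin,
                               chrom = "chr01_02")

  report <- list(
    config = config, config_hash = fnv1a_hash(config),
    species = lapply(species, function(s) s$genome),
    truth = lapply(species, function(s) s$truth),
    matrices = lapply(mats, function(m)
      lapply(m, function(x) c(bins = nrow(x$bins), cv = attr(x, "ice_cv")))),
    profiles = profiles, fractions = fractions, tadsets = tadsets,
    synteny = synteny, coloc = coloc, switches = switches,
    conservation = conservation, expression = expr, origin_decay = decay,
    counts = list(
      blocks = vapply(synteny, function(s) nrow(s$blocks), numeric(1)),
      breaks = vapply(synteny, function(s) nrow(s$breaks1), numeric(1)),
      tads = vapply(tadsets, function(t) nrow(t$domains), numeric(1)),
      conserved = vapply(conservation, function(cn)
        sum(cn$table$status == "conserved"), numeric(1)))
  )
  class(report) <- "run_report"
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

# gene table rows overlapping any window (vectorized helper)
overlap_hits <- function(genes, windows) {
  hit <- logical(nrow(genes))
  for (ch in unique(genes$chrom)) {
    sel <- which(genes$chrom == ch)
    w <- windows[windows$chrom == ch, , drop = FALSE]
    if (!nrow(w)) next
    for (k in seq_len(nrow(w)))
      hit[sel] <- hit[sel] | (genes$start[sel] < w$end[k] &
                                genes$end[sel] > w$start[k])
  }
  hit
}

# conserved/rearranged status of each gene's containing assessed domain
tad_status_of_genes <- function(gene_ids, genes, cons_table) {
  ct <- cons_table[cons_table$status != "unassessed", , drop = FALSE]
  domain_field_of_genes(gene_ids, genes, ct, "status")
}

# value of a per-domain column for each gene's containing domain (NA outside)
domain_field_of_genes <- function(gene_ids, genes, domains, field) {
  g <- genes[match(gene_ids, genes$gene_id), ]
  mid <- (g$start + g$end) / 2
  out <- rep(NA_character_, length(gene_ids))
  if (!is.null(domains) && nrow(domains)) for (k in seq_len(nrow(domains))) {
    sel <- g$chrom == domains$chrom[k] & mid >= domains$start[k] &
      mid < domains$end[k]
    out[sel] <- domains[[field]][k]
  }
  out
}

write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (sp in names(report$species))
    write_sim_genome(report$species[[sp]], file.path(outdir, "genomes"))
  for (key in names(report$synteny)) {
    brk <- report$synteny[[key]]$breaks1
    utils::write.table(brk, file.path(outdir, paste0("breaks_", key, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (sp in names(report$tadsets)) {
    td <- report$tadsets[[sp]]
    utils::write.table(td$domains,
                       file.path(outdir, paste0("tads_", sp, ".bed")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  summary <- list(config_hash = report$config_hash, counts = report$counts,
                  fractions = report$fractions)
  jsonlite::write_json(summary, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report", x$config_hash, "\n")
  cat(" breaks:", paste(names(x$counts$breaks), x$counts$breaks,
                        collapse = ", "), "\n")
  cat(" TADs:  ", paste(names(x$counts$tads), x$counts$tads,
                        collapse = ", "), "\n")
  invisible(x)
}
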