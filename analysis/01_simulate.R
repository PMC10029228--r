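#!/usr/bin/env Rscript
# Simulate the three-species study system: an ancestral genome with
# gene-density-coupled A/B compartment blocks and an ancestral TAD tiling,
# and three descendants carrying inversions, translocations and (in spC) a
# whole-chromosome fusion. Writes genomes, origin segments and truth tables
# under results/sim/.

suppressPackageStartupMessages(library(synteny3d))
seed <- as.integer(Sys.getenv("ANALYSIS_SEED", "1"))
outdir <- "results/sim"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- default_config(seed = seed)
anc <- simulate_ancestor(cfg$ancestor$n_chrom, cfg$ancestor$genes_per_chrom,
                         cfg$ancestor$gene_spacing, cfg$ancestor$bin_size,
                         seed = synteny3d:::derive_seed(seed, "ancestor"))
write_sim_genome(anc, outdir)
message("ancestor: ", nrow(anc$chroms), " chromosomes, ",
        nrow(anc$genes), " genes, ",
        round(sum(anc$chroms$length) / 1e6, 1), " Mb")

evs <- synteny3d:::demo_events(cfg)
for (sp in names(evs)) {
  ev <- snap_events_to_boundaries(anc, evs[[sp]], prob = 0.7, max_shift = 10,
                                  seed = synteny3d:::derive_seed(seed, paste0("snap_", sp)))
  d <- apply_rearrangements(anc, ev,
    seed = synteny3d:::derive_seed(seed, paste0("derive_", sp)),
    species_id = sp, switch_near_breaks = if (sp == "spA") 0 else 0.9,
    switch_window = 50000)
  write_sim_genome(d$genome, outdir)
  utils::write.table(d$truth$breakpoints,
                     file.path(outdir, paste0(sp, ".breakpoints.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(d$truth$tads,
                     file.path(outdir, paste0(sp, ".tad_truth.bed")),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  message(sp, ": ", nrow(d$truth$breakpoints), " planted junctions, ",
          nrow(d$truth$tads), " truth domains (",
          nrow(d$truth$destroyed_tads), " ancestral domains destroyed)")
}
message("done; outputs in ", outdir)
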