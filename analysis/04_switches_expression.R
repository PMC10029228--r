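#!/usr/bin/env Rscript
# Compartment switches around synteny breaks and the orthologous
# expression-divergence contrasts: near-break vs distal genes, conserved vs
# rearranged TADs, and proximal vs distal conserved TADs.

suppressPackageStartupMessages(library(synteny3d))
report <- readRDS("results/report.rds")

for (key in names(report$switches)) {
  message("== ", key)
  print(attr(report$switches[[key]]$calls, "counts"))
  enr <- report$switches[[key]]$enrichment
  utils::write.table(enr, paste0("results/switch_enrichment_", key, ".tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  print(enr[, c("state", "odds_ratio", "p")], digits = 3)
}

for (key in names(report$expression)) {
  ex <- report$expression[[key]]
  utils::write.table(ex$divergence,
                     paste0("results/divergence_", key, ".tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tt <- ex$tests
  message(sprintf(
    "%s: near-break > distal p=%.2g; conserved < rearranged p=%.2g; proximal~distal conserved p=%.2g",
    key, tt$near_vs_distal$p,
    if (!is.null(tt$conserved_vs_rearranged))
      tt$conserved_vs_rearranged$p else NA,
    if (!is.null(tt$proximal_vs_distal_conserved))
      tt$proximal_vs_distal_conserved$p else NA))
}
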