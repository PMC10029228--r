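#!/usr/bin/env Rscript
# Origin-stratified in-cis decay on the fused chromosome of spC: mean
# normalized contact per log2 distance stratum for same- vs different-
# ancestral-origin bin pairs, with stratified rank-sum p-values.

suppressPackageStartupMessages(library(synteny3d))
report <- readRDS("results/report.rds")

dec <- report$origin_decay
utils::write.table(dec, "results/origin_decay.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
print(dec[, c("dist_bin", "mean_same", "mean_diff", "n_same", "n_diff",
              "p")], digits = 3)
pop <- dec$n_same >= 50 & dec$n_diff >= 50
message("same-origin exceeds different-origin in ",
        sum(dec$mean_same[pop] > dec$mean_diff[pop]), "/", sum(pop),
        " populated distance strata")
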