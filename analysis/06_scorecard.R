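#!/usr/bin/env Rscript
# Score every stage of the run against the simulation's planted truth and
# write the scorecard.

suppressPackageStartupMessages(library(synteny3d))
report <- readRDS("results/report.rds")

sc <- validate_report(report)
utils::write.table(sc, "results/scorecard.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
print(sc, digits = 3)
graded <- sc[!is.na(sc$pass), ]
message(sum(graded$pass), "/", nrow(graded), " graded checks pass")
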