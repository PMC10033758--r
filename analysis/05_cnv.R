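#!/usr/bin/env Rscript
# Windowed copy-number analysis of the hypoxia track against its
# matched normoxia control: 50 kb windows, mappability >= 0.85,
# breakpoint threshold 0.8, ploidy selected over {2,3,4}, and CNV /
# CNG / CNL window counts.

suppressPackageStartupMessages(library(hypoxigen))

case <- read.delim("results/data/coverage_case.tsv")
control <- read.delim("results/data/coverage_control.tsv")

res <- call_cnv(case, control, breakpoint_threshold = 0.8,
                min_mappability = 0.85, ploidy = "auto")
write.table(res$segments, "results/cnv_segments.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

s <- res$summary
cat(sprintf("selected ploidy: %d\n", s$selected_ploidy))
cat(sprintf(
  "windows: %d retained; CNV %d (gain %d, loss %d) at 50 kb per window\n",
  s$retained_windows, s$cnv_windows, s$cng_windows, s$cnl_windows))
cat("called segments:\n")
print(res$segments[res$segments$status != "neutral", ], digits = 3)
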