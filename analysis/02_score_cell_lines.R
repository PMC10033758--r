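#!/usr/bin/env Rscript
# Hypoxia scoring of the simulated cell-line panel: replicate-averaged
# signature fold changes, geometric-mean score per line, relative score
# and HH/HL stratification, plus the median-dichotomized cohort score.

suppressPackageStartupMessages(library(hypoxigen))

fc <- read.delim("results/data/signature_fc.tsv")
scores <- score_cell_lines(fc)
write.table(scores, "results/cell_line_scores.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("cell-line hypoxia scores (HH = relative score > 0):\n")
print(scores, digits = 4)
cat(sprintf("-> %d HH lines, %d HL lines\n",
            sum(scores$group == "HH"), sum(scores$group == "HL")))

cohort_expr <- read.delim("results/data/cohort_expression.tsv",
                          row.names = 1)
calls <- score_cohort(cohort_expr)
write.table(calls, "results/cohort_calls.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("cohort: %d patients stratified HH, %d HL (score > 0 rule)\n",
            sum(calls$group == "HH"), sum(calls$group == "HL")))
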