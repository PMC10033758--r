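#!/usr/bin/env Rscript
# Transcriptome response to chronic hypoxia: moderated differential
# expression at the signed-FC +/- 2 / FDR 0.05 thresholds, and
# splicing-index analysis with event selection at |SI| > 2 /
# exon FDR < 0.05.

suppressPackageStartupMessages(library(hypoxigen))

seed <- as.integer(Sys.getenv("ANALYSIS_SEED", "1"))
mat <- as.matrix(read.delim("results/data/expression_matrix.tsv",
                            row.names = 1, check.names = FALSE))
samples <- read.delim("results/data/expression_samples.tsv")

de <- moderated_de_test(mat, samples$condition)
write.table(de, "results/de_results.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
up <- sum(de$significant & de$signed_fc > 0)
down <- sum(de$significant & de$signed_fc < 0)
cat(sprintf("DE: %d significant transcript clusters (%d up, %d down) of %d\n",
            sum(de$significant), up, down, nrow(de)))

# splicing signals are regenerated from the shared seed (generators are
# pure functions of the config)
spl <- simulate_splicing_signals(sim_config(seed = seed))
res <- splicing_results(spl$psr, spl$gene, spl$psr_map,
                        spl$samples$condition, spl$events)
write.table(res, "results/splicing_results.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("splicing: %d significant transcripts; predicted events: %s\n",
            nrow(res),
            paste(names(sort(table(res$event), decreasing = TRUE)),
                  sort(table(res$event), decreasing = TRUE),
                  sep = "=", collapse = ", ")))
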