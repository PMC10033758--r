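#!/usr/bin/env Rscript
# Generate every input of the chronic-hypoxia analysis at study scale:
# signature fold changes for 12 cell lines, paired normoxia/hypoxia
# expression and splicing signals, 24 matched MAF pairs (2 groups x 3
# cell lines x 4 pairs), 50 kb coverage tracks with planted CNV
# segments, and a 50-patient cohort. All downstream drivers reuse the
# same seed, so the generated and re-derived objects agree.

suppressPackageStartupMessages(library(hypoxigen))

seed <- as.integer(Sys.getenv("ANALYSIS_SEED", "1"))
cfg <- sim_config(seed = seed)
out <- file.path("results", "data")
dir.create(file.path(out, "maf"), recursive = TRUE, showWarnings = FALSE)

tsv <- function(df, name, rn = FALSE)
  write.table(df, file.path(out, name), sep = "\t", quote = FALSE,
              row.names = rn, col.names = TRUE)

sig <- simulate_signature_fc(cfg)
tsv(sig$fc, "signature_fc.tsv")

expr <- simulate_expression_matrix(cfg)
tsv(as.data.frame(expr$matrix), "expression_matrix.tsv", rn = TRUE)
tsv(expr$samples, "expression_samples.tsv")

mafs <- simulate_paired_mafs(cfg)
for (bc in names(mafs$mafs))
  write_maf(mafs$mafs[[bc]], file.path(out, "maf", paste0(bc, ".maf")))
tsv(mafs$manifest, "maf_manifest.tsv")
tsv(mafs$pairs, "maf_pairs.tsv")

cov <- simulate_coverage(cfg)
tsv(cov$case, "coverage_case.tsv")
tsv(cov$control, "coverage_control.tsv")

cohort <- simulate_cohort(cfg)
tsv(cohort$expression, "cohort_expression.tsv", rn = TRUE)
tsv(cohort$alterations, "cohort_alterations.tsv", rn = TRUE)

cat(sprintf(paste0(
  "simulated with seed %d: %d cell lines x %d signature genes, ",
  "%d transcripts (%d vs %d arrays), %d MAF pairs, %d coverage windows, ",
  "%d patients\n"),
  seed, cfg$n_cell_lines, cfg$n_signature_genes, cfg$n_transcripts,
  cfg$n_samples_per_condition, cfg$n_samples_per_condition,
  nrow(mafs$pairs), cfg$n_windows, cfg$n_patients))
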