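#!/usr/bin/env Rscript
# Mutational landscape after 20 passages in hypoxia: read the paired
# MAFs back from disk, normalize each hypoxia sample against its
# matched normoxia control, and report TMB, variant-class and SNV-class
# spectra, transition/transversion percentages and top mutated genes,
# with the HH-vs-HL group comparison.

suppressPackageStartupMessages(library(hypoxigen))

pairs <- read.delim("results/data/maf_pairs.tsv")
mafs <- lapply(c(pairs$normoxia, pairs$hypoxia), function(bc)
  read_maf(file.path("results", "data", "maf", paste0(bc, ".maf"))))
names(mafs) <- c(pairs$normoxia, pairs$hypoxia)

land <- summarize_landscape(mafs, pairs, exome_size_mb = 57.7)
write.table(land$per_pair, "results/landscape_pairs.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(land$cell_line, "results/landscape_cell_lines.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(land$group, "results/landscape_groups.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("per-group TMB (mutations/Mb over a 57.7 Mb footprint):\n")
print(land$group, digits = 4)

g <- split(land$per_pair$tmb, land$per_pair$group)
tt <- t_test_unpaired(g$HH, g$HL, labels = c("HH", "HL"))
cat(sprintf("HH vs HL TMB: %.3f vs %.3f mut/Mb, t = %.2f, p = %.3g\n",
            tt$mean[1], tt$mean[2], tt$t_statistic, tt$p_value))

for (grp in names(land$group_spectra)) {
  sp <- land$group_spectra[[grp]]
  cat(sprintf("%s top variant classes: %s | transitions %.1f%%\n", grp,
              paste(names(sp$class_counts)[1:3],
                    sp$class_counts[1:3], sep = "=", collapse = ", "),
              sp$transition_pct))
}

top <- top_mutated_genes(land$private, 10L)
write.table(top, "results/top_genes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("top mutated genes:", paste(top$gene, collapse = ", "), "\n")
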