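# End-to-end orchestration on a simulation scenario: scoring and
# stratification, differential expression and splicing, paired variant
# subtraction with landscape summaries, windowed CNV calling, cohort
# concordance, and the HH-vs-HL group comparisons, written as TSV tables
# plus one machine-readable summary JSON.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run the full analysis pipeline on a simulation scenario
#'
#' Generates every input from `cfg`, executes all analysis stages and
#' writes their outputs under `out_dir`:
#' cell-line scores (`cell_line_scores.tsv`), cohort calls
#' (`cohort_calls.tsv`), DE results (`de_results.tsv`), splicing results
#' (`splicing_results.tsv`), per-pair landscape (`landscape_pairs.tsv`),
#' top genes (`top_genes.tsv`), CNV segments (`cnv_segments.tsv`) and a
#' single `summary.json` with every reported quantity (group TMB means,
#' confidence intervals and p-value, spectra, CNV counts, DEG counts,
#' concordance). The run is a pure function of `cfg`: the same config
#' yields byte-identical summary JSON.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   file output.
#' @return The summary list, invisibly written to `summary.json`.
#' @export
run_pipeline <- function(cfg, out_dir = NULL) {
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  # -- hypoxia scoring of cell lines -------------------------------------
  sig <- simulate_signature_fc(cfg)
  scores <- score_cell_lines(sig$fc)

  # -- differential expression -------------------------------------------
  expr <- simulate_expression_matrix(cfg)
  de <- moderated_de_test(expr$matrix, expr$samples$condition)
  n_sig_de <- sum(de$significant)

  # -- splicing -----------------------------------------------------------
  spl <- simulate_splicing_signals(cfg)
  spl_res <- splicing_results(spl$psr, spl$gene, spl$psr_map,
                              spl$samples$condition, spl$events)

  # -- mutational landscape ----------------------------------------------
  sim_maf <- simulate_paired_mafs(cfg)
  landscape <- summarize_landscape(sim_maf$mafs, sim_maf$pairs,
                                   cfg$exome_size_mb)
  top_genes <- top_mutated_genes(landscape$private, 10L)

  groups <- names(cfg$hypoxia_rate_per_mb)
  tmb_by_group <- split(landscape$per_pair$tmb, landscape$per_pair$group)
  tmb_test <- t_test_unpaired(tmb_by_group[[groups[1]]],
                              tmb_by_group[[groups[2]]],
                              labels = groups)

  # -- copy number --------------------------------------------------------
  cov <- simulate_coverage(cfg)
  cnv <- call_cnv(cov$case, cov$control)

  # -- cohort stratification and concordance ------------------------------
  cohort <- simulate_cohort(cfg)
  calls <- score_cohort(cohort$expression)
  conc <- alteration_concordance(cohort$alterations, calls)

  summary <- list(
    seed = cfg$seed,
    parameters = list(
      exome_size_mb = cfg$exome_size_mb,
      window_size_bp = cfg$window_size_bp,
      breakpoint_threshold = 0.8,
      min_mappability = 0.85,
      hypoxia_rate_per_mb = as.list(cfg$hypoxia_rate_per_mb)
    ),
    cell_line_scores = scores,
    group_tmb = list(
      groups = groups,
      mean = tmb_test$mean,
      ci95 = apply(tmb_test$ci95, 1, identity, simplify = FALSE),
      p_value = tmb_test$p_value
    ),
    landscape_groups = landscape$group,
    class_spectrum = lapply(landscape$group_spectra, function(s)
      as.list(s$class_counts)),
    snv_spectrum = lapply(landscape$group_spectra, function(s)
      as.list(s$snv_class_counts)),
    transition_pct = lapply(landscape$group_spectra, `[[`,
                            "transition_pct"),
    top_genes = top_genes,
    cnv = cnv$summary,
    n_significant_de = n_sig_de,
    n_significant_splicing = nrow(spl_res),
    cohort = list(
      n_HH = sum(calls$group == "HH"),
      n_HL = sum(calls$group == "HL"),
      concordant_count = conc$concordant_count,
      concordance_total = conc$total
    )
  )

  if (!is.null(out_dir)) {
    write_tsv(scores, file.path(out_dir, "cell_line_scores.tsv"))
    write_tsv(calls, file.path(out_dir, "cohort_calls.tsv"))
    write_tsv(de, file.path(out_dir, "de_results.tsv"))
    write_tsv(spl_res, file.path(out_dir, "splicing_results.tsv"))
    write_tsv(landscape$per_pair, file.path(out_dir, "landscape_pairs.tsv"))
    write_tsv(top_genes, file.path(out_dir, "top_genes.tsv"))
    write_tsv(cnv$segments, file.path(out_dir, "cnv_segments.tsv"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(summary)
}
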