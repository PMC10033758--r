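test_that("config validation rejects invalid parameters", {
  expect_error(sim_config(group_effect = 0), "group_effect")
  expect_error(sim_config(group_effect = -2), "group_effect")
  expect_error(sim_config(de_effect = 0.5), "de_effect")
  expect_error(sim_config(depth_mean = 0), "depth_mean")
  expect_error(sim_config(alteration_enrichment = 0),
               "alteration_enrichment")
  expect_error(sim_config(class_mixture = c(Bogus_Class = 1)), "Bogus")
  expect_error(sim_config(class_mixture = c(Missense_Mutation = 0.5,
                                            Silent = 0.4)), "sum to 1")
  expect_error(sim_config(cnv_segments = list(c(10, 50, 1), c(40, 80, 3))),
               "non-overlapping")
  expect_error(sim_config(cnv_segments = list(c(10, 5000, 1))),
               "within")
  expect_error(sim_config(true_ploidy = 5), "ploidy")
  expect_error(sim_config(transition_bias = 1.2), "transition_bias")
})

test_that("every generator is deterministic under its config", {
  cfg <- small_cfg(seed = 11L)
  for (gen in list(simulate_signature_fc, simulate_expression_matrix,
                   simulate_splicing_signals, simulate_paired_mafs,
                   simulate_coverage, simulate_cohort)) {
    expect_identical(gen(cfg), gen(cfg))
  }
  # a different seed changes the draw
  expect_false(identical(simulate_signature_fc(cfg)$fc,
                         simulate_signature_fc(small_cfg(seed = 12L))$fc))
})

test_that("signature fold changes separate groups only when planted", {
  # no planted effect: the two latent groups are indistinguishable
  # (two-sample t on per-line mean log FCs, the independent unit,
  # non-significant in >= 90% of seeds)
  null_p <- vapply(1:100, function(s) {
    sim <- simulate_signature_fc(sim_config(seed = s, group_effect = 1))
    line_mean <- tapply(log(sim$fc$fold_change), sim$fc$cell_line, mean)
    sens <- sim$truth$sensitive[match(names(line_mean),
                                      sim$truth$cell_line)]
    stats::t.test(line_mean[sens], line_mean[!sens])$p.value
  }, numeric(1))
  expect_gte(mean(null_p > 0.05), 0.90)

  # 4-fold separation: score ranking puts every sensitive line on top
  perfect <- vapply(1:100, function(s) {
    sim <- simulate_signature_fc(sim_config(seed = s, group_effect = 4))
    sc <- score_cell_lines(sim$fc)
    sens <- sim$truth$cell_line[sim$truth$sensitive]
    all(sc$cell_line[seq_along(sens)] %in% sens)
  }, logical(1))
  expect_gte(mean(perfect), 0.95)

  expect_true(all(simulate_signature_fc(small_cfg())$fc$fold_change > 0))
})

test_that("expression generator plants DE truth as configured", {
  cfg0 <- small_cfg(de_fraction = 0)
  expect_identical(nrow(simulate_expression_matrix(cfg0)$truth), 0L)

  cfg <- small_cfg(seed = 5L)
  sim <- simulate_expression_matrix(cfg)
  expect_identical(dim(sim$matrix),
                   c(cfg$n_transcripts, 2L * cfg$n_samples_per_condition))
  expect_true(all(sim$matrix > 0))
  expect_equal(nrow(sim$truth), round(cfg$de_fraction * cfg$n_transcripts))
  # planted transcripts shift in the recorded direction
  hyp <- sim$samples$condition == "hypoxia"
  for (i in seq_len(min(5L, nrow(sim$truth)))) {
    row <- sim$matrix[sim$truth$transcript[i], ]
    lfc <- log2(mean(row[hyp]) / mean(row[!hyp]))
    expect_identical(sign(lfc), as.numeric(sim$truth$direction[i]))
  }
})

test_that("splicing generator plants cassette exons with top-scored labels", {
  cfg <- small_cfg(seed = 3L)
  sim <- simulate_splicing_signals(cfg)
  expect_identical(nrow(sim$psr), 3L * cfg$n_transcripts)
  expect_gt(nrow(sim$truth), 0L)
  # the planted PSR is shifted ~4-fold against its gene in hypoxia
  hyp <- sim$samples$condition == "hypoxia"
  tc <- sim$truth$transcript[1]
  norm_sig <- sim$psr[sim$truth$psr_id[1], ] / sim$gene[tc, ]
  expect_gt(mean(norm_sig[hyp]) / mean(norm_sig[!hyp]), 3)
  # true event scores highest for every planted transcript
  by_tc <- split(sim$events, sim$events$transcript)
  expect_true(all(vapply(by_tc, function(ev)
    ev$event[which.max(ev$score)] == "cassette exon", logical(1))))

  expect_identical(nrow(simulate_splicing_signals(
    small_cfg(splice_fraction = 0))$truth), 0L)
})

test_that("paired MAF generator honors sharing, rates and truth counts", {
  cfg <- sim_config(seed = 2L)
  sim <- simulate_paired_mafs(cfg)
  expect_identical(nrow(sim$pairs), 24L)  # 2 groups x 3 lines x 4 pairs
  for (i in sample.int(nrow(sim$pairs), 4L)) {
    hyp <- sim$mafs[[sim$pairs$hypoxia[i]]]
    norm <- sim$mafs[[sim$pairs$normoxia[i]]]
    expect_identical(nrow(norm), cfg$background_shared_variants)
    priv <- subtract_paired(hyp, norm)
    expect_identical(nrow(priv),
                     sim$truth$k_private[sim$truth$hypoxia ==
                                           sim$pairs$hypoxia[i]])
    expect_identical(nrow(hyp), nrow(norm) + nrow(priv))
  }

  # zero hypoxia rate: subtraction empty, TMB 0 for every pair
  sim0 <- simulate_paired_mafs(
    sim_config(seed = 2L, hypoxia_rate_per_mb = c(HH = 0, HL = 0)))
  land0 <- summarize_landscape(sim0$mafs, sim0$pairs)
  expect_true(all(land0$per_pair$tmb == 0))

  # frameshift-insertion-weighted mixture tops the class spectrum
  land <- summarize_landscape(sim$mafs, sim$pairs, cfg$exome_size_mb)
  for (g in names(land$group_spectra))
    expect_identical(names(land$group_spectra[[g]]$class_counts)[1],
                     "Frame_Shift_Ins")
})

test_that("coverage generator writes valid tracks and truth", {
  cfg <- small_cfg(seed = 9L)
  sim <- simulate_coverage(cfg)
  expect_identical(nrow(sim$case), cfg$n_windows)
  expect_true(all(sim$case$end - sim$case$start == cfg$window_size_bp))
  expect_true(all(sim$control$mappability == 1))
  expect_identical(sim$truth$copy_number, 1L)
  # planted loss halves the expected case depth
  loss_win <- (sim$truth$start_window + 1L):sim$truth$end_window
  expect_lt(mean(sim$case$depth[loss_win]),
            0.7 * mean(sim$control$depth[loss_win]))

  low <- simulate_coverage(small_cfg(low_mappability_fraction = 0.1))
  expect_equal(sum(low$case$mappability < 0.85),
               round(0.1 * cfg$n_windows))
})

test_that("cohort generator couples expression and alterations to the factor", {
  cfg <- sim_config(seed = 4L)
  sim <- simulate_cohort(cfg)
  expect_identical(dim(sim$expression),
                   c(cfg$n_patients, cfg$n_signature_genes))
  # expression tracks the latent factor
  expect_gt(stats::cor(log2(sim$expression[[1]]), sim$truth$factor), 0.7)
  # alterations enriched in factor-high patients
  expect_gt(mean(as.matrix(sim$alterations)[sim$truth$high, ]),
            mean(as.matrix(sim$alterations)[!sim$truth$high, ]))

  # null enrichment: concordance count behaves as a binomial null
  conc <- vapply(1:100, function(s) {
    co <- simulate_cohort(sim_config(seed = s, alteration_enrichment = 1))
    calls <- score_cohort(co$expression)
    alteration_concordance(co$alterations, calls)$concordant_count
  }, numeric(1))
  expect_gt(mean(conc), 3.5)
  expect_lt(mean(conc), 6.5)

  # stratification yields two non-empty groups in nearly all seeds
  both <- vapply(1:40, function(s) {
    calls <- score_cohort(simulate_cohort(sim_config(seed = s))$expression)
    all(c("HH", "HL") %in% calls$group)
  }, logical(1))
  expect_gte(mean(both), 0.95)
})
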