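test_that("MAF files round-trip through write and read", {
  sim <- simulate_paired_mafs(sim_config(seed = 1L))
  maf <- sim$mafs[[sim$pairs$hypoxia[1]]]
  path <- withr::local_tempfile(fileext = ".maf")
  write_maf(maf, path)
  back <- read_maf(path)
  expect_equal(back, maf, ignore_attr = TRUE)

  # extra columns survive read but are dropped on write with a warning
  maf$extra_note <- "x"
  expect_warning(write_maf(maf, path), "extra_note")

  # empty body with a valid header is a valid empty MAF
  write_maf(maf[0, seq_len(9)], path)
  expect_identical(nrow(read_maf(path)), 0L)
})

test_that("malformed MAFs are rejected with informative errors", {
  sim <- simulate_paired_mafs(sim_config(seed = 1L))
  maf <- sim$mafs[[sim$pairs$normoxia[1]]]
  path <- withr::local_tempfile(fileext = ".maf")

  write_maf(maf, path)
  txt <- readLines(path)
  expect_error(read_maf(textConnection(sub("\tChromosome", "", txt[1]))))

  bad <- maf
  bad$Tumor_Seq_Allele2[bad$Variant_Type == "SNP"][1] <-
    bad$Reference_Allele[bad$Variant_Type == "SNP"][1]
  write_maf(bad, path)
  expect_error(read_maf(path), "line")
  expect_error(write_maf(maf[, -2], path), "Chromosome")
})

test_that("paired subtraction equals the brute-force oracle exactly", {
  # forced cases
  sim <- simulate_paired_mafs(sim_config(seed = 3L))
  norm <- sim$mafs[[sim$pairs$normoxia[1]]]
  expect_identical(nrow(subtract_paired(norm, norm)), 0L)

  v <- norm[7, ]
  v$Start_Position <- v$Start_Position + 1L
  v$End_Position <- v$Start_Position
  hyp <- rbind(norm, v)
  got <- subtract_paired(hyp, norm)
  expect_identical(got$Start_Position, v$Start_Position)

  # randomized oracle equivalence
  set.seed(17)
  for (i in 1:20) {
    pr <- random_maf_pair()
    got <- subtract_paired(pr$hypoxia, pr$normoxia)
    want <- subtract_oracle(pr$hypoxia, pr$normoxia)
    rownames(want) <- NULL
    expect_identical(got, want)
    # idempotence and cardinality bookkeeping
    expect_identical(subtract_paired(got, pr$normoxia), got)
    expect_identical(nrow(got) + (nrow(pr$hypoxia) - nrow(got)),
                     nrow(pr$hypoxia))
  }

  # duplicates collapse with a warning before subtraction
  dup <- rbind(norm, norm[1, ])
  expect_warning(out <- subtract_paired(dup, norm[0, ]), "duplicate")
  expect_identical(nrow(out), nrow(norm))
})

test_that("TMB is count over footprint", {
  sim <- simulate_paired_mafs(sim_config(seed = 1L))
  maf <- sim$mafs[[sim$pairs$normoxia[1]]]
  expect_equal(compute_tmb(maf[0, ], 57.7), 0)
  expect_equal(compute_tmb(maf[seq_len(57L), ], 57), 1)
  expect_error(compute_tmb(maf, 0), "positive")
  # linearity in count, inverse-linearity in footprint
  expect_equal(compute_tmb(maf, 57.7) / 2, compute_tmb(maf, 2 * 57.7))
  expect_equal(compute_tmb(rbind(maf, maf[1:10, ]), 57.7),
               (nrow(maf) + 10) / 57.7)
  # non-silent option drops Silent records
  n_sil <- sum(maf$Variant_Classification == "Silent")
  expect_equal(compute_tmb(maf, 57.7, nonsilent_only = TRUE),
               (nrow(maf) - n_sil) / 57.7)
})

test_that("SNV classification folds purine references onto pyrimidines", {
  # full enumeration against the hand-written convention
  expect_equal(classify_snv("C", "T"), data.frame(class = "C>T",
               type = "transition"), ignore_attr = TRUE)
  expect_equal(classify_snv("G", "A")$class, "C>T")
  expect_equal(classify_snv("G", "A")$type, "transition")
  expect_equal(classify_snv("A", "C")$class, "T>G")
  expect_equal(classify_snv("A", "C")$type, "transversion")
  expect_equal(classify_snv("A", "G")$class, "T>C")
  expect_equal(classify_snv("T", "A")$class, "T>A")
  expect_equal(classify_snv("G", "C")$class, "C>G")
  expect_equal(classify_snv("G", "T")$class, "C>A")
  all_cls <- classify_snv(rep(c("A", "C", "G", "T"), each = 3),
                          c("C", "G", "T", "A", "G", "T",
                            "A", "C", "T", "A", "C", "G"))
  expect_true(all(all_cls$class %in%
                    c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")))
  expect_identical(sum(all_cls$type == "transition"), 4L)
  expect_error(classify_snv("A", "A"), "distinct")
  expect_error(classify_snv("-", "A"), "single bases")
})

test_that("landscape summaries recover the planted spectrum", {
  cfg <- sim_config(seed = 5L)
  sim <- simulate_paired_mafs(cfg)
  land <- summarize_landscape(sim$mafs, sim$pairs, cfg$exome_size_mb)
  expect_identical(nrow(land$per_pair), 24L)
  # spectra bookkeeping per group
  for (g in names(land$group_spectra)) {
    sp <- land$group_spectra[[g]]
    n_priv <- sum(land$per_pair$n_variants[land$per_pair$group == g])
    expect_identical(sum(sp$class_counts), n_priv)
  }
  # transition percentage tracks the planted bias
  ti <- vapply(1:5, function(s) {
    sim_s <- simulate_paired_mafs(sim_config(seed = s))
    land_s <- summarize_landscape(sim_s$mafs, sim_s$pairs)
    mean(vapply(land_s$group_spectra, `[[`, numeric(1), "transition_pct"))
  }, numeric(1))
  expect_lt(abs(mean(ti) - 70), 5)

  expect_error(summarize_landscape(sim$mafs[1:3], sim$pairs), "not found")
})

test_that("top-gene ranking matches a brute-force tally oracle", {
  cfg <- sim_config(seed = 8L)
  sim <- simulate_paired_mafs(cfg)
  land <- summarize_landscape(sim$mafs, sim$pairs)
  top <- top_mutated_genes(land$private, 10L)
  expect_identical(nrow(top), 10L)

  # oracle: loop over all records, tally per-gene sample sets and counts
  sample_sets <- list(); totals <- list()
  for (b in names(land$private)) {
    df <- land$private[[b]]
    for (i in seq_len(nrow(df))) {
      g <- df$Hugo_Symbol[i]
      sample_sets[[g]] <- union(sample_sets[[g]], b)
      totals[[g]] <- (if (is.null(totals[[g]])) 0L else totals[[g]]) + 1L
    }
  }
  oracle <- data.frame(gene = names(sample_sets),
                       n_samples = vapply(sample_sets, length, integer(1)),
                       n_variants = unlist(totals[names(sample_sets)]))
  oracle <- oracle[order(-oracle$n_samples, -oracle$n_variants,
                         oracle$gene), ]
  expect_identical(top$gene, utils::head(oracle$gene, 10))
  expect_identical(top$n_samples, utils::head(oracle$n_samples, 10))
  expect_identical(top$n_variants, utils::head(oracle$n_variants, 10))
  expect_equal(top$pct_samples,
               utils::head(oracle$n_samples, 10) / 24 * 100)

  # documented tie-break: equal sample counts resolved by variant count
  priv <- list(
    s1 = data.frame(Hugo_Symbol = c("A", "A", "A", "B"), .x = 1),
    s2 = data.frame(Hugo_Symbol = c("A", "A", "B", "B"), .x = 1))
  priv <- lapply(priv, function(d) {
    d$.sample <- NULL; d$.x <- NULL
    d$Variant_Classification <- "Missense_Mutation"
    d
  })
  tt <- top_mutated_genes(priv, 2L)
  expect_identical(tt$gene, c("A", "B"))  # 5 vs 3 variants, both in 2/2
})
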