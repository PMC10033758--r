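# Shared fixtures built in code.

# Small config for fast per-module tests; study-scale defaults are used
# only where a check calibrates against them.
small_cfg <- function(seed = 1L, ...) {
  sim_config(seed = seed, n_transcripts = 300L, n_windows = 600L,
             cnv_segments = list(c(100L, 180L, 1L)), ...)
}

# Truth status per window for a simulated coverage track.
coverage_truth_status <- function(cov, cfg) {
  cn <- rep(cfg$true_ploidy, cfg$n_windows)
  tr <- cov$truth
  for (i in seq_len(nrow(tr)))
    cn[(tr$start_window[i] + 1L):tr$end_window[i]] <- tr$copy_number[i]
  ifelse(cn > cfg$true_ploidy, "gain",
         ifelse(cn < cfg$true_ploidy, "loss", "neutral"))
}

# Window-status accuracy of a call_cnv() result against planted truth.
cnv_status_accuracy <- function(res, cov, cfg) {
  truth <- coverage_truth_status(cov, cfg)
  called <- rep(res$segments$status, res$segments$n_windows)
  mean(called == truth[res$ratios$window + 1L])
}

# Independent brute-force oracle: textbook BH step-up, written directly
# from the definition (sort, p * m / rank, cumulative minimum from the
# largest rank, restore order).
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Independent brute-force oracle for paired subtraction: O(n^2) row-wise
# field comparison, no key construction.
subtract_oracle <- function(hyp, norm) {
  keep <- vapply(seq_len(nrow(hyp)), function(i) {
    !any(vapply(seq_len(nrow(norm)), function(j) {
      hyp$Chromosome[i] == norm$Chromosome[j] &&
        hyp$Start_Position[i] == norm$Start_Position[j] &&
        hyp$End_Position[i] == norm$End_Position[j] &&
        hyp$Reference_Allele[i] == norm$Reference_Allele[j] &&
        hyp$Tumor_Seq_Allele2[i] == norm$Tumor_Seq_Allele2[j] &&
        hyp$Variant_Type[i] == norm$Variant_Type[j]
    }, logical(1)))
  }, logical(1))
  out <- hyp[keep, , drop = FALSE]
  out[order(out$Chromosome, out$Start_Position), , drop = FALSE]
}

# Random small MAF pair with controlled overlap, for oracle checks.
random_maf_pair <- function(n_shared = 20L, n_norm_only = 10L,
                            n_hyp_only = 15L) {
  mk <- function(n, offset) {
    if (n == 0L) {
      out <- mk(1L, offset)
      return(out[0L, , drop = FALSE])
    }
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L),
                  character(1))
    data.frame(
      Hugo_Symbol = sample(sprintf("G%02d", 1:20), n, replace = TRUE),
      Chromosome = sample(c("chr1", "chr2"), n, replace = TRUE),
      Start_Position = offset + sample.int(10000L, n),
      End_Position = 0L,
      Reference_Allele = ref,
      Tumor_Seq_Allele2 = alt,
      Variant_Classification = "Missense_Mutation",
      Variant_Type = "SNP",
      Tumor_Sample_Barcode = "S",
      stringsAsFactors = FALSE
    )
  }
  shared <- mk(n_shared, 0L)
  shared$End_Position <- shared$Start_Position
  norm_only <- mk(n_norm_only, 20000L)
  norm_only$End_Position <- norm_only$Start_Position
  hyp_only <- mk(n_hyp_only, 40000L)
  hyp_only$End_Position <- hyp_only$Start_Position
  list(hypoxia = rbind(shared, hyp_only),
       normoxia = rbind(shared, norm_only))
}
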