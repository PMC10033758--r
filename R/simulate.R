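# Synthetic-data generators. Each is a pure function of its sim_config
# (including the seed): identical config => identical output. Generators
# use distinct seed offsets so the streams for different data modalities
# are independent of each other under one config.

seed_offsets <- c(signature = 0L, expression = 1L, splicing = 2L,
                  mafs = 3L, coverage = 4L, cohort = 5L)

set_sim_seed <- function(cfg, stream) {
  set.seed(cfg$seed + seed_offsets[[stream]])
}

#' Simulate replicate-level signature fold changes
#'
#' Emulates the raw material of the cell-line hypoxia score: per
#' (cell line, gene, replicate) fold changes of the signature genes under
#' acute hypoxia, with a latent sensitivity label per cell line.
#' Sensitive lines are drawn with per-gene fold-change medians
#' `group_effect`-fold higher than resistant lines; `group_effect = 1`
#' plants no separation.
#'
#' @param cfg A [sim_config()].
#' @return A list with `fc` (data.frame: `cell_line`, `gene`, `replicate`,
#'   `fold_change`, all fold changes strictly positive) and `truth`
#'   (data.frame: `cell_line`, `sensitive`).
#' @export
simulate_signature_fc <- function(cfg) {
  cfg <- validate_sim_config(cfg)
  set_sim_seed(cfg, "signature")

  lines <- sprintf("CL%02d", seq_len(cfg$n_cell_lines))
  n_sens <- ceiling(cfg$n_cell_lines / 2)
  sensitive <- seq_len(cfg$n_cell_lines) <= n_sens
  genes <- sprintf("SIG%02d", seq_len(cfg$n_signature_genes))

  gene_base <- stats::rnorm(cfg$n_signature_genes, mean = 1, sd = 0.3)
  line_effect <- stats::rnorm(cfg$n_cell_lines, mean = 0, sd = 0.15)

  grid <- expand.grid(replicate = seq_len(cfg$n_replicate_experiments),
                      gene = seq_len(cfg$n_signature_genes),
                      line = seq_len(cfg$n_cell_lines))
  log2fc <- gene_base[grid$gene] + line_effect[grid$line] +
    ifelse(sensitive[grid$line], log2(cfg$group_effect), 0) +
    stats::rnorm(nrow(grid), sd = 0.3)

  list(
    fc = data.frame(cell_line = lines[grid$line],
                    gene = genes[grid$gene],
                    replicate = grid$replicate,
                    fold_change = 2 ^ log2fc,
                    stringsAsFactors = FALSE),
    truth = data.frame(cell_line = lines, sensitive = sensitive,
                       stringsAsFactors = FALSE)
  )
}

#' Simulate an array expression matrix with planted DE transcripts
#'
#' Log-normal intensities for `n_transcripts` transcript clusters over
#' paired normoxia/hypoxia sample groups; a `de_fraction` of transcripts
#' carries a `de_effect`-fold multiplicative shift in hypoxia (random
#' direction).
#'
#' @param cfg A [sim_config()].
#' @return A list with `matrix` (linear intensities, transcripts x
#'   samples), `samples` (data.frame: `sample_id`, `condition`), and
#'   `truth` (data.frame: `transcript`, `direction` in {-1, +1}; empty
#'   when `de_fraction = 0`).
#' @export
simulate_expression_matrix <- function(cfg) {
  cfg <- validate_sim_config(cfg)
  if (cfg$n_samples_per_condition < 2L)
    stop("n_samples_per_condition must be >= 2", call. = FALSE)
  set_sim_seed(cfg, "expression")

  n <- cfg$n_samples_per_condition
  transcripts <- sprintf("TC%06d", seq_len(cfg$n_transcripts))
  samples <- data.frame(
    sample_id = c(sprintf("N%d", seq_len(n)), sprintf("H%d", seq_len(n))),
    condition = rep(c("normoxia", "hypoxia"), each = n),
    stringsAsFactors = FALSE
  )

  base <- stats::rnorm(cfg$n_transcripts, mean = 7, sd = 1.5)
  log2mat <- matrix(base, nrow = cfg$n_transcripts, ncol = 2 * n) +
    matrix(stats::rnorm(cfg$n_transcripts * 2 * n, sd = 0.35),
           nrow = cfg$n_transcripts)

  n_de <- round(cfg$de_fraction * cfg$n_transcripts)
  truth <- data.frame(transcript = character(0), direction = integer(0),
                      stringsAsFactors = FALSE)
  if (n_de > 0) {
    idx <- sample.int(cfg$n_transcripts, n_de)
    dir <- sample(c(-1L, 1L), n_de, replace = TRUE)
    hyp_cols <- which(samples$condition == "hypoxia")
    log2mat[idx, hyp_cols] <- log2mat[idx, hyp_cols] +
      dir * log2(cfg$de_effect)
    truth <- data.frame(transcript = transcripts[idx], direction = dir,
                        stringsAsFactors = FALSE)
  }

  mat <- 2 ^ log2mat
  dimnames(mat) <- list(transcripts, samples$sample_id)
  list(matrix = mat, samples = samples, truth = truth)
}

splice_event_levels <- c("cassette exon", "intron retention",
                         "alt 5′ donor", "alt 3′ acceptor",
                         "mutually exclusive exons", "alt first exon",
                         "alt last exon", "complex")

#' Simulate gene/probe-region signals with planted cassette exons
#'
#' Each transcript gets a gene-level summary signal and three probe
#' selection region (PSR) signals per sample; PSR signals track the gene
#' signal so that normalization cancels sample effects. A
#' `splice_fraction` of transcripts is planted with one PSR shifted
#' 4-fold in hypoxia while its gene signal is unchanged (the signature of
#' a cassette exon), and carries candidate event labels whose scores rank
#' the true event highest.
#'
#' @param cfg A [sim_config()].
#' @return A list with `gene` (matrix transcripts x samples), `psr`
#'   (matrix PSR x samples), `psr_map` (data.frame: `psr_id`,
#'   `transcript`), `samples`, `events` (data.frame: `transcript`,
#'   `event`, `score`), and `truth` (data.frame: `transcript`, `psr_id`).
#' @export
simulate_splicing_signals <- function(cfg) {
  cfg <- validate_sim_config(cfg)
  set_sim_seed(cfg, "splicing")

  n <- cfg$n_samples_per_condition
  n_t <- cfg$n_transcripts
  n_psr <- 3L
  transcripts <- sprintf("TC%06d", seq_len(n_t))
  samples <- data.frame(
    sample_id = c(sprintf("N%d", seq_len(n)), sprintf("H%d", seq_len(n))),
    condition = rep(c("normoxia", "hypoxia"), each = n),
    stringsAsFactors = FALSE
  )
  n_s <- nrow(samples)

  gene_log2 <- matrix(stats::rnorm(n_t, mean = 7, sd = 1), n_t, n_s) +
    matrix(stats::rnorm(n_t * n_s, sd = 0.25), n_t)

  psr_map <- data.frame(
    psr_id = sprintf("TC%06d_PSR%d", rep(seq_len(n_t), each = n_psr),
                     rep(seq_len(n_psr), n_t)),
    transcript = rep(transcripts, each = n_psr),
    stringsAsFactors = FALSE
  )
  offset <- stats::rnorm(nrow(psr_map), sd = 0.5)
  psr_log2 <- gene_log2[rep(seq_len(n_t), each = n_psr), , drop = FALSE] +
    offset +
    matrix(stats::rnorm(nrow(psr_map) * n_s, sd = 0.25), nrow(psr_map))

  n_spl <- round(cfg$splice_fraction * n_t)
  truth <- data.frame(transcript = character(0), psr_id = character(0),
                      stringsAsFactors = FALSE)
  events <- data.frame(transcript = character(0), event = character(0),
                       score = numeric(0), stringsAsFactors = FALSE)
  if (n_spl > 0) {
    idx <- sample.int(n_t, n_spl)
    hyp_cols <- which(samples$condition == "hypoxia")
    psr_row <- (idx - 1L) * n_psr + 1L   # first PSR of each planted transcript
    psr_log2[psr_row, hyp_cols] <- psr_log2[psr_row, hyp_cols] + log2(4)
    truth <- data.frame(transcript = transcripts[idx],
                        psr_id = psr_map$psr_id[psr_row],
                        stringsAsFactors = FALSE)
    # candidate events: true cassette exon scored highest, plus two decoys
    decoys <- vapply(seq_len(n_spl), function(i)
      sample(setdiff(splice_event_levels, "cassette exon"), 2L),
      character(2))
    events <- data.frame(
      transcript = rep(transcripts[idx], each = 3L),
      event = as.vector(rbind("cassette exon", decoys)),
      score = as.vector(rbind(stats::runif(n_spl, 0.70, 0.95),
                              stats::runif(n_spl, 0.05, 0.50),
                              stats::runif(n_spl, 0.05, 0.50))),
      stringsAsFactors = FALSE
    )
  }

  gene <- 2 ^ gene_log2
  psr <- 2 ^ psr_log2
  dimnames(gene) <- list(transcripts, samples$sample_id)
  dimnames(psr) <- list(psr_map$psr_id, samples$sample_id)
  list(gene = gene, psr = psr, psr_map = psr_map, samples = samples,
       events = events, truth = truth)
}

# study design of the exome arm: 3 cell lines per hypoxia group,
# 2 biological x 2 technical replicates => 4 matched pairs per line
.maf_lines_per_group <- 3L
.maf_bio_reps <- 2L
.maf_tech_reps <- 2L

transition_partner <- c(A = "G", G = "A", C = "T", T = "C")

draw_unique_positions <- function(n, contig_len, exclude = integer(0)) {
  pos <- integer(0)
  taken <- exclude
  while (length(pos) < n) {
    cand <- sample.int(contig_len, n - length(pos), replace = TRUE)
    cand <- setdiff(unique(cand), taken)
    pos <- c(pos, cand)
    taken <- c(taken, cand)
  }
  pos
}

random_bases <- function(lens) {
  vapply(lens, function(k)
    paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = ""),
    character(1))
}

# One batch of synthetic MAF records on contig chrS at given positions.
make_maf_records <- function(pos, cfg, genes, gene_w, barcode) {
  n <- length(pos)
  if (n == 0L)
    return(data.frame(Hugo_Symbol = character(0), Chromosome = character(0),
                      Start_Position = integer(0), End_Position = integer(0),
                      Reference_Allele = character(0),
                      Tumor_Seq_Allele2 = character(0),
                      Variant_Classification = character(0),
                      Variant_Type = character(0),
                      Tumor_Sample_Barcode = character(0),
                      stringsAsFactors = FALSE))
  cls <- sample(names(cfg$class_mixture), n, replace = TRUE,
                prob = cfg$class_mixture)
  type <- ifelse(cls %in% c("Frame_Shift_Ins", "In_Frame_Ins"), "INS",
          ifelse(cls %in% c("Frame_Shift_Del", "In_Frame_Del"), "DEL", "SNP"))
  ref <- character(n); alt <- character(n); end <- pos

  is_snp <- type == "SNP"
  if (any(is_snp)) {
    r <- sample(c("A", "C", "G", "T"), sum(is_snp), replace = TRUE)
    ti <- stats::runif(sum(is_snp)) < cfg$transition_bias
    a <- character(sum(is_snp))
    a[ti] <- transition_partner[r[ti]]
    if (any(!ti)) {
      tv <- list(A = c("C", "T"), G = c("C", "T"),
                 C = c("A", "G"), T = c("A", "G"))
      a[!ti] <- vapply(r[!ti], function(b) sample(tv[[b]], 1L), character(1))
    }
    ref[is_snp] <- r; alt[is_snp] <- a
  }
  is_ins <- type == "INS"
  if (any(is_ins)) {
    len <- ifelse(cls[is_ins] == "In_Frame_Ins", 3L,
                  sample(c(1L, 2L), sum(is_ins), replace = TRUE))
    ref[is_ins] <- "-"
    alt[is_ins] <- random_bases(len)
  }
  is_del <- type == "DEL"
  if (any(is_del)) {
    len <- ifelse(cls[is_del] == "In_Frame_Del", 3L,
                  sample(c(1L, 2L), sum(is_del), replace = TRUE))
    ref[is_del] <- random_bases(len)
    alt[is_del] <- "-"
    end[is_del] <- pos[is_del] + len - 1L
  }

  data.frame(
    Hugo_Symbol = sample(genes, n, replace = TRUE, prob = gene_w),
    Chromosome = "chrS",
    Start_Position = pos,
    End_Position = end,
    Reference_Allele = ref,
    Tumor_Seq_Allele2 = alt,
    Variant_Classification = cls,
    Variant_Type = type,
    Tumor_Sample_Barcode = barcode,
    stringsAsFactors = FALSE
  )
}

#' Simulate paired normoxia/hypoxia MAF tables
#'
#' For each of 3 cell lines per hypoxia group and 4 matched pairs per cell
#' line (2 biological x 2 technical replicates), generates a normoxia MAF
#' and a hypoxia MAF sharing exactly `background_shared_variants`
#' identical records; the hypoxia MAF additionally contains
#' `K ~ Poisson(rate_group * exome_size_mb)` hypoxia-private records with
#' classes drawn from `class_mixture` and transition-biased SNV
#' substitutions. Variant positions are uniform over a single synthetic
#' contig `chrS`; identity keys are unique within each sample.
#'
#' @param cfg A [sim_config()]; `hypoxia_rate_per_mb` must be a named
#'   vector giving the per-group rates.
#' @return A list with `mafs` (named list, barcode -> MAF data.frame),
#'   `manifest` (data.frame: `sample_id`, `cell_line`, `condition`,
#'   `biological_rep`, `technical_rep`), `pairs` (data.frame: `normoxia`,
#'   `hypoxia`, `cell_line`, `group`, `biological_rep`, `technical_rep`),
#'   and `truth` (data.frame with the planted private count `k_private`
#'   and rate per pair).
#' @export
simulate_paired_mafs <- function(cfg) {
  cfg <- validate_sim_config(cfg)
  if (is.null(names(cfg$hypoxia_rate_per_mb)))
    stop("invalid parameter: `hypoxia_rate_per_mb` must be named by group",
         call. = FALSE)
  set_sim_seed(cfg, "mafs")

  contig_len <- round(cfg$exome_size_mb * 1e6)
  genes <- sprintf("GENE%02d", 1:60)
  gene_w <- 1 / seq_along(genes)   # Zipf-like: a few recurrently hit genes

  groups <- names(cfg$hypoxia_rate_per_mb)
  design <- expand.grid(technical_rep = seq_len(.maf_tech_reps),
                        biological_rep = seq_len(.maf_bio_reps),
                        line = seq_len(.maf_lines_per_group),
                        group = groups, stringsAsFactors = FALSE)
  design$cell_line <- paste0(design$group, "_", design$line)

  mafs <- list(); manifest <- list(); pairs <- list(); truth <- list()
  for (i in seq_len(nrow(design))) {
    d <- design[i, ]
    tag <- sprintf("%s_b%dt%d", d$cell_line, d$biological_rep,
                   d$technical_rep)
    bc_n <- paste0(tag, "_N")
    bc_h <- paste0(tag, "_H")

    bg_pos <- draw_unique_positions(cfg$background_shared_variants,
                                    contig_len)
    bg <- make_maf_records(bg_pos, cfg, genes, gene_w, bc_n)

    rate <- cfg$hypoxia_rate_per_mb[[d$group]]
    k <- stats::rpois(1L, rate * cfg$exome_size_mb)
    priv_pos <- draw_unique_positions(k, contig_len, exclude = bg_pos)
    priv <- make_maf_records(priv_pos, cfg, genes, gene_w, bc_h)

    bg_h <- bg
    bg_h$Tumor_Sample_Barcode <- bc_h
    hyp <- rbind(bg_h, priv)
    hyp <- hyp[order(hyp$Chromosome, hyp$Start_Position), ]
    rownames(hyp) <- NULL
    norm <- bg[order(bg$Chromosome, bg$Start_Position), ]
    rownames(norm) <- NULL

    mafs[[bc_n]] <- norm
    mafs[[bc_h]] <- hyp
    manifest[[length(manifest) + 1L]] <- data.frame(
      sample_id = c(bc_n, bc_h), cell_line = d$cell_line,
      condition = c("normoxia", "hypoxia"),
      biological_rep = d$biological_rep, technical_rep = d$technical_rep,
      stringsAsFactors = FALSE)
    pairs[[length(pairs) + 1L]] <- data.frame(
      normoxia = bc_n, hypoxia = bc_h, cell_line = d$cell_line,
      group = d$group, biological_rep = d$biological_rep,
      technical_rep = d$technical_rep, stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <- data.frame(
      hypoxia = bc_h, cell_line = d$cell_line, group = d$group,
      k_private = k, rate_per_mb = rate, stringsAsFactors = FALSE)
  }

  list(mafs = mafs,
       manifest = do.call(rbind, manifest),
       pairs = do.call(rbind, pairs),
       truth = do.call(rbind, truth))
}

#' Simulate matched case/control coverage tracks
#'
#' Control depth is Poisson(`depth_mean`) per fixed-width window on the
#' synthetic contig `chrS`; the case track follows
#' Poisson(`depth_mean * CN / true_ploidy`) with planted copy-number
#' segments from `cnv_segments`. Mappability is 1.0 except for an
#' optional `low_mappability_fraction` of windows.
#'
#' @param cfg A [sim_config()].
#' @return A list with `case` and `control` (BED-like data.frames:
#'   `chrom`, `start`, `end`, `depth`, `mappability`; 0-based half-open),
#'   `truth` (data.frame of planted segments: `start_window`,
#'   `end_window`, `copy_number`) and `true_ploidy`.
#' @export
simulate_coverage <- function(cfg) {
  cfg <- validate_sim_config(cfg)
  set_sim_seed(cfg, "coverage")

  n <- cfg$n_windows
  start <- (seq_len(n) - 1L) * cfg$window_size_bp
  cn <- rep(cfg$true_ploidy, n)
  segs <- lapply(cfg$cnv_segments, as.integer)
  for (s in segs) cn[(s[1] + 1L):s[2]] <- s[3]

  mapp <- rep(1, n)
  n_low <- round(cfg$low_mappability_fraction * n)
  if (n_low > 0) mapp[sample.int(n, n_low)] <- stats::runif(n_low, 0.2, 0.8)

  control <- data.frame(chrom = "chrS", start = start,
                        end = start + cfg$window_size_bp,
                        depth = stats::rpois(n, cfg$depth_mean),
                        mappability = mapp, stringsAsFactors = FALSE)
  case <- control
  case$depth <- stats::rpois(n, cfg$depth_mean * cn / cfg$true_ploidy)

  truth <- if (length(segs)) {
    data.frame(start_window = vapply(segs, `[`, integer(1), 1L),
               end_window = vapply(segs, `[`, integer(1), 2L),
               copy_number = vapply(segs, `[`, integer(1), 3L))
  } else {
    data.frame(start_window = integer(0), end_window = integer(0),
               copy_number = integer(0))
  }
  list(case = case, control = control, truth = truth,
       true_ploidy = cfg$true_ploidy)
}

#' Simulate a patient cohort with a latent hypoxia factor
#'
#' Each patient carries a latent hypoxia factor; signature-gene
#' expression is positively correlated with it, and per-gene binary
#' alteration events have their odds multiplied by
#' `alteration_enrichment` for patients in the top half of the factor.
#'
#' @param cfg A [sim_config()]; requires `n_patients >= 4`.
#' @return A list with `expression` (data.frame, patients x signature
#'   genes, linear scale, rownames = patient ids), `alterations`
#'   (data.frame, patients x alteration genes, 0/1), and `truth`
#'   (data.frame: `patient`, `factor`, `high`).
#' @export
simulate_cohort <- function(cfg) {
  cfg <- validate_sim_config(cfg)
  if (cfg$n_patients < 4L)
    stop("n_patients must be >= 4", call. = FALSE)
  set_sim_seed(cfg, "cohort")

  patients <- sprintf("P%03d", seq_len(cfg$n_patients))
  z <- stats::rnorm(cfg$n_patients)
  high <- rank(z, ties.method = "first") > cfg$n_patients / 2

  genes <- sprintf("SIG%02d", seq_len(cfg$n_signature_genes))
  mu <- stats::rnorm(cfg$n_signature_genes, mean = 8, sd = 1)
  log2e <- outer(z, rep(1, cfg$n_signature_genes)) +
    matrix(mu, cfg$n_patients, cfg$n_signature_genes, byrow = TRUE) +
    matrix(stats::rnorm(cfg$n_patients * cfg$n_signature_genes, sd = 0.3),
           cfg$n_patients)
  expression <- as.data.frame(2 ^ log2e, row.names = patients)
  names(expression) <- genes

  alt_genes <- sprintf("ALT%02d", seq_len(cfg$n_alteration_genes))
  p0 <- 0.15
  odds <- p0 / (1 - p0) * ifelse(high, cfg$alteration_enrichment, 1)
  p <- odds / (1 + odds)
  alterations <- as.data.frame(
    matrix(stats::rbinom(cfg$n_patients * cfg$n_alteration_genes, 1L,
                         rep(p, cfg$n_alteration_genes)),
           cfg$n_patients, cfg$n_alteration_genes),
    row.names = patients)
  names(alterations) <- alt_genes

  list(expression = expression, alterations = alterations,
       truth = data.frame(patient = patients, factor = z, high = high,
                          stringsAsFactors = FALSE))
}
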