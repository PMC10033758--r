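#' Simulation configuration
#'
#' Builds and validates the configuration object consumed by every
#' `simulate_*()` generator. The defaults reproduce the study design the
#' pipeline was built for: 12 cell lines scored with an 8-gene hypoxia
#' signature (fold changes from three replicate experiments), paired
#' normoxia/hypoxia exome samples (2 biological x 2 technical replicates
#' per cell line, so 4 matched pairs), hypoxia-private mutation rates of
#' 3.0 vs 1.6 mutations/Mb for the sensitive (HH) and resistant (HL)
#' groups over a 57.7 Mb exome footprint, a variant-class mixture
#' dominated by frameshift insertions, a transition-biased SNV spectrum,
#' 50 kb coverage windows at mean depth 100, and a patient cohort whose
#' signature-gene expression tracks a latent hypoxia factor.
#'
#' @param seed Integer seed; every generator is a pure function of the
#'   config including this seed.
#' @param n_cell_lines Number of cell lines scored with the signature.
#' @param n_signature_genes Number of genes in the hypoxia signature.
#' @param n_replicate_experiments Replicate fold-change measurements per
#'   (cell line, gene).
#' @param group_effect Multiplicative fold-change separation between
#'   hypoxia-sensitive and resistant cell lines (must be > 0; 1 means no
#'   planted separation).
#' @param n_transcripts Number of transcript clusters on the simulated array.
#' @param n_samples_per_condition Arrays per condition (normoxia/hypoxia).
#' @param de_fraction Proportion of transcripts planted as differentially
#'   expressed.
#' @param de_effect Linear fold change of planted DE transcripts (>= 1).
#' @param splice_fraction Proportion of transcripts planted with a cassette
#'   exon splicing event.
#' @param background_shared_variants Variants shared by both members of each
#'   normoxia/hypoxia pair (clonal/germline background).
#' @param hypoxia_rate_per_mb Named numeric `c(HH = ..., HL = ...)`:
#'   hypoxia-private mutation rate per megabase for each group.
#' @param exome_size_mb Sequenced exome footprint in megabases.
#' @param class_mixture Named probabilities over MAF
#'   `Variant_Classification` labels; must sum to 1.
#' @param transition_bias Proportion of simulated SNVs that are transitions.
#' @param n_windows Number of 0-based coverage windows on the synthetic
#'   contig.
#' @param window_size_bp Window width in bp.
#' @param depth_mean Mean control read depth per window.
#' @param cnv_segments List of `c(start_window, end_window, copy_number)`
#'   triplets (half-open window index ranges) planted in the case track.
#' @param true_ploidy Baseline copy number of the simulated genome (2, 3
#'   or 4).
#' @param n_patients Patients in the simulated cohort.
#' @param alteration_enrichment Odds multiplier for gene-alteration events
#'   in patients in the top half of the latent hypoxia factor.
#' @param n_alteration_genes Genes tracked in the cohort alteration table.
#' @param low_mappability_fraction Fraction of coverage windows given a
#'   mappability below the default 0.85 filter (0 = all windows mappable).
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_cell_lines = 12L,
                       n_signature_genes = 8L,
                       n_replicate_experiments = 3L,
                       group_effect = 4,
                       n_transcripts = 2000L,
                       n_samples_per_condition = 4L,
                       de_fraction = 0.05,
                       de_effect = 4,
                       splice_fraction = 0.05,
                       background_shared_variants = 100L,
                       hypoxia_rate_per_mb = c(HH = 3.0, HL = 1.6),
                       exome_size_mb = 57.7,
                       class_mixture = default_class_mixture(),
                       transition_bias = 0.7,
                       n_windows = 2000L,
                       window_size_bp = 50000L,
                       depth_mean = 100,
                       cnv_segments = list(c(300L, 500L, 1L),
                                           c(1200L, 1350L, 3L)),
                       true_ploidy = 2L,
                       n_patients = 50L,
                       alteration_enrichment = 5,
                       n_alteration_genes = 10L,
                       low_mappability_fraction = 0) {
  cfg <- list(
    seed = as.integer(seed),
    n_cell_lines = as.integer(n_cell_lines),
    n_signature_genes = as.integer(n_signature_genes),
    n_replicate_experiments = as.integer(n_replicate_experiments),
    group_effect = group_effect,
    n_transcripts = as.integer(n_transcripts),
    n_samples_per_condition = as.integer(n_samples_per_condition),
    de_fraction = de_fraction,
    de_effect = de_effect,
    splice_fraction = splice_fraction,
    background_shared_variants = as.integer(background_shared_variants),
    hypoxia_rate_per_mb = hypoxia_rate_per_mb,
    exome_size_mb = exome_size_mb,
    class_mixture = class_mixture,
    transition_bias = transition_bias,
    n_windows = as.integer(n_windows),
    window_size_bp = as.integer(window_size_bp),
    depth_mean = depth_mean,
    cnv_segments = cnv_segments,
    true_ploidy = as.integer(true_ploidy),
    n_patients = as.integer(n_patients),
    alteration_enrichment = alteration_enrichment,
    n_alteration_genes = as.integer(n_alteration_genes),
    low_mappability_fraction = low_mappability_fraction
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' Default variant-classification mixture
#'
#' Frameshift insertions dominate, followed by missense mutations,
#' mirroring the class ordering observed after chronic hypoxia exposure.
#'
#' @return Named numeric vector of probabilities summing to 1.
#' @export
default_class_mixture <- function() {
  c(Frame_Shift_Ins = 0.35,
    Missense_Mutation = 0.30,
    Frame_Shift_Del = 0.10,
    Nonsense_Mutation = 0.05,
    Silent = 0.10,
    Splice_Site = 0.04,
    In_Frame_Ins = 0.03,
    In_Frame_Del = 0.03)
}

maf_classes <- c("Frame_Shift_Ins", "Frame_Shift_Del", "Missense_Mutation",
                 "Nonsense_Mutation", "Silent", "Splice_Site",
                 "In_Frame_Ins", "In_Frame_Del")

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  counts <- c("n_cell_lines", "n_signature_genes", "n_replicate_experiments",
              "n_transcripts", "n_samples_per_condition", "n_windows",
              "window_size_bp", "true_ploidy", "n_patients",
              "n_alteration_genes")
  for (nm in counts) {
    if (length(cfg[[nm]]) != 1L || is.na(cfg[[nm]]) || cfg[[nm]] <= 0L)
      stop("invalid parameter: `", nm, "` must be a strictly positive count",
           call. = FALSE)
  }
  props <- c("de_fraction", "splice_fraction", "transition_bias",
             "low_mappability_fraction")
  for (nm in props) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1)
      stop("invalid parameter: `", nm, "` must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$group_effect <= 0)
    stop("invalid parameter: `group_effect` must be positive", call. = FALSE)
  if (cfg$de_effect < 1)
    stop("invalid parameter: `de_effect` must be >= 1 (linear fold change)",
         call. = FALSE)
  if (any(cfg$hypoxia_rate_per_mb < 0))
    stop("invalid parameter: `hypoxia_rate_per_mb` must be nonnegative",
         call. = FALSE)
  if (cfg$exome_size_mb <= 0)
    stop("invalid parameter: `exome_size_mb` must be positive", call. = FALSE)
  if (cfg$depth_mean <= 0)
    stop("invalid parameter: `depth_mean` must be positive", call. = FALSE)
  if (cfg$background_shared_variants < 0)
    stop("invalid parameter: `background_shared_variants` must be >= 0",
         call. = FALSE)
  if (cfg$alteration_enrichment <= 0)
    stop("invalid parameter: `alteration_enrichment` must be positive",
         call. = FALSE)
  if (!cfg$true_ploidy %in% c(2L, 3L, 4L))
    stop("invalid parameter: `true_ploidy` must be 2, 3 or 4", call. = FALSE)

  mix <- cfg$class_mixture
  if (is.null(names(mix)) || any(!nzchar(names(mix))))
    stop("invalid parameter: `class_mixture` must be a named vector",
         call. = FALSE)
  bad <- setdiff(names(mix), maf_classes)
  if (length(bad))
    stop("invalid parameter: unknown variant class in `class_mixture`: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-9)
    stop("invalid parameter: `class_mixture` probabilities must be ",
         "nonnegative and sum to 1", call. = FALSE)

  segs <- cfg$cnv_segments
  if (length(segs)) {
    m <- do.call(rbind, lapply(segs, as.numeric))
    if (ncol(m) != 3L)
      stop("invalid parameter: each cnv_segment must be ",
           "(start_window, end_window, copy_number)", call. = FALSE)
    if (any(m[, 1] < 0) || any(m[, 2] > cfg$n_windows) ||
        any(m[, 1] >= m[, 2]) || any(m[, 3] < 0))
      stop("invalid parameter: cnv_segments must be nonempty half-open ",
           "ranges within [0, n_windows) with nonnegative copy number",
           call. = FALSE)
    o <- order(m[, 1])
    m <- m[o, , drop = FALSE]
    if (nrow(m) > 1L && any(m[-1L, 1] < m[-nrow(m), 2]))
      stop("invalid parameter: cnv_segments must be non-overlapping",
           call. = FALSE)
  }
  cfg
}
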