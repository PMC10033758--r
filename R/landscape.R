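# Mutational-landscape summaries of the hypoxia-private variant sets:
# per-pair TMB, variant-classification spectra, six-class SNV spectra,
# transition/transversion percentages, and top-mutated-gene tables, with
# cell-line and group aggregates (mean and t-based 95% CI).

snv_classes <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

summarize_one_pair <- function(records, exome_size_mb) {
  class_counts <- sort(table(records$Variant_Classification),
                       decreasing = TRUE)
  snp <- records[records$Variant_Type == "SNP", , drop = FALSE]
  snv_counts <- stats::setNames(integer(length(snv_classes)), snv_classes)
  ti_pct <- tv_pct <- NA_real_
  if (nrow(snp)) {
    cls <- classify_snv(snp$Reference_Allele, snp$Tumor_Seq_Allele2)
    tab <- table(factor(cls$class, levels = snv_classes))
    snv_counts[] <- as.integer(tab)
    ti_pct <- 100 * mean(cls$type == "transition")
    tv_pct <- 100 - ti_pct
  }
  list(tmb = compute_tmb(records, exome_size_mb),
       n_variants = nrow(records),
       class_counts = class_counts,
       snv_class_counts = snv_counts,
       transition_pct = ti_pct,
       transversion_pct = tv_pct)
}

#' Per-pair, per-cell-line and per-group mutational landscape
#'
#' For every matched pair the hypoxia MAF is normalized against its
#' normoxia control ([subtract_paired()]); the retained hypoxia-private
#' variants are summarized as TMB, variant-classification counts,
#' six-class SNV counts and transition/transversion percentages.
#' Cell-line and group aggregates report the mean TMB with its t-based
#' 95% confidence interval, pooled class spectra (descending) and pooled
#' transition percentage.
#'
#' @param mafs Named list of MAF data.frames, one per sample barcode.
#' @param pairs Data.frame with columns `normoxia`, `hypoxia`,
#'   `cell_line`, `group` (as produced by [simulate_paired_mafs()]).
#' @param exome_size_mb Footprint in megabases for the TMB denominator.
#' @return A list with `per_pair` (data.frame: one row per pair with
#'   `tmb`, `n_variants`, `transition_pct`, ...), `private` (named list
#'   of hypoxia-private record sets, keyed by hypoxia barcode),
#'   `cell_line` and `group` aggregate data.frames, and pooled spectra
#'   `class_counts` / `snv_class_counts` per group.
#' @export
summarize_landscape <- function(mafs, pairs, exome_size_mb = 57.7) {
  need <- setdiff(c(pairs$normoxia, pairs$hypoxia), names(mafs))
  if (length(need))
    stop("pair barcode(s) not found among MAFs: ",
         paste(need, collapse = ", "), call. = FALSE)

  private <- list()
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    pr <- subtract_paired(mafs[[pairs$hypoxia[i]]],
                          mafs[[pairs$normoxia[i]]])
    private[[pairs$hypoxia[i]]] <- pr
    s <- summarize_one_pair(pr, exome_size_mb)
    rows[[i]] <- data.frame(
      hypoxia = pairs$hypoxia[i], normoxia = pairs$normoxia[i],
      cell_line = pairs$cell_line[i], group = pairs$group[i],
      n_variants = s$n_variants, tmb = s$tmb,
      transition_pct = s$transition_pct,
      transversion_pct = s$transversion_pct,
      stringsAsFactors = FALSE)
  }
  per_pair <- do.call(rbind, rows)

  aggregate_level <- function(key) {
    out <- lapply(split(per_pair, per_pair[[key]]), function(df) {
      ci <- if (nrow(df) >= 2L) mean_ci(df$tmb)
            else c(mean = mean(df$tmb), low = NA_real_, high = NA_real_)
      data.frame(level = df[[key]][1], n_pairs = nrow(df),
                 mean_tmb = ci[["mean"]], ci_low = ci[["low"]],
                 ci_high = ci[["high"]],
                 mean_transition_pct = mean(df$transition_pct, na.rm = TRUE),
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, out)
    names(res)[1] <- key
    rownames(res) <- NULL
    res
  }

  pooled_spectra <- function(barcodes) {
    all_rec <- do.call(rbind, private[barcodes])
    summarize_one_pair(all_rec, exome_size_mb)[
      c("class_counts", "snv_class_counts", "transition_pct")]
  }
  group_spectra <- lapply(split(per_pair$hypoxia, per_pair$group),
                          pooled_spectra)

  list(per_pair = per_pair,
       private = private,
       cell_line = aggregate_level("cell_line"),
       group = aggregate_level("group"),
       group_spectra = group_spectra,
       exome_size_mb = exome_size_mb)
}

#' Top mutated genes
#'
#' Genes ranked by the number of samples carrying at least one retained
#' variant in the gene (descending), then by total variant count
#' (descending), then by gene label (ascending). Reports per-class
#' counts and the percentage of samples mutated.
#'
#' @param private Named list of hypoxia-private MAF data.frames, one per
#'   sample.
#' @param n Number of genes to report (default 10).
#' @return Data.frame with columns `gene`, `n_samples`, `pct_samples`,
#'   `n_variants`, plus one count column per variant classification.
#' @export
top_mutated_genes <- function(private, n = 10L) {
  if (n < 1L)
    stop("n must be >= 1", call. = FALSE)
  all_rec <- do.call(rbind, lapply(names(private), function(b) {
    df <- private[[b]]
    if (nrow(df)) cbind(df, .sample = b) else NULL
  }))
  if (is.null(all_rec) || nrow(all_rec) == 0L)
    return(data.frame(gene = character(0), n_samples = integer(0),
                      pct_samples = numeric(0), n_variants = integer(0)))

  n_total_samples <- length(private)
  per_gene <- split(all_rec, all_rec$Hugo_Symbol)
  stats_df <- data.frame(
    gene = names(per_gene),
    n_samples = vapply(per_gene, function(df)
      length(unique(df$.sample)), integer(1)),
    n_variants = vapply(per_gene, nrow, integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  stats_df$pct_samples <- 100 * stats_df$n_samples / n_total_samples
  ord <- order(-stats_df$n_samples, -stats_df$n_variants, stats_df$gene)
  top <- utils::head(stats_df[ord, , drop = FALSE], n)

  cls_levels <- sort(unique(all_rec$Variant_Classification))
  cls_counts <- vapply(top$gene, function(g) {
    as.integer(table(factor(per_gene[[g]]$Variant_Classification,
                            levels = cls_levels)))
  }, integer(length(cls_levels)))
  cls_counts <- matrix(cls_counts, ncol = length(cls_levels), byrow = TRUE,
                       dimnames = list(NULL, cls_levels))
  out <- cbind(top[, c("gene", "n_samples", "pct_samples", "n_variants")],
               as.data.frame(cls_counts))
  rownames(out) <- NULL
  out
}
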