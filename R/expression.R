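# Moderated differential expression in the signed-fold-change dialect of
# array software: tests run on log2 intensities with per-transcript
# variances shrunk toward the across-transcript mean variance, fold
# changes are reported as signed linear ratios (r if r >= 1, else -1/r),
# and significance requires |FC| >= 2 together with BH FDR <= 0.05.

#' Signed linear fold change
#'
#' Ratio `r = mean_case / mean_control` reported as `r` when `r >= 1`
#' and `-1/r` otherwise, so down-regulation is symmetric with
#' up-regulation and `|signed_fc| >= 1` always.
#'
#' @param mean_case,mean_control Strictly positive group means
#'   (vectorized).
#' @return Signed fold change(s).
#' @examples
#' signed_fold_change(4, 2)   #  2
#' signed_fold_change(2, 4)   # -2
#' @export
signed_fold_change <- function(mean_case, mean_control) {
  if (any(!is.finite(mean_case) | mean_case <= 0) ||
      any(!is.finite(mean_control) | mean_control <= 0))
    stop("group means must be strictly positive", call. = FALSE)
  r <- mean_case / mean_control
  ifelse(r >= 1, r, -1 / r)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment via [stats::p.adjust()] with input validation.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, order-preserving.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L)
    stop("empty p-value vector", call. = FALSE)
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Moderated two-group differential-expression test
#'
#' Per transcript, a two-sample comparison of log2 intensities with the
#' per-transcript pooled variance `s^2` shrunk toward the mean variance
#' across transcripts `s0^2`:
#' `s~^2 = (d0 * s0^2 + d * s^2) / (d0 + d)` with `d = n1 + n2 - 2`,
#' giving `t = dmean / (s~ * sqrt(1/n1 + 1/n2))` on `d + d0` degrees of
#' freedom. `prior_df = 0` recovers the ordinary pooled two-sample t.
#' Fold changes are signed linear ratios of the group means; a
#' transcript is significant when `signed_fc <= -2` or `>= 2` and the BH
#' FDR is `<= 0.05`.
#'
#' @param mat Strictly positive intensity matrix (transcripts x samples),
#'   linear scale; log2 is taken internally.
#' @param condition Character vector over columns with values in
#'   `{control, case}` labels.
#' @param case,control Labels of the two conditions (defaults
#'   "hypoxia" vs "normoxia").
#' @param prior_df Prior degrees of freedom `d0` of the variance
#'   moderation (default 4).
#' @param fc_threshold,fdr_threshold Significance thresholds (defaults 2
#'   and 0.05).
#' @return Data.frame with columns `transcript`, `signed_fc`,
#'   `t_statistic`, `p_value`, `fdr`, `significant`.
#' @export
moderated_de_test <- function(mat, condition, case = "hypoxia",
                              control = "normoxia", prior_df = 4,
                              fc_threshold = 2, fdr_threshold = 0.05) {
  mat <- as.matrix(mat)
  if (any(!is.finite(mat) | mat <= 0))
    stop("intensity matrix must be strictly positive", call. = FALSE)
  if (length(condition) != ncol(mat))
    stop("condition labels must match matrix columns", call. = FALSE)
  if (prior_df < 0)
    stop("prior_df must be nonnegative", call. = FALSE)
  i1 <- which(condition == case)
  i2 <- which(condition == control)
  if (length(i1) < 2L || length(i2) < 2L)
    stop("each condition needs at least 2 samples", call. = FALSE)

  lm2 <- log2(mat)
  n1 <- length(i1); n2 <- length(i2)
  m1 <- rowMeans(lm2[, i1, drop = FALSE])
  m2 <- rowMeans(lm2[, i2, drop = FALSE])
  v1 <- apply(lm2[, i1, drop = FALSE], 1, stats::var)
  v2 <- apply(lm2[, i2, drop = FALSE], 1, stats::var)
  d <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / d
  s0_2 <- mean(s2)
  s2_mod <- (prior_df * s0_2 + d * s2) / (prior_df + d)

  tstat <- (m1 - m2) / sqrt(s2_mod * (1 / n1 + 1 / n2))
  tstat[s2_mod == 0 & m1 == m2] <- 0
  p <- 2 * stats::pt(-abs(tstat), df = d + prior_df)
  fdr <- bh_fdr(p)

  fc <- signed_fold_change(rowMeans(mat[, i1, drop = FALSE]),
                           rowMeans(mat[, i2, drop = FALSE]))
  data.frame(
    transcript = if (is.null(rownames(mat)))
      as.character(seq_len(nrow(mat))) else rownames(mat),
    signed_fc = fc,
    t_statistic = tstat,
    p_value = p,
    fdr = fdr,
    significant = abs(fc) >= fc_threshold & fdr <= fdr_threshold,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Shared, group-specific and common DEG sets
#'
#' `common_all` is the intersection of the significant sets over all cell
#' lines; each group's specific set is the intersection over that group's
#' lines minus `common_all`. The three outputs are pairwise disjoint.
#'
#' @param sets Named list, one character vector of significant gene ids
#'   per cell line.
#' @param groups Named character vector mapping each cell line to one of
#'   two group labels.
#' @return List with elements `common_all` and one `<label>_specific` per
#'   group label.
#' @export
deg_set_algebra <- function(sets, groups) {
  if (!length(sets))
    stop("empty set list", call. = FALSE)
  unknown <- setdiff(names(sets), names(groups))
  if (length(unknown))
    stop("cell line(s) without group label: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  labels <- unique(groups[names(sets)])
  common_all <- Reduce(intersect, sets)
  out <- list(common_all = sort(common_all))
  for (lab in labels) {
    members <- sets[names(sets)[groups[names(sets)] == lab]]
    out[[paste0(lab, "_specific")]] <-
      sort(setdiff(Reduce(intersect, members), common_all))
  }
  out
}
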