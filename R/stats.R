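# Group statistics used throughout the analysis: t-based 95% confidence
# intervals, unpaired two-sided t-tests (Student pooled-variance by
# default, Welch optional), one-way ANOVA with Sidak-corrected pairwise
# comparisons, and HH-vs-HL alteration-frequency concordance.

#' Mean with t-based confidence interval
#'
#' `mean +/- t_{(1+level)/2, n-1} * sd / sqrt(n)` with sample SD.
#'
#' @param values Numeric vector, `n >= 2`.
#' @param level Confidence level (default 0.95).
#' @return Named numeric vector `c(mean, low, high)`.
#' @export
mean_ci <- function(values, level = 0.95) {
  n <- length(values)
  if (n < 2L)
    stop("at least 2 values are required", call. = FALSE)
  m <- mean(values)
  half <- stats::qt((1 + level) / 2, df = n - 1) *
    stats::sd(values) / sqrt(n)
  c(mean = m, low = m - half, high = m + half)
}

#' Unpaired two-sided t-test with group summaries
#'
#' Student pooled-variance by default (`flavor = "student"`), Welch via
#' `flavor = "welch"`. If both groups have zero variance and equal
#' means, `p = 1` by convention.
#'
#' @param a,b Numeric vectors (each `n >= 2`).
#' @param flavor `"student"` or `"welch"`.
#' @param labels Character pair naming the groups.
#' @return List with `labels`, `n`, `mean`, `ci95` (2 x 2 matrix),
#'   `t_statistic`, `df`, `p_value`, `test_flavor`.
#' @export
t_test_unpaired <- function(a, b, flavor = c("student", "welch"),
                            labels = c("A", "B")) {
  flavor <- match.arg(flavor)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values", call. = FALSE)

  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      tt <- list(statistic = 0, parameter = length(a) + length(b) - 2,
                 p.value = 1)
    } else {
      tt <- list(statistic = sign(mean(a) - mean(b)) * Inf,
                 parameter = length(a) + length(b) - 2, p.value = 0)
    }
  } else {
    ht <- stats::t.test(a, b, var.equal = (flavor == "student"),
                        alternative = "two.sided")
    tt <- list(statistic = unname(ht$statistic),
               parameter = unname(ht$parameter), p.value = ht$p.value)
  }
  ci <- rbind(mean_ci(a), mean_ci(b))
  rownames(ci) <- labels
  list(labels = labels,
       n = c(length(a), length(b)),
       mean = c(mean(a), mean(b)),
       ci95 = ci,
       t_statistic = tt$statistic,
       df = tt$parameter,
       p_value = tt$p.value,
       test_flavor = flavor)
}

#' One-way ANOVA with Sidak-corrected pairwise comparisons
#'
#' Ordinary one-way ANOVA; each requested pair is compared with a
#' pooled-variance t using the ANOVA residual mean square and residual
#' degrees of freedom, and p-values are Sidak-adjusted:
#' `p' = 1 - (1 - p)^m` for `m` comparisons. Degenerate all-constant
#' input yields `p = 1` by convention.
#'
#' @param groups Named list of numeric vectors (k >= 2 groups, each
#'   `n >= 2`).
#' @param comparisons List of character pairs (group names) to compare;
#'   default all pairs.
#' @return List with `f_statistic`, `df`, `p_value` (ANOVA), and
#'   `comparisons` data.frame (`group1`, `group2`, `t`, `p_raw`,
#'   `p_adjusted`).
#' @export
anova_sidak <- function(groups, comparisons = NULL) {
  if (length(groups) < 2L)
    stop("at least 2 groups are required", call. = FALSE)
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("each group needs at least 2 values", call. = FALSE)
  if (is.null(comparisons))
    comparisons <- utils::combn(names(groups), 2, simplify = FALSE)
  if (!length(comparisons))
    stop("empty comparisons list", call. = FALSE)

  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, integer(1))),
              levels = names(groups))
  n <- length(y)
  df_resid <- n - length(groups)
  mse <- sum(vapply(groups, function(x)
    sum((x - mean(x))^2), numeric(1))) / df_resid

  if (mse == 0) {
    grand <- mean(y)
    msb <- sum(vapply(groups, function(x)
      length(x) * (mean(x) - grand)^2, numeric(1))) / (length(groups) - 1)
    fstat <- if (msb == 0) NA_real_ else Inf
    p_anova <- if (msb == 0) 1 else 0
  } else {
    fit <- stats::aov(y ~ g)
    s <- summary(fit)[[1]]
    fstat <- s[["F value"]][1]
    p_anova <- s[["Pr(>F)"]][1]
  }

  m <- length(comparisons)
  comp <- do.call(rbind, lapply(comparisons, function(pr) {
    x1 <- groups[[pr[1]]]; x2 <- groups[[pr[2]]]
    se <- sqrt(mse * (1 / length(x1) + 1 / length(x2)))
    tval <- if (se == 0) {
      if (mean(x1) == mean(x2)) 0 else sign(mean(x1) - mean(x2)) * Inf
    } else (mean(x1) - mean(x2)) / se
    p_raw <- if (is.infinite(tval)) 0
             else if (se == 0) 1
             else 2 * stats::pt(-abs(tval), df = df_resid)
    data.frame(group1 = pr[1], group2 = pr[2], t = tval, p_raw = p_raw,
               p_adjusted = pmin(1, 1 - (1 - p_raw)^m),
               stringsAsFactors = FALSE)
  }))
  list(f_statistic = fstat, df = c(length(groups) - 1, df_resid),
       p_value = p_anova, comparisons = comp)
}

#' HH-vs-HL alteration-frequency concordance
#'
#' For each listed gene, the alteration frequency in the hypoxia-high
#' and hypoxia-low patient groups; the concordant count is the number of
#' genes whose HH frequency strictly exceeds the HL frequency.
#'
#' @param alterations Data.frame/matrix of 0/1 alteration events,
#'   patients in rows (rownames = patient ids), genes in columns.
#' @param cohort_calls Data.frame from [score_cohort()] (columns
#'   `patient`, `group`).
#' @param genes Gene columns to compare; default all.
#' @return List with `per_gene` (data.frame: `gene`, `freq_HH`,
#'   `freq_HL`), `concordant_count`, `total`.
#' @export
alteration_concordance <- function(alterations, cohort_calls,
                                   genes = colnames(alterations)) {
  alterations <- as.data.frame(alterations)
  missing <- setdiff(genes, names(alterations))
  if (length(missing))
    stop("gene(s) absent from alteration table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  idx <- match(cohort_calls$patient, rownames(alterations))
  if (anyNA(idx))
    stop("cohort patient(s) absent from alteration table", call. = FALSE)
  hh <- idx[cohort_calls$group == "HH"]
  hl <- idx[cohort_calls$group == "HL"]
  per_gene <- data.frame(
    gene = genes,
    freq_HH = vapply(genes, function(g)
      mean(alterations[hh, g]), numeric(1)),
    freq_HL = vapply(genes, function(g)
      mean(alterations[hl, g]), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(per_gene = per_gene,
       concordant_count = sum(per_gene$freq_HH > per_gene$freq_HL),
       total = length(genes))
}
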