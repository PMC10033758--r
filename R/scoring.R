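# Cell-line hypoxia scoring and cohort stratification.
#
# A cell line's hypoxia score is the geometric mean, over the signature
# genes, of its replicate-averaged fold changes under hypoxia. Relative
# scores (score minus the geometric mean of all scores) split lines into
# hypoxia-high (HH, relative score > 0) and hypoxia-low (HL). In patient
# cohorts the score is rank-based: each signature gene contributes +1 or
# -1 by comparison with its cohort median, and the summed score > 0
# defines HH.

#' Average signature fold changes over replicates
#'
#' @param fc_table Data.frame with columns `cell_line`, `gene`,
#'   `replicate`, `fold_change` (all fold changes strictly positive).
#' @return Data.frame with columns `cell_line`, `gene`, `mean_fc`
#'   (arithmetic mean over replicates).
#' @export
average_gene_fold_changes <- function(fc_table) {
  required <- c("cell_line", "gene", "fold_change")
  missing <- setdiff(required, names(fc_table))
  if (length(missing))
    stop("fc_table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (nrow(fc_table) == 0L)
    stop("fc_table is empty", call. = FALSE)
  bad <- which(!is.finite(fc_table$fold_change) | fc_table$fold_change <= 0)
  if (length(bad))
    stop("non-positive fold change for cell line ",
         fc_table$cell_line[bad[1]], ", gene ", fc_table$gene[bad[1]],
         " (row ", bad[1], ")", call. = FALSE)
  agg <- stats::aggregate(fold_change ~ cell_line + gene, data = fc_table,
                          FUN = mean)
  names(agg)[names(agg) == "fold_change"] <- "mean_fc"
  agg[order(agg$cell_line, agg$gene), , drop = FALSE]
}

#' Hypoxia score of one cell line
#'
#' Geometric mean of the replicate-averaged signature-gene fold changes.
#'
#' @param gene_means Positive numeric vector of per-gene mean fold changes.
#' @return The geometric mean, a positive scalar.
#' @examples
#' hypoxia_score(c(1, 2, 4, 8, 1, 2, 4, 8))  # 2^1.5
#' @export
hypoxia_score <- function(gene_means) {
  if (length(gene_means) == 0L)
    stop("gene_means is empty", call. = FALSE)
  if (any(!is.finite(gene_means) | gene_means <= 0))
    stop("gene means must be strictly positive", call. = FALSE)
  exp(mean(log(gene_means)))
}

#' Relative hypoxia scores and HH/HL grouping
#'
#' Each cell line's relative score is its hypoxia score minus the
#' geometric mean of all scores; lines with relative score > 0 form the
#' hypoxia-high (HH) group, the rest hypoxia-low (HL).
#'
#' @param scores Named positive numeric vector, one hypoxia score per
#'   cell line (>= 2 lines).
#' @return Data.frame with columns `cell_line`, `score`,
#'   `relative_score`, `group` ("HH"/"HL"), ordered by decreasing score.
#' @export
relative_scores <- function(scores) {
  if (length(scores) < 2L)
    stop("at least 2 cell lines are required", call. = FALSE)
  if (any(!is.finite(scores) | scores <= 0))
    stop("scores must be strictly positive", call. = FALSE)
  # exact center when all scores coincide, so relatives are exactly zero
  center <- if (max(scores) == min(scores)) scores[[1]]
            else exp(mean(log(scores)))
  rel <- scores - center
  out <- data.frame(
    cell_line = if (is.null(names(scores))) as.character(seq_along(scores))
                else names(scores),
    score = unname(scores),
    relative_score = unname(rel),
    group = ifelse(rel > 0, "HH", "HL"),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score cell lines from a replicate fold-change table
#'
#' Convenience composition: replicate averaging, per-line geometric-mean
#' score, relative score and HH/HL group.
#'
#' @inheritParams average_gene_fold_changes
#' @return As [relative_scores()].
#' @export
score_cell_lines <- function(fc_table) {
  means <- average_gene_fold_changes(fc_table)
  scores <- vapply(split(means$mean_fc, means$cell_line), hypoxia_score,
                   numeric(1))
  relative_scores(scores)
}

#' Median-dichotomized cohort hypoxia score
#'
#' For each signature gene the cohort median is computed (midpoint median
#' for even cohorts); each patient scores +1 if their expression is
#' strictly above the median and -1 otherwise (ties score -1). The
#' hypoxia score is the sum over genes, and patients with score > 0 are
#' stratified HH, the rest HL.
#'
#' @param expression Data.frame or matrix, patients in rows (rownames =
#'   patient ids), genes in columns, linear or log scale (the score is
#'   rank-based, so any strictly increasing per-gene transform gives
#'   identical calls).
#' @param genes Character vector of signature gene columns to use;
#'   default all columns.
#' @return Data.frame with columns `patient`, `hypoxia_score`, `group`,
#'   plus one `score_<gene>` column in {-1, +1} per gene.
#' @export
score_cohort <- function(expression, genes = colnames(expression)) {
  expression <- as.data.frame(expression)
  if (nrow(expression) < 2L)
    stop("at least 2 patients are required", call. = FALSE)
  missing <- setdiff(genes, names(expression))
  if (length(missing))
    stop("missing signature gene column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  sub <- expression[, genes, drop = FALSE]
  if (anyNA(sub))
    stop("missing values among signature genes", call. = FALSE)

  gene_scores <- vapply(sub, function(x) {
    ifelse(x > stats::median(x), 1L, -1L)
  }, integer(nrow(sub)))
  gene_scores <- matrix(gene_scores, nrow = nrow(sub),
                        dimnames = list(NULL, genes))
  total <- rowSums(gene_scores)
  out <- data.frame(
    patient = if (is.null(rownames(expression)))
      as.character(seq_len(nrow(expression))) else rownames(expression),
    hypoxia_score = as.integer(total),
    group = ifelse(total > 0, "HH", "HL"),
    stringsAsFactors = FALSE
  )
  colnames(gene_scores) <- paste0("score_", genes)
  cbind(out, as.data.frame(gene_scores))
}
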