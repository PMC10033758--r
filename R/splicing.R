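# Splicing-index analysis of probe-selection-region (PSR) signals.
# Probe signals are normalized by their gene-level signal per sample, so
# that transcript-wide expression changes cancel; the splicing index is
# the signed fold change (hypoxia vs normoxia) of the normalized means.
# A transcript is significant when |SI| > 2 and the exon-level BH FDR is
# < 0.05 (strict inequalities, as in the array-software convention), and
# its splicing event is the candidate with the highest event score;
# transcripts without any scored candidate are excluded.

#' Canonical splicing-event labels (tie-break order)
#' @export
splicing_event_labels <- function() splice_event_levels

#' Per-probe and per-transcript splicing index
#'
#' @param psr Strictly positive PSR signal matrix (probe regions x
#'   samples).
#' @param gene Strictly positive gene signal matrix (transcripts x
#'   samples).
#' @param psr_map Data.frame mapping `psr_id` to `transcript`; every PSR
#'   row must map to a row of `gene`.
#' @param condition Character vector over samples
#'   ("normoxia"/"hypoxia").
#' @param prior_df Prior degrees of freedom of the moderated test on log2
#'   normalized signals.
#' @return A list with `probes` (per-PSR data.frame: `psr_id`,
#'   `transcript`, `splicing_index`, `p_value`, `exon_fdr`) and
#'   `transcripts` (per-transcript data.frame: `transcript`,
#'   `splicing_index` of the probe with maximal `|SI|`, its `exon_fdr`,
#'   and `significant`).
#' @export
splicing_index <- function(psr, gene, psr_map, condition, prior_df = 4,
                           si_threshold = 2, fdr_threshold = 0.05) {
  psr <- as.matrix(psr); gene <- as.matrix(gene)
  if (any(psr <= 0) || any(gene <= 0))
    stop("signals must be strictly positive", call. = FALSE)
  if (is.null(rownames(gene)))
    stop("gene matrix must have transcript rownames", call. = FALSE)
  idx <- match(psr_map$transcript, rownames(gene))
  if (anyNA(idx))
    stop("probe region(s) without gene signal: ",
         paste(unique(psr_map$psr_id[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  if (nrow(psr_map) != nrow(psr))
    stop("psr_map must have one row per PSR row", call. = FALSE)

  normalized <- psr / gene[idx, , drop = FALSE]
  res <- moderated_de_test(normalized, condition, prior_df = prior_df,
                           fc_threshold = si_threshold,
                           fdr_threshold = fdr_threshold)
  probes <- data.frame(
    psr_id = psr_map$psr_id,
    transcript = psr_map$transcript,
    splicing_index = res$signed_fc,
    p_value = res$p_value,
    exon_fdr = res$fdr,
    stringsAsFactors = FALSE
  )

  pick <- tapply(seq_len(nrow(probes)), probes$transcript, function(ii) {
    ii[which.max(abs(probes$splicing_index[ii]))]
  })
  pick <- unlist(pick)
  transcripts <- data.frame(
    transcript = probes$transcript[pick],
    splicing_index = probes$splicing_index[pick],
    exon_fdr = probes$exon_fdr[pick],
    stringsAsFactors = FALSE, row.names = NULL
  )
  transcripts$significant <-
    abs(transcripts$splicing_index) > si_threshold &
    transcripts$exon_fdr < fdr_threshold
  transcripts <- transcripts[order(transcripts$transcript), , drop = FALSE]
  rownames(transcripts) <- NULL
  list(probes = probes, transcripts = transcripts)
}

#' Select the most likely splicing event
#'
#' Returns the candidate with the maximal event score; ties are broken by
#' the fixed label order of [splicing_event_labels()]. An empty candidate
#' list marks the transcript as excluded.
#'
#' @param candidates Data.frame with columns `event` and `score`
#'   (scores in `[0, 1]`), possibly empty.
#' @return List with `event` (label or `NA`), `score` (or `NA`) and
#'   `excluded` (logical).
#' @export
select_event <- function(candidates) {
  if (is.null(candidates) || nrow(candidates) == 0L)
    return(list(event = NA_character_, score = NA_real_, excluded = TRUE))
  if (any(!is.finite(candidates$score) | candidates$score < 0 |
          candidates$score > 1))
    stop("event scores must lie in [0, 1]", call. = FALSE)
  ord <- order(-candidates$score,
               match(candidates$event, splice_event_levels))
  best <- candidates[ord[1L], ]
  list(event = best$event, score = best$score, excluded = FALSE)
}

#' Full splicing-result table
#'
#' Combines per-transcript splicing indices with event selection:
#' significant transcripts with no scored candidate event are excluded
#' from the final report.
#'
#' @inheritParams splicing_index
#' @param events Data.frame of candidate events (`transcript`, `event`,
#'   `score`).
#' @return Data.frame of significant, non-excluded transcripts with
#'   columns `transcript`, `splicing_index`, `exon_fdr`, `event`,
#'   `event_score`; the full per-transcript table (including excluded
#'   flags) is attached as attribute `"all"`.
#' @export
splicing_results <- function(psr, gene, psr_map, condition, events,
                             prior_df = 4) {
  si <- splicing_index(psr, gene, psr_map, condition, prior_df = prior_df)
  tab <- si$transcripts
  sel <- lapply(tab$transcript, function(tc) {
    select_event(events[events$transcript == tc, , drop = FALSE])
  })
  tab$event <- vapply(sel, `[[`, character(1), "event")
  tab$event_score <- vapply(sel, `[[`, numeric(1), "score")
  tab$excluded <- vapply(sel, `[[`, logical(1), "excluded")
  final <- tab[tab$significant & !tab$excluded,
               c("transcript", "splicing_index", "exon_fdr", "event",
                 "event_score")]
  rownames(final) <- NULL
  attr(final, "all") <- tab
  final
}
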