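# Windowed copy-number analysis of a hypoxia (case) coverage track
# against its matched normoxia (control) track: median-normalized depth
# ratios with mappability/depth filtering, recursive binary change-point
# segmentation on log2 ratios, ploidy selection over {2,3,4} by integer
# resolvability of segment ratios, integer copy-number calls and
# gain/loss window counts. A simplified windowed-ratio re-implementation
# in the spirit of matched-control CNV callers (GC bias cancels in the
# case/control ratio).

check_same_grid <- function(case, control) {
  if (nrow(case) != nrow(control) ||
      !all(case$chrom == control$chrom) ||
      !all(case$start == control$start) ||
      !all(case$end == control$end))
    stop("case and control tracks must share an identical window grid",
         call. = FALSE)
}

#' Per-window case/control depth ratios
#'
#' Windows failing the mappability or control-depth filters are dropped;
#' each track is normalized by the median depth of its retained windows,
#' so the ratio is invariant to uniform depth scaling of either track.
#'
#' @param case,control BED-like coverage data.frames (`chrom`, `start`,
#'   `end`, `depth`, `mappability`) on identical window grids.
#' @param min_mappability Minimum window mappability (default 0.85).
#' @param min_control_depth Minimum control depth per window (default 10
#'   reads, to avoid ratio blow-ups).
#' @return Data.frame of retained windows with columns `chrom`, `start`,
#'   `end`, `window` (0-based index in the input grid), `ratio`.
#' @export
window_ratios <- function(case, control, min_mappability = 0.85,
                          min_control_depth = 10) {
  check_same_grid(case, control)
  keep <- control$mappability >= min_mappability &
    case$mappability >= min_mappability &
    control$depth >= min_control_depth
  if (!any(keep))
    stop("all windows removed by mappability/depth filters", call. = FALSE)
  cs <- case$depth[keep] / stats::median(case$depth[keep])
  ct <- control$depth[keep] / stats::median(control$depth[keep])
  data.frame(chrom = case$chrom[keep], start = case$start[keep],
             end = case$end[keep], window = which(keep) - 1L,
             ratio = cs / ct, stringsAsFactors = FALSE)
}

# Phase 1 of segmentation: exhaustive recursive binary splitting of one
# contig's log2 ratios. Each region is split at the point minimizing
# total within-segment squared error (each side >= min_len windows),
# descending until regions are too short to split. Returns the left
# boundaries of the fine partition (1-based, excluding 1).
split_full <- function(x, lo, hi, min_len) {
  n <- hi - lo + 1L
  if (n < 2L * min_len)
    return(integer(0))
  seg <- x[lo:hi]
  cum <- cumsum(seg); cum2 <- cumsum(seg^2)
  k <- min_len:(n - min_len)            # candidate left part sizes
  sse_l <- cum2[k] - cum[k]^2 / k
  sse_r <- (cum2[n] - cum2[k]) - (cum[n] - cum[k])^2 / (n - k)
  kb <- k[which.min(sse_l + sse_r)]
  c(split_full(x, lo, lo + kb - 1L, min_len),
    lo + kb,
    split_full(x, lo + kb, hi, min_len))
}

# Phase 2: agglomerative merging of adjacent fine segments. A boundary
# is retained only when the breakpoint rule fires: the difference of
# segment means must reach breakpoint_threshold times the pooled
# within-segment SD of the two segments, be nonzero, and be
# statistically solid (>= 3 standard errors of the mean difference, so
# that chance fluctuations between short fine segments do not survive);
# otherwise the most similar adjacent pair is merged, until every
# remaining boundary is a genuine breakpoint.
merge_segments <- function(x, bounds, threshold, eps = 1e-12, min_z = 3) {
  starts <- c(1L, bounds)
  ends <- c(bounds - 1L, length(x))
  n <- ends - starts + 1L
  sm <- vapply(seq_along(starts), function(i)
    sum(x[starts[i]:ends[i]]), numeric(1))
  ss <- vapply(seq_along(starts), function(i)
    sum(x[starts[i]:ends[i]]^2), numeric(1))

  repeat {
    if (length(n) == 1L) break
    i <- seq_len(length(n) - 1L)
    m1 <- sm[i] / n[i]; m2 <- sm[i + 1L] / n[i + 1L]
    diff <- abs(m1 - m2)
    sse <- (ss[i] - sm[i]^2 / n[i]) +
      (ss[i + 1L] - sm[i + 1L]^2 / n[i + 1L])
    pooled_sd <- sqrt(pmax(sse, 0) / pmax(n[i] + n[i + 1L] - 2L, 1L))
    se <- pooled_sd * sqrt(1 / n[i] + 1 / n[i + 1L])
    keep <- diff >= threshold * pooled_sd & diff >= min_z * se & diff > eps
    if (all(keep)) break
    # merge the most similar non-breakpoint pair first
    score <- ifelse(diff <= eps, 0,
                    ifelse(pooled_sd > 0, diff / (threshold * pooled_sd),
                           Inf))
    j <- which.min(replace(score, keep, Inf))
    sm[j] <- sm[j] + sm[j + 1L]
    ss[j] <- ss[j] + ss[j + 1L]
    n[j] <- n[j] + n[j + 1L]
    ends[j] <- ends[j + 1L]
    sm <- sm[-(j + 1L)]; ss <- ss[-(j + 1L)]; n <- n[-(j + 1L)]
    starts <- starts[-(j + 1L)]; ends <- ends[-(j + 1L)]
  }
  cbind(starts, ends)
}

#' Segment window ratios into constant-ratio runs
#'
#' Binary change-point segmentation on log2 ratios, per contig, in two
#' phases: exhaustive recursive binary splitting at the
#' squared-error-optimal point down to the minimum segment length,
#' followed by agglomerative merging of adjacent segments. A breakpoint
#' is retained only when the difference of the adjacent segment means
#' reaches `breakpoint_threshold` multiples of their pooled
#' within-segment standard deviation; exactly constant tracks therefore
#' yield a single segment, and short copy-number segments embedded in
#' long neutral stretches are recovered. Minimum segment length is 3
#' windows.
#'
#' @param ratios Data.frame from [window_ratios()].
#' @param breakpoint_threshold Acceptance threshold (default 0.8).
#' @param min_len Minimum segment length in windows (default 3).
#' @return Data.frame of segments with columns `chrom`, `start_index`,
#'   `end_index` (half-open indices into the retained-window table),
#'   `n_windows`, `mean_ratio` (geometric mean of window ratios).
#' @export
segment_ratios <- function(ratios, breakpoint_threshold = 0.8,
                           min_len = 3L) {
  if (!is.finite(breakpoint_threshold) || breakpoint_threshold <= 0)
    stop("breakpoint_threshold must be positive", call. = FALSE)
  if (nrow(ratios) == 0L)
    stop("no retained windows to segment", call. = FALSE)

  out <- list()
  offset <- 0L
  for (chrom in unique(ratios$chrom)) {
    idx <- which(ratios$chrom == chrom)
    lr <- log2(pmax(ratios$ratio[idx], 1e-3))  # floor guards zero depths
    bounds <- split_full(lr, 1L, length(idx), as.integer(min_len))
    segs <- merge_segments(lr, bounds, breakpoint_threshold)
    for (i in seq_len(nrow(segs))) {
      s <- segs[i, ]
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom,
        start_index = offset + s[1] - 1L,
        end_index = offset + s[2],
        n_windows = s[2] - s[1] + 1L,
        mean_ratio = 2 ^ mean(lr[s[1]:s[2]]),
        stringsAsFactors = FALSE)
    }
    offset <- offset + length(idx)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Select the baseline ploidy that explains most windows
#'
#' For each candidate ploidy `P` the explained fraction is the share of
#' windows whose `ratio * P` lies within `epsilon` of an integer; the
#' candidate with the largest fraction wins, ties going to the smallest
#' ploidy.
#'
#' @param ratios Numeric vector of window ratios (typically per-window
#'   segment-mean ratios, which average out counting noise).
#' @param candidates Candidate ploidies (default `c(2, 3, 4)`).
#' @param epsilon Integer-resolution tolerance (default 0.1).
#' @param tie_tol Explained fractions within `tie_tol` of the maximum
#'   count as ties, resolved toward the smallest ploidy (default 0.02,
#'   so a higher ploidy must explain at least 2% more windows to be
#'   preferred over a lower one).
#' @return The selected ploidy (integer).
#' @export
select_ploidy <- function(ratios, candidates = c(2L, 3L, 4L),
                          epsilon = 0.1, tie_tol = 0.02) {
  if (length(ratios) == 0L)
    stop("empty ratio set", call. = FALSE)
  if (length(candidates) == 0L)
    stop("no candidate ploidies", call. = FALSE)
  explained <- vapply(candidates, function(P) {
    x <- ratios * P
    mean(abs(x - round(x)) <= epsilon)
  }, numeric(1))
  as.integer(min(candidates[explained >= max(explained) - tie_tol]))
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Integer copy-number calls for segments
#'
#' `copy_number = round(mean_ratio * ploidy)` (halves round away from
#' zero); `status` is gain when the copy number exceeds the ploidy, loss
#' when below, neutral otherwise.
#'
#' @param segments Data.frame from [segment_ratios()].
#' @param ploidy Baseline copy number (>= 1).
#' @return `segments` with added `copy_number` and `status` columns.
#' @export
call_copy_number <- function(segments, ploidy) {
  if (ploidy < 1)
    stop("ploidy must be >= 1", call. = FALSE)
  cn <- as.integer(round_half_away(segments$mean_ratio * ploidy))
  segments$copy_number <- cn
  segments$status <- ifelse(cn > ploidy, "gain",
                     ifelse(cn < ploidy, "loss", "neutral"))
  segments
}

#' CNV / CNG / CNL window counts
#'
#' @param segments Called segments from [call_copy_number()].
#' @return List with `cng_windows`, `cnl_windows`, `cnv_windows`
#'   (= gains + losses) and `retained_windows`.
#' @export
count_cnv <- function(segments) {
  cng <- sum(segments$n_windows[segments$status == "gain"])
  cnl <- sum(segments$n_windows[segments$status == "loss"])
  list(cng_windows = cng, cnl_windows = cnl, cnv_windows = cng + cnl,
       retained_windows = sum(segments$n_windows))
}

#' Full windowed CNV pipeline for one case/control pair
#'
#' Composes ratio computation, segmentation, ploidy selection (on
#' per-window segment-mean ratios when `ploidy = "auto"`), copy-number
#' calling and window counting.
#'
#' @inheritParams window_ratios
#' @inheritParams segment_ratios
#' @param ploidy `"auto"` (select over `c(2, 3, 4)`) or a fixed integer.
#' @param epsilon Tolerance for ploidy selection.
#' @return List with `ratios`, `segments` (with per-window calls),
#'   `selected_ploidy`, and `summary` (the [count_cnv()] counts plus
#'   `breakpoint_threshold`).
#' @export
call_cnv <- function(case, control, breakpoint_threshold = 0.8,
                     min_mappability = 0.85, min_control_depth = 10,
                     ploidy = "auto", epsilon = 0.1) {
  ratios <- window_ratios(case, control, min_mappability,
                          min_control_depth)
  segments <- segment_ratios(ratios, breakpoint_threshold)
  window_mean <- rep(segments$mean_ratio, segments$n_windows)
  selected <- if (identical(ploidy, "auto"))
    select_ploidy(window_mean, epsilon = epsilon) else as.integer(ploidy)
  segments <- call_copy_number(segments, selected)
  counts <- count_cnv(segments)
  counts$breakpoint_threshold <- breakpoint_threshold
  counts$selected_ploidy <- selected
  list(ratios = ratios, segments = segments, selected_ploidy = selected,
       summary = counts)
}
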