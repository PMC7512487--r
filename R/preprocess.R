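#' Filter physiologically implausible RR intervals
#'
#' Drops intervals longer than `max_rr` (default 2 s). Positions where an
#' interval was removed are reported as continuity breaks so that windowing
#' can avoid stitching beats across a gap.
#'
#' @param intervals numeric RR vector, seconds.
#' @param max_rr retention bound in seconds.
#' @return list with `intervals` (kept values), `n_removed`, and
#'   `break_after` (indices into the *kept* series after which continuity is
#'   broken). An empty result is returned flagged (`empty = TRUE`), not as an
#'   error.
#' @examples
#' filter_rr(c(0.8, 2.5, 0.9))
#' @export
filter_rr <- function(intervals, max_rr = 2) {
  stopifnot(max_rr > 0)
  intervals <- as.numeric(intervals)
  keep <- intervals <= max_rr
  kept <- intervals[keep]
  # a removed interval at original position i breaks continuity after the
  # kept beat immediately preceding it
  break_after <- unique(cumsum(keep)[!keep])
  break_after <- break_after[break_after > 0 & break_after < length(kept)]
  list(intervals = kept, n_removed = sum(!keep),
       break_after = as.integer(break_after), empty = length(kept) == 0L)
}

#' Segment an RR series into non-overlapping fixed-length windows
#'
#' Cuts `window`-beat segments left to right; the trailing remainder is
#' dropped and counted. Optional continuity breaks (from [filter_rr()] or
#' episode boundaries) restart the windowing, so no segment spans a gap.
#'
#' @param intervals numeric RR vector, seconds.
#' @param window beats per segment (>= 4; the study uses 30 and 12).
#' @param label rhythm label attached to every produced segment.
#' @param break_after indices after which a new window must start.
#' @param start_beat index of the first interval in the source series, used
#'   to keep segment positions traceable.
#' @return list with `segments` (list of [rr_segment()]) and `n_dropped`
#'   (intervals not covered by any window). Beat conservation holds:
#'   `window * length(segments) + n_dropped == length(intervals)`.
#' @examples
#' segment_rr(runif(65, 0.6, 1.0), window = 30)$n_dropped  # 5
#' @export
segment_rr <- function(intervals, window = 30L, label = "UNKNOWN",
                       break_after = integer(0), start_beat = 1L) {
  window <- as.integer(window)
  if (window < 4L) stop("window must be >= 4 beats")
  intervals <- as.numeric(intervals)
  n <- length(intervals)
  bounds <- sort(unique(c(0L, as.integer(break_after), n)))
  segments <- list()
  n_dropped <- 0L
  for (b in seq_len(length(bounds) - 1L)) {
    lo <- bounds[b] + 1L
    hi <- bounds[b + 1L]
    run <- hi - lo + 1L
    k <- run %/% window
    n_dropped <- n_dropped + run - k * window
    for (j in seq_len(k)) {
      at <- lo + (j - 1L) * window
      segments[[length(segments) + 1L]] <-
        rr_segment(intervals[at:(at + window - 1L)], label = label,
                   start_beat = start_beat + at - 1L)
    }
  }
  list(segments = segments, n_dropped = n_dropped)
}

#' Map segment rhythm labels onto a classification task
#'
#' `"af_vs_n"` keeps AF and N segments only (AFL and junctional-rhythm
#' segments are excluded); `"af_vs_nonaf"` merges N, AFL and J into the
#' single class `NONAF`.
#'
#' @param segments list of labelled [rr_segment()]s with labels in
#'   `{AF, N, AFL, J}`.
#' @param task `"af_vs_n"` or `"af_vs_nonaf"`.
#' @return list of segments with task labels; an attribute `n_excluded`
#'   counts segments dropped by `"af_vs_n"`.
#' @export
label_segments <- function(segments, task = c("af_vs_n", "af_vs_nonaf")) {
  task <- match.arg(task)
  labels <- vapply(segments, function(s) s$label, character(1))
  bad <- setdiff(unique(labels), c("AF", "N", "AFL", "J"))
  if (length(bad) > 0) {
    stop("unknown rhythm code(s): ", paste(bad, collapse = ", "))
  }
  if (task == "af_vs_n") {
    keep <- labels %in% c("AF", "N")
    out <- segments[keep]
    attr(out, "n_excluded") <- sum(!keep)
    return(out)
  }
  out <- lapply(segments, function(s) {
    if (s$label != "AF") s$label <- "NONAF"
    s
  })
  attr(out, "n_excluded") <- 0L
  out
}

#' Extract, filter and window rhythm-pure segments from an annotated series
#'
#' Episodes are single-rhythm runs of beats. Each episode is filtered
#' (`<= max_rr`) and windowed independently, so segments never straddle an
#' episode boundary and never span a filtered-out gap; every segment carries
#' its episode's rhythm label.
#'
#' @param intervals full RR series, seconds; interval `i` is indexed by its
#'   terminating beat.
#' @param episodes data.frame with columns `start_beat`, `end_beat`
#'   (inclusive interval indices) and `rhythm` in `{AF, N, AFL, J}`;
#'   non-overlapping and ordered.
#' @param window beats per segment.
#' @param max_rr RR retention bound, seconds.
#' @return list with `segments`, `n_dropped` (windowing remainder) and
#'   `n_removed` (filtered intervals).
#' @export
segment_episodes <- function(intervals, episodes, window = 30L, max_rr = 2) {
  need <- c("start_beat", "end_beat", "rhythm")
  if (!all(need %in% names(episodes))) {
    stop("episodes must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(episodes) > 1L) {
    ord <- order(episodes$start_beat)
    episodes <- episodes[ord, ]
    if (any(episodes$start_beat[-1] <= episodes$end_beat[-nrow(episodes)])) {
      stop("episodes overlap")
    }
  }
  if (any(episodes$start_beat >= episodes$end_beat)) {
    stop("each episode needs start_beat < end_beat")
  }
  segments <- list()
  n_dropped <- 0L
  n_removed <- 0L
  for (e in seq_len(nrow(episodes))) {
    lo <- episodes$start_beat[e]
    hi <- min(episodes$end_beat[e], length(intervals))
    if (lo > length(intervals)) next
    f <- filter_rr(intervals[lo:hi], max_rr)
    n_removed <- n_removed + f$n_removed
    if (f$empty || length(f$intervals) < window) {
      n_dropped <- n_dropped + length(f$intervals)
      next
    }
    sr <- segment_rr(f$intervals, window, label = episodes$rhythm[e],
                     break_after = f$break_after, start_beat = lo)
    segments <- c(segments, sr$segments)
    n_dropped <- n_dropped + sr$n_dropped
  }
  list(segments = segments, n_dropped = n_dropped, n_removed = n_removed)
}

#' Default thresholds of the 2-of-5 signal-quality noise rule
#'
#' @return list of the five per-index thresholds plus `min_criteria = 2`.
#' @export
sqi_thresholds <- function() {
  list(bsqi = 0.5, tsqi = 0, isqi = 0, psqi = 0.8, ksqi = 3,
       min_criteria = 2L)
}

#' 2-of-5 signal-quality noise decision
#'
#' A 10-s ECG window is declared noisy when at least `min_criteria` of the
#' five predicates hold: `bsqi < 0.5`, `tsqi == 0`, `isqi == 0`,
#' `psqi < 0.8`, `ksqi < 3`. Vectorized over rows of a data frame of SQI
#' values.
#'
#' @param sqi data.frame (or named list) with columns `bsqi`, `tsqi`,
#'   `isqi`, `psqi`, `ksqi`; all finite.
#' @param thresholds as produced by [sqi_thresholds()].
#' @return logical vector, `TRUE` = noisy.
#' @examples
#' is_noisy(data.frame(bsqi = 0.4, tsqi = 0, isqi = 1, psqi = 0.9, ksqi = 5))
#' @export
is_noisy <- function(sqi, thresholds = sqi_thresholds()) {
  sqi <- as.data.frame(sqi)
  need <- c("bsqi", "tsqi", "isqi", "psqi", "ksqi")
  if (!all(need %in% names(sqi))) {
    stop("sqi must have columns: ", paste(need, collapse = ", "))
  }
  vals <- sqi[need]
  if (!all(vapply(vals, function(v) all(is.finite(v)), logical(1)))) {
    stop("SQI values must be finite")
  }
  hits <- (vals$bsqi < thresholds$bsqi) +
    (vals$tsqi == thresholds$tsqi) +
    (vals$isqi == thresholds$isqi) +
    (vals$psqi < thresholds$psqi) +
    (vals$ksqi < thresholds$ksqi)
  hits >= thresholds$min_criteria
}

#' Flag segments overlapping noisy 10-s windows
#'
#' Converts beat-indexed segments to time spans (cumulative RR) and marks a
#' segment when any (`rule = "any"`, conservative default) or most
#' (`rule = "majority"`) of the 10-s windows it overlaps are noisy.
#'
#' @param segments list of [rr_segment()]s positioned via `start_beat` in the
#'   source series `intervals`.
#' @param intervals the full RR series the segments were cut from, seconds.
#' @param sqi data.frame with `t_start_s` plus the five SQI columns; each row
#'   describes the 10-s window starting at `t_start_s`.
#' @param thresholds see [sqi_thresholds()].
#' @param rule `"any"` or `"majority"`.
#' @return logical vector along `segments`, `TRUE` = excluded as noisy.
#' @export
segment_noise_gate <- function(segments, intervals, sqi,
                               thresholds = sqi_thresholds(),
                               rule = c("any", "majority")) {
  rule <- match.arg(rule)
  if (!"t_start_s" %in% names(sqi)) stop("sqi must have column t_start_s")
  noisy <- is_noisy(sqi, thresholds)
  t_beat <- c(0, cumsum(as.numeric(intervals)))  # beat i ends at t_beat[i+1]
  win_lo <- sqi$t_start_s
  win_hi <- sqi$t_start_s + 10
  vapply(segments, function(s) {
    i0 <- s$start_beat
    i1 <- s$start_beat + length(s$intervals) - 1L
    t0 <- t_beat[i0]
    t1 <- t_beat[min(i1 + 1L, length(t_beat))]
    ov <- win_lo < t1 & win_hi > t0
    if (!any(ov)) return(FALSE)
    if (rule == "any") any(noisy[ov]) else mean(noisy[ov]) > 0.5
  }, logical(1))
}
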