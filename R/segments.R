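#' RR-interval segment
#'
#' A fixed-length window of RR intervals (seconds), the unit on which all
#' entropy measures are computed, with an optional rhythm label.
#'
#' @param intervals numeric vector of RR intervals in seconds; all positive,
#'   finite, at least 4 beats.
#' @param label optional rhythm class, one of `"AF"`, `"N"`, `"AFL"`, `"J"`,
#'   `"NONAF"`, `"UNKNOWN"`.
#' @param start_beat 1-based index of the first beat of this window in the
#'   source series (bookkeeping only).
#'
#' @return An object of class `rr_segment`: a list with elements `intervals`,
#'   `label` and `start_beat`.
#' @examples
#' seg <- rr_segment(c(0.8, 0.82, 0.79, 0.81), label = "N")
#' length(seg$intervals)
#' @export
rr_segment <- function(intervals, label = "UNKNOWN", start_beat = 1L) {
  intervals <- as.numeric(intervals)
  if (length(intervals) < 4L) {
    stop("an rr_segment needs at least 4 intervals, got ", length(intervals))
  }
  if (!all(is.finite(intervals))) {
    stop("RR intervals must all be finite")
  }
  if (any(intervals <= 0)) {
    stop("RR intervals must all be positive (seconds)")
  }
  label <- match.arg(label, c("AF", "N", "AFL", "J", "NONAF", "UNKNOWN"))
  structure(
    list(intervals = intervals, label = label,
         start_beat = as.integer(start_beat)),
    class = "rr_segment"
  )
}

#' @export
print.rr_segment <- function(x, ...) {
  cat(sprintf("<rr_segment> %d beats, label %s, mean RR %.3f s\n",
              length(x$intervals), x$label, mean(x$intervals)))
  invisible(x)
}

# Accept either an rr_segment or a bare numeric vector everywhere.
seg_intervals <- function(segment) {
  if (inherits(segment, "rr_segment")) return(segment$intervals)
  x <- as.numeric(segment)
  if (!all(is.finite(x)) || any(x <= 0)) {
    stop("RR intervals must be finite and positive")
  }
  x
}

#' Tuning parameters for the entropy measures
#'
#' Collects every tuning symbol used by the four measures: the embedding
#' dimension `m`, the fuzzy similarity weight `n`, the flexible tolerance
#' schedule (`r_init`, `r_step`, `r_max`, `min_avg_matches`), the heart-rate
#' adjustment weight `w` and the small denominator guard `epsilon` of the
#' ranged distance.
#'
#' Defaults: `m = 1` (appropriate for 12-30-beat windows and the COSEn
#' convention), `n = 2`, `r_init = 0.05` with additive steps of `0.05` capped
#' at `r_max = 1` (the ranged distance lives in `[0, 1)`), a quota of
#' `min_avg_matches = 5` average matches per template, `w = 1` (plain
#' subtraction of `log(RRmean)`) and `epsilon = 1e-10`.
#'
#' @param m embedding dimension (template length, beats), `>= 1`.
#' @param n fuzzy similarity weight (exponent on the distance), `> 0`.
#' @param r_init initial tolerance of the flexible-threshold search.
#' @param r_step additive tolerance increment per search step.
#' @param r_max cap of the search grid; `NULL` means measure-specific
#'   (1 for the ranged distance, the maximum pairwise distance for Chebyshev).
#' @param min_avg_matches required average number of matches per template
#'   (at dimension `m + 1`) that terminates the search.
#' @param w heart-rate adjustment weight, `>= 0`.
#' @param epsilon denominator guard of the ranged distance, `> 0`.
#'
#' @return A validated list of class `entropy_params`.
#' @examples
#' p <- entropy_params(m = 1, n = 2)
#' p$r_init
#' @export
entropy_params <- function(m = 1L, n = 2, r_init = 0.05, r_step = 0.05,
                           r_max = NULL, min_avg_matches = 5, w = 1,
                           epsilon = 1e-10) {
  m <- as.integer(m)
  stopifnot(m >= 1L, n > 0, r_init > 0, r_step > 0, min_avg_matches > 0,
            w >= 0, epsilon > 0)
  if (!is.null(r_max)) stopifnot(r_max >= r_init)
  structure(
    list(m = m, n = n, r_init = r_init, r_step = r_step, r_max = r_max,
         min_avg_matches = min_avg_matches, w = w, epsilon = epsilon),
    class = "entropy_params"
  )
}

#' @export
print.entropy_params <- function(x, ...) {
  cat(sprintf(
    "<entropy_params> m=%d n=%g r_init=%g r_step=%g r_max=%s quota=%g w=%g eps=%g\n",
    x$m, x$n, x$r_init, x$r_step,
    if (is.null(x$r_max)) "auto" else format(x$r_max),
    x$min_avg_matches, x$w, x$epsilon))
  invisible(x)
}

# One computed entropy value plus its diagnostics. `flag` is "ok" unless the
# value is non-finite, in which case it says why ("a_zero", "b_zero") or that
# the tolerance search ran out of grid ("r_quota_unmet", value still computed).
entropy_result <- function(value, measure, r_used = NA_real_, b_m = NA_real_,
                           a_m1 = NA_real_, flag = "ok") {
  structure(
    list(value = value, measure = measure, r_used = r_used,
         b_m = b_m, a_m1 = a_m1, flag = flag),
    class = "entropy_result"
  )
}

#' @export
print.entropy_result <- function(x, ...) {
  cat(sprintf("<entropy_result> %s = %.4f (r=%s, B=%s, A=%s, flag=%s)\n",
              x$measure, x$value,
              format(x$r_used, digits = 4), format(x$b_m, digits = 4),
              format(x$a_m1, digits = 4), x$flag))
  invisible(x)
}
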