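# Run code under a temporary RNG state when a seed is given; otherwise use
# the ambient stream. Keeps generators reproducible without clobbering the
# caller's RNG.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

clip_rr <- function(x, lo = 0.25, hi = 2) {
  n_clipped <- sum(x < lo | x > hi)
  x <- pmin(pmax(x, lo), hi)
  attr(x, "n_clipped") <- n_clipped
  x
}

#' Generate an AF-like RR series
#'
#' Atrial fibrillation presents as an irregular, serially near-uncorrelated
#' RR sequence at an elevated heart rate. The model is iid log-normal with
#' the requested mean and coefficient of variation — it captures the
#' near-random irregularity of AF RR intervals without modelling AV-node
#' physiology. Intervals are clipped to (0.25 s, 2 s), mirroring the
#' preprocessing retention bound; the clip count is attached.
#'
#' @param n_beats number of intervals (>= 12).
#' @param mean_rr mean RR in seconds (default 0.6 s, a quickened AF rate).
#' @param cv coefficient of variation (default 0.25).
#' @param seed optional integer for a reproducible draw.
#' @return numeric RR vector with attribute `n_clipped`.
#' @examples
#' rr <- synth_af_rr(30, seed = 1)
#' @export
synth_af_rr <- function(n_beats = 30L, mean_rr = 0.6, cv = 0.25,
                        seed = NULL) {
  stopifnot(n_beats >= 12L, mean_rr > 0, cv >= 0)
  with_seed(seed, {
    if (cv == 0) {
      clip_rr(rep(mean_rr, n_beats))
    } else {
      s2 <- log(1 + cv^2)
      clip_rr(stats::rlnorm(n_beats, meanlog = log(mean_rr) - s2 / 2,
                            sdlog = sqrt(s2)))
    }
  })
}

#' Generate a sinus-rhythm-like RR series
#'
#' Normal sinus rhythm is regular but not constant: a slow respiratory
#' modulation (respiratory sinus arrhythmia) rides on a long mean RR with
#' small beat-to-beat noise. Interval `k` is
#' `mean_rr + resp_depth * sin(2 pi resp_freq t_k) + N(0, sd_rr)` with `t_k`
#' the cumulative beat time.
#'
#' @param n_beats number of intervals (>= 12).
#' @param mean_rr mean RR in seconds (default 0.85 s).
#' @param sd_rr Gaussian beat-to-beat noise SD in seconds (default 0.03 s).
#' @param resp_freq respiratory frequency in Hz (default 0.25 Hz, ~15
#'   breaths/min).
#' @param resp_depth modulation amplitude in seconds (default 0.04 s).
#' @param seed optional integer for a reproducible draw.
#' @return numeric RR vector with attribute `n_clipped`.
#' @export
synth_nsr_rr <- function(n_beats = 30L, mean_rr = 0.85, sd_rr = 0.03,
                         resp_freq = 0.25, resp_depth = 0.04, seed = NULL) {
  stopifnot(n_beats >= 12L, mean_rr > 0, sd_rr >= 0, resp_depth >= 0,
            resp_freq > 0)
  with_seed(seed, {
    x <- numeric(n_beats)
    t_k <- 0
    noise <- if (sd_rr > 0) stats::rnorm(n_beats, 0, sd_rr) else
      numeric(n_beats)
    for (k in seq_len(n_beats)) {
      x[k] <- mean_rr + resp_depth * sin(2 * pi * resp_freq * t_k) + noise[k]
      t_k <- t_k + x[k]
    }
    clip_rr(x)
  })
}

#' Shuffled-NSR null series
#'
#' A second null model: a sinus-rhythm series with its beat order randomly
#' permuted. Marginal distribution identical to NSR, serial structure
#' destroyed — useful for separating what a detector owes to the RR
#' distribution from what it owes to beat ordering.
#'
#' @inheritParams synth_nsr_rr
#' @return numeric RR vector.
#' @export
synth_shuffled_nsr_rr <- function(n_beats = 30L, mean_rr = 0.85,
                                  sd_rr = 0.03, resp_freq = 0.25,
                                  resp_depth = 0.04, seed = NULL) {
  with_seed(seed, {
    x <- synth_nsr_rr(n_beats, mean_rr, sd_rr, resp_freq, resp_depth,
                      seed = NULL)
    nc <- attr(x, "n_clipped")
    x <- sample(as.numeric(x))
    attr(x, "n_clipped") <- nc
    x
  })
}

#' Generate a labelled synthetic segment dataset
#'
#' `n_af` AF-like and `n_nsr` NSR-like segments of `window` beats each,
#' every segment drawn independently, labels `"AF"` / `"NONAF"` attached.
#' The defaults (500 + 500 segments of 30 beats) are the desk-scale study
#' conditions used throughout the package's own evaluation.
#'
#' @param n_af,n_nsr class counts (>= 1).
#' @param window beats per segment.
#' @param seed integer seed controlling the whole dataset.
#' @param af_args,nsr_args named lists of overrides passed to
#'   [synth_af_rr()] / [synth_nsr_rr()].
#' @return list of labelled [rr_segment()]s, AF first.
#' @examples
#' ds <- synth_dataset(5, 5, seed = 1)
#' table(vapply(ds, function(s) s$label, character(1)))
#' @export
synth_dataset <- function(n_af = 500L, n_nsr = 500L, window = 30L, seed = 1L,
                          af_args = list(), nsr_args = list()) {
  stopifnot(n_af >= 1L, n_nsr >= 1L)
  with_seed(seed, {
    af <- lapply(seq_len(n_af), function(i) {
      rr <- do.call(synth_af_rr, c(list(n_beats = window), af_args))
      rr_segment(rr, label = "AF", start_beat = 1L + (i - 1L) * window)
    })
    nsr <- lapply(seq_len(n_nsr), function(i) {
      rr <- do.call(synth_nsr_rr, c(list(n_beats = window), nsr_args))
      rr_segment(rr, label = "NONAF",
                 start_beat = 1L + (n_af + i - 1L) * window)
    })
    c(af, nsr)
  })
}
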