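# Comparator tolerance convention: 0.2 * SD of the segment. A constant
# segment has SD 0; any positive tolerance then yields identical results
# (all distances are 0), so a nominal 1 ms floor keeps the value defined.
default_tolerance <- function(x) max(0.2 * stats::sd(x), 1e-3)

#' Mean similarity degree among template vectors
#'
#' Averages the pairwise similarity degrees over templates at dimension
#' `dim`. For the ranged-distance fuzzy form the double sum runs over all
#' `(i, j)` pairs including `i = j`, and both the `m` and `m + 1` levels use
#' the same `N - m` templates, so the averaging counts match the entropy
#' definition exactly; the comparator (Chebyshev/Heaviside) form excludes
#' self-matches.
#'
#' @param x RR series (`rr_segment` or numeric vector).
#' @param dim template dimension at which similarity is evaluated.
#' @param n fuzzy similarity weight (ignored for Heaviside).
#' @param r tolerance.
#' @param distance `"ranged"` or `"chebyshev"`.
#' @param similarity `"fuzzy"` (graded `exp(-d^n/r)`) or `"heaviside"`
#'   (binary `d <= r`).
#' @param exclude_self drop the `i = j` pairs before averaging.
#' @param n_templates template count; defaults to all `N - dim + 1`. The
#'   entropy measures pass `N - m` at both levels.
#' @param epsilon ranged-distance denominator guard.
#' @return mean similarity in `[0, 1]`.
#' @export
mean_similarity <- function(x, dim, n = 2, r = 0.2,
                            distance = c("ranged", "chebyshev"),
                            similarity = c("fuzzy", "heaviside"),
                            exclude_self = FALSE, n_templates = NULL,
                            epsilon = 1e-10) {
  distance <- match.arg(distance)
  similarity <- match.arg(similarity)
  x <- seg_intervals(x)
  min_nt <- if (exclude_self) 2L else 1L
  nt_avail <- length(x) - dim
  if (is.null(n_templates)) n_templates <- nt_avail + 1L
  if (n_templates < min_nt) {
    stop("segment too short: only ", n_templates, " template(s) at dim ", dim)
  }
  D <- pairwise_distances(x, dim, distance, epsilon, n_templates)
  S <- if (similarity == "fuzzy") fuzzy_similarity(D, n, r) else (D <= r) * 1
  if (exclude_self) {
    mean(S[row(S) != col(S)])
  } else {
    mean(S)
  }
}

#' Flexible tolerance-threshold search
#'
#' Walks the tolerance grid `r_init, r_init + r_step, ...` and returns the
#' smallest value at which the average number of matches per template at
#' dimension `m + 1` reaches `min_avg_matches`. "Matches" are the sum of
#' fuzzy similarity degrees (self-pairs included) for the ranged fuzzy
#' kernel, or the count of templates within `r` (self excluded) for the
#' Chebyshev/Heaviside kernel. If the quota is never met the search stops at
#' `r_max` and flags it.
#'
#' @param x RR series (`rr_segment` or numeric vector).
#' @param params an [entropy_params()] object supplying `m`, `n`, the `r`
#'   schedule and the match quota.
#' @param distance,similarity kernel selection as in [mean_similarity()].
#' @param exclude_self drop self-pairs from the match mass; defaults to the
#'   kernel convention (`FALSE` for ranged fuzzy, `TRUE` for Chebyshev).
#' @return list with `r` (selected tolerance), `met` (quota reached?),
#'   `avg_matches` (average matches at `r`) and `steps` (grid points tried).
#' @export
flexible_r_search <- function(x, params = entropy_params(),
                              distance = c("ranged", "chebyshev"),
                              similarity = c("fuzzy", "heaviside"),
                              exclude_self = NULL) {
  distance <- match.arg(distance)
  similarity <- match.arg(similarity)
  x <- seg_intervals(x)
  if (!all(is.finite(x))) stop("non-finite RR intervals")
  m <- params$m
  nt <- length(x) - m
  if (nt < 2L) stop("segment too short for m = ", m, ": N = ", length(x))
  if (is.null(exclude_self)) exclude_self <- distance == "chebyshev"

  D <- pairwise_distances(x, m + 1L, distance, params$epsilon, nt)
  Dn <- if (similarity == "fuzzy") D^params$n else D
  r_max <- params$r_max
  if (is.null(r_max)) {
    r_max <- if (distance == "ranged") 1 else max(max(D), params$r_init)
  }
  off <- row(D) != col(D)

  avg_matches_at <- function(r) {
    S <- if (similarity == "fuzzy") exp(-Dn / r) else (Dn <= r) * 1
    if (exclude_self) {
      mean(rowSums(S) - diag(S))
    } else {
      mean(rowSums(S))
    }
  }

  r <- params$r_init
  steps <- 1L
  repeat {
    am <- avg_matches_at(r)
    if (am >= params$min_avg_matches || r >= r_max) break
    r <- min(r + params$r_step, r_max)
    steps <- steps + 1L
  }
  list(r = r, met = am >= params$min_avg_matches, avg_matches = am,
       steps = steps)
}

#' Ranged-distance fuzzy entropy for AF detection
#'
#' The detector at the core of this package. Templates of length `m` and
#' `m + 1` (both `N - m` of them) are compared with the gain-invariant ranged
#' distance, graded by the fuzzy kernel `exp(-d^n/r)` with the tolerance `r`
#' chosen by [flexible_r_search()], and turned into a density-based entropy
#'
#' `-log(A / B) + log(2 r) - w * log(RRmean)`
#'
#' where `B` and `A` are the mean similarity degrees at dimensions `m` and
#' `m + 1`, and the last term adjusts for heart rate (AF typically quickens
#' the rate, shortening `RRmean`). With `w = 1` the adjustment is a plain
#' subtraction of `log(RRmean)`; `w` can be tuned on labelled data with
#' [tune_w()].
#'
#' @param segment an [rr_segment()] or numeric RR vector (seconds).
#' @param params an [entropy_params()] object.
#' @return An `entropy_result` with the entropy `value` (nats), the selected
#'   tolerance `r_used`, the similarity means `b_m` and `a_m1`, and a `flag`
#'   ("ok", "a_zero", "b_zero" or "r_quota_unmet"). Non-finite values are
#'   flagged, never silently replaced.
#' @examples
#' set.seed(1)
#' entropy_af(rr_segment(rlnorm(30, log(0.6), 0.25)))
#' @export
entropy_af <- function(segment, params = entropy_params()) {
  x <- seg_intervals(segment)
  m <- params$m
  if (length(x) <= m + 1L) {
    stop("segment too short: N = ", length(x), " needs N > m + 1 = ", m + 1L)
  }
  search <- flexible_r_search(x, params, distance = "ranged",
                              similarity = "fuzzy", exclude_self = FALSE)
  r <- search$r
  nt <- length(x) - m
  b_m <- mean_similarity(x, m, params$n, r, "ranged", "fuzzy",
                         exclude_self = FALSE, n_templates = nt,
                         epsilon = params$epsilon)
  a_m1 <- mean_similarity(x, m + 1L, params$n, r, "ranged", "fuzzy",
                          exclude_self = FALSE, n_templates = nt,
                          epsilon = params$epsilon)
  flag <- if (!search$met) "r_quota_unmet" else "ok"
  if (a_m1 == 0) flag <- "a_zero"
  if (b_m == 0) flag <- "b_zero"
  value <- -log(a_m1 / b_m) + log(2 * r) - params$w * log(mean(x))
  entropy_result(value, "ENTROPY_AF", r_used = r, b_m = b_m, a_m1 = a_m1,
                 flag = flag)
}

#' Sample entropy (comparator)
#'
#' Classical SampEn: the negative log of the conditional probability that
#' templates matching within `r` (Chebyshev distance, hard threshold,
#' self-matches excluded) at length `m` still match at length `m + 1`. Both
#' levels use the same `N - m` templates. Zero match counts at either level
#' make the value non-finite; the result is flagged rather than coerced.
#'
#' @param segment an [rr_segment()] or numeric RR vector.
#' @param m template length (default 2, standard HRV practice).
#' @param r tolerance in seconds; default `0.2 * sd(segment)`.
#' @return An `entropy_result` (`measure = "SAMPEN"`).
#' @export
sampen <- function(segment, m = 2L, r = NULL) {
  x <- seg_intervals(segment)
  m <- as.integer(m)
  if (length(x) <= m + 1L) {
    stop("segment too short: N = ", length(x), " needs N > m + 1 = ", m + 1L)
  }
  if (is.null(r)) r <- default_tolerance(x)
  if (r <= 0) stop("tolerance r must be > 0")
  nt <- length(x) - m
  if (nt < 2L) stop("need at least 2 templates")
  b <- mean_similarity(x, m, r = r, distance = "chebyshev",
                       similarity = "heaviside", exclude_self = TRUE,
                       n_templates = nt)
  a <- mean_similarity(x, m + 1L, r = r, distance = "chebyshev",
                       similarity = "heaviside", exclude_self = TRUE,
                       n_templates = nt)
  flag <- "ok"
  if (a == 0) flag <- "a_zero"
  if (b == 0) flag <- "b_zero"
  entropy_result(-log(a / b), "SAMPEN", r_used = r, b_m = b, a_m1 = a,
                 flag = flag)
}

#' Fuzzy measure entropy (comparator)
#'
#' Sum of a local and a global fuzzy entropy term. The local term removes
#' each template's own mean (shape similarity), the global term removes the
#' series mean (level similarity); both use Chebyshev distances, the fuzzy
#' kernel `exp(-d^n/r)` and exclude self-pairs.
#'
#' @param segment an [rr_segment()] or numeric RR vector.
#' @param m template length (default 2).
#' @param n fuzzy similarity weight applied to both terms (default 2).
#' @param r tolerance in seconds; default `0.2 * sd(segment)`.
#' @return An `entropy_result` (`measure = "FUZZYMEN"`); `b_m`/`a_m1` hold
#'   the local-term means.
#' @export
fuzzymen <- function(segment, m = 2L, n = 2, r = NULL) {
  x <- seg_intervals(segment)
  m <- as.integer(m)
  if (length(x) <= m + 1L) {
    stop("segment too short: N = ", length(x), " needs N > m + 1 = ", m + 1L)
  }
  if (is.null(r)) r <- default_tolerance(x)
  if (r <= 0) stop("tolerance r must be > 0")
  nt <- length(x) - m

  term <- function(center) {
    mean_sim <- function(dim) {
      tm <- embed_vectors(x, dim, nt)
      tm <- if (center == "local") tm - rowMeans(tm) else tm - mean(x)
      ntp <- nrow(tm)
      D <- matrix(0, ntp, ntp)
      for (k in seq_len(ncol(tm))) {
        D <- pmax(D, abs(outer(tm[, k], tm[, k], "-")))
      }
      S <- fuzzy_similarity(D, n, r)
      mean(S[row(S) != col(S)])
    }
    c(b = mean_sim(m), a = mean_sim(m + 1L))
  }

  loc <- term("local")
  glo <- term("global")
  flag <- "ok"
  if (loc[["a"]] == 0 || glo[["a"]] == 0) flag <- "a_zero"
  if (loc[["b"]] == 0 || glo[["b"]] == 0) flag <- "b_zero"
  value <- -log(loc[["a"]] / loc[["b"]]) - log(glo[["a"]] / glo[["b"]])
  entropy_result(value, "FUZZYMEN", r_used = r, b_m = loc[["b"]],
                 a_m1 = loc[["a"]], flag = flag)
}

#' Coefficient of sample entropy (comparator)
#'
#' SampEn at a flexible tolerance, converted to a density estimate and
#' adjusted for heart rate: `SampEn(m, r*) + log(2 r*) - log(RRmean)`, where
#' `r*` comes from [flexible_r_search()] with Chebyshev distance and hard
#' (Heaviside) matching, stepping by `0.01 * sd(segment)` per grid point.
#'
#' @param segment an [rr_segment()] or numeric RR vector.
#' @param params an [entropy_params()]; `m = 1` by default. `r_step` is
#'   overridden by the Chebyshev convention `0.01 * sd(segment)` unless
#'   `chebyshev_step` is given.
#' @param chebyshev_step optional explicit additive step in seconds.
#' @return An `entropy_result` (`measure = "COSEN"`).
#' @export
cosen <- function(segment, params = entropy_params(m = 1L),
                  chebyshev_step = NULL) {
  x <- seg_intervals(segment)
  m <- params$m
  if (length(x) <= m + 1L) {
    stop("segment too short: N = ", length(x), " needs N > m + 1 = ", m + 1L)
  }
  step <- if (!is.null(chebyshev_step)) chebyshev_step else
    max(0.01 * stats::sd(x), 1e-4)
  p <- entropy_params(m = m, n = params$n, r_init = params$r_init,
                      r_step = step, r_max = params$r_max,
                      min_avg_matches = params$min_avg_matches,
                      w = params$w, epsilon = params$epsilon)
  search <- flexible_r_search(x, p, distance = "chebyshev",
                              similarity = "heaviside", exclude_self = TRUE)
  r <- search$r
  se <- sampen(x, m = m, r = r)
  flag <- se$flag
  if (flag == "ok" && !search$met) flag <- "r_quota_unmet"
  value <- se$value + log(2 * r) - log(mean(x))
  entropy_result(value, "COSEN", r_used = r, b_m = se$b_m, a_m1 = se$a_m1,
                 flag = flag)
}

#' Tune the heart-rate adjustment weight on labelled segments
#'
#' The heart-rate weight `w` is a trained parameter: it scales how strongly
#' `-log(RRmean)` contributes to the detector output. This utility evaluates
#' the training AUC (exact Mann-Whitney) of `part + w * (-log(RRmean))` over
#' a grid of `w` values, where `part` is the gain-invariant
#' `-log(A/B) + log(2r)` component computed once per segment, and returns the
#' maximizer (ties toward the smaller `w`).
#'
#' @param segments list of labelled [rr_segment()]s.
#' @param params an [entropy_params()]; its `w` is ignored here.
#' @param w_grid candidate weights (default 0 to 2 in steps of 0.1).
#' @param positive label treated as AF (default `"AF"`).
#' @return list with `w` (best weight), `auc` (training AUC at `w`) and
#'   `table` (data frame of the full grid).
#' @export
tune_w <- function(segments, params = entropy_params(),
                   w_grid = seq(0, 2, by = 0.1), positive = "AF") {
  labels <- vapply(segments, function(s) s$label, character(1))
  y <- labels == positive
  if (!any(y) || all(y)) stop("need both classes to tune w")
  p0 <- entropy_params(m = params$m, n = params$n, r_init = params$r_init,
                       r_step = params$r_step, r_max = params$r_max,
                       min_avg_matches = params$min_avg_matches, w = 0,
                       epsilon = params$epsilon)
  part <- vapply(segments, function(s) entropy_af(s, p0)$value, numeric(1))
  neg_log_rrmean <- vapply(segments,
                           function(s) -log(mean(s$intervals)), numeric(1))
  aucs <- vapply(w_grid, function(w) {
    auc_mw(part + w * neg_log_rrmean, labels, positive = positive)
  }, numeric(1))
  best <- which.max(aucs)
  list(w = w_grid[best], auc = aucs[best],
       table = data.frame(w = w_grid, auc = aucs))
}

#' Compute all entropy measures over a list of segments
#'
#' Per-segment table with the four measures and their diagnostics, in the
#' layout written by the CLI `compute` command.
#'
#' @param segments list of [rr_segment()]s (or numeric vectors).
#' @param params an [entropy_params()] for the ranged-fuzzy detector and
#'   COSEn.
#' @param measures subset of `c("sampen", "fuzzymen", "cosen", "entropy_af")`
#'   or `"all"`.
#' @param sampen_m,fuzzymen_m comparator template lengths (default 2).
#' @return data.frame with one row per segment: `segment_id`, `start_beat`,
#'   `n_beats`, `rrmean_s`, one column per measure, `r_used_af`,
#'   `r_used_cosen`, `quality_flag` and `label`. Non-finite entropies stay
#'   non-finite; `quality_flag` collects the per-measure flags.
#' @export
compute_entropies <- function(segments, params = entropy_params(),
                              measures = "all", sampen_m = 2L,
                              fuzzymen_m = 2L) {
  all_measures <- c("sampen", "fuzzymen", "cosen", "entropy_af")
  if (identical(measures, "all")) measures <- all_measures
  measures <- match.arg(measures, all_measures, several.ok = TRUE)
  segments <- lapply(segments, function(s) {
    if (inherits(s, "rr_segment")) s else rr_segment(s)
  })

  one <- function(i) {
    s <- segments[[i]]
    row <- list(segment_id = i, start_beat = s$start_beat,
                n_beats = length(s$intervals), rrmean_s = mean(s$intervals),
                sampen = NA_real_, fuzzymen = NA_real_, cosen = NA_real_,
                entropy_af = NA_real_, r_used_af = NA_real_,
                r_used_cosen = NA_real_, quality_flag = "ok",
                label = s$label)
    flags <- character(0)
    keep <- function(res, name) {
      row[[name]] <<- res$value
      if (res$flag != "ok") flags <<- c(flags, paste0(name, ":", res$flag))
      res
    }
    if ("sampen" %in% measures) keep(sampen(s, m = sampen_m), "sampen")
    if ("fuzzymen" %in% measures) {
      keep(fuzzymen(s, m = fuzzymen_m, n = params$n), "fuzzymen")
    }
    if ("cosen" %in% measures) {
      row$r_used_cosen <- keep(cosen(s, params), "cosen")$r_used
    }
    if ("entropy_af" %in% measures) {
      row$r_used_af <- keep(entropy_af(s, params), "entropy_af")$r_used
    }
    if (length(flags) > 0) row$quality_flag <- paste(flags, collapse = ";")
    as.data.frame(row, stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(seq_along(segments), one))
}
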