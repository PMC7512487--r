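#' Embed an RR series into consecutive template vectors
#'
#' Forms the sequence of `m`-length templates `(x(i), ..., x(i+m-1))` for
#' `i = 1, ..., N - m` (the last admissible template, starting at `N - m + 1`,
#' is deliberately not formed so the template count matches the `m + 1`
#' level used by the entropy definitions).
#'
#' @param x numeric series (an `rr_segment` or a bare vector).
#' @param m template length, `1 <= m < length(x)`.
#' @param n_templates number of templates to form; defaults to
#'   `length(x) - m`. May be at most `length(x) - m + 1`.
#' @return numeric matrix with `n_templates` rows and `m` columns; row `i` is
#'   the template starting at beat `i`.
#' @examples
#' embed_vectors(c(0.8, 0.9, 0.7, 0.8), 2)
#' @export
embed_vectors <- function(x, m, n_templates = NULL) {
  x <- if (inherits(x, "rr_segment")) x$intervals else as.numeric(x)
  n <- length(x)
  m <- as.integer(m)
  if (m < 1L) stop("m must be >= 1")
  if (n <= m) stop("series too short to embed: N = ", n, ", m = ", m)
  if (is.null(n_templates)) n_templates <- n - m
  if (n_templates < 1L || n_templates > n - m + 1L) {
    stop("n_templates must be in [1, N - m + 1]")
  }
  idx <- outer(seq_len(n_templates), 0:(m - 1L), "+")
  matrix(x[idx], nrow = n_templates,
         dimnames = list(NULL, paste0("k", 0:(m - 1L))))
}

#' Ranged (normalized) distance between two template vectors
#'
#' `(max|u_k - v_k| - min|u_k - v_k|) / (max|u_k - v_k| + min|u_k - v_k| + eps)`.
#' Bounded in `[0, 1)`; invariant under a common positive rescaling of both
#' vectors (up to the `epsilon` perturbation) and under adding the same
#' constant to every element, which makes the entropy built on it insensitive
#' to signal gain. For `m = 1` the max and min coincide, so the distance is
#' identically 0 (see the package vignette for the consequences).
#'
#' @param u,v numeric vectors of equal length.
#' @param epsilon small positive guard against a zero denominator.
#' @return distance in `[0, 1)`.
#' @examples
#' ranged_distance(c(1, 2), c(2, 4))  # ~1/3
#' @export
ranged_distance <- function(u, v, epsilon = 1e-10) {
  if (length(u) != length(v)) {
    stop("length mismatch: ", length(u), " vs ", length(v))
  }
  if (epsilon <= 0) stop("epsilon must be > 0")
  a <- abs(u - v)
  (max(a) - min(a)) / (max(a) + min(a) + epsilon)
}

#' Chebyshev distance between two template vectors
#'
#' The element-wise maximum absolute difference, used by the comparator
#' measures (SampEn, FuzzyMEn, COSEn). In seconds when the inputs are RR
#' intervals.
#'
#' @param u,v numeric vectors of equal length.
#' @return `max_k |u_k - v_k| >= 0`, zero iff `u == v`.
#' @export
chebyshev_distance <- function(u, v) {
  if (length(u) != length(v)) {
    stop("length mismatch: ", length(u), " vs ", length(v))
  }
  max(abs(u - v))
}

#' Fuzzy similarity degree
#'
#' Graded membership `exp(-d^n / r)`: 1 for identical templates, smoothly
#' decreasing with distance, approaching a hard 0/1 decision at `d = 1` as
#' `n` grows. Vectorized over `d`.
#'
#' @param d non-negative distance(s).
#' @param n similarity weight (exponent), `> 0`.
#' @param r tolerance, `> 0`.
#' @return similarity in `(0, 1]`.
#' @examples
#' fuzzy_similarity(0.5, n = 2, r = 0.2)  # exp(-1.25)
#' @export
fuzzy_similarity <- function(d, n, r) {
  if (r <= 0) stop("tolerance r must be > 0")
  if (n <= 0) stop("similarity weight n must be > 0")
  if (any(d < 0)) stop("distances must be non-negative")
  exp(-(d^n) / r)
}

# All pairwise distances between templates at dimension `dim`, as a symmetric
# n_templates x n_templates matrix. Computed column-by-column over the
# template coordinates so segments of typical window length stay in fast
# vectorized code.
pairwise_distances <- function(x, dim, kind = c("ranged", "chebyshev"),
                               epsilon = 1e-10, n_templates = NULL) {
  kind <- match.arg(kind)
  tm <- embed_vectors(x, dim, n_templates)
  nt <- nrow(tm)
  mx <- matrix(0, nt, nt)
  if (kind == "chebyshev") {
    for (k in seq_len(ncol(tm))) {
      mx <- pmax(mx, abs(outer(tm[, k], tm[, k], "-")))
    }
    return(mx)
  }
  mn <- matrix(Inf, nt, nt)
  for (k in seq_len(ncol(tm))) {
    a <- abs(outer(tm[, k], tm[, k], "-"))
    mx <- pmax(mx, a)
    mn <- pmin(mn, a)
  }
  (mx - mn) / (mx + mn + epsilon)
}
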