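# Brute-force reference implementations, written straight from the
# definitions with explicit loops. They stay independent of the package's
# vectorized code paths.

oracle_ranged <- function(u, v, eps = 1e-10) {
  a <- abs(u - v)
  (max(a) - min(a)) / (max(a) + min(a) + eps)
}

oracle_chebyshev <- function(u, v) max(abs(u - v))

# mean similarity by double loop; self pairs included unless excluded
oracle_mean_similarity <- function(x, dim, n, r, kind, fuzzy, exclude_self,
                                   nt, eps = 1e-10) {
  total <- 0
  count <- 0
  for (i in seq_len(nt)) {
    for (j in seq_len(nt)) {
      if (exclude_self && i == j) next
      u <- x[i:(i + dim - 1)]
      v <- x[j:(j + dim - 1)]
      d <- if (kind == "ranged") oracle_ranged(u, v, eps) else
        oracle_chebyshev(u, v)
      s <- if (fuzzy) exp(-(d^n) / r) else as.numeric(d <= r)
      total <- total + s
      count <- count + 1
    }
  }
  total / count
}

# SampEn by direct template counting (Chebyshev, hard threshold, no self
# matches, N - m templates at both lengths)
oracle_sampen <- function(x, m, r) {
  nt <- length(x) - m
  A <- 0
  B <- 0
  for (i in seq_len(nt)) {
    for (j in seq_len(nt)) {
      if (i == j) next
      dm <- 0
      for (k in 0:(m - 1)) dm <- max(dm, abs(x[i + k] - x[j + k]))
      if (dm <= r) B <- B + 1
      dm1 <- max(dm, abs(x[i + m] - x[j + m]))
      if (dm1 <= r) A <- A + 1
    }
  }
  -log(A / B)
}

# FuzzyMEn from the definition: local (template-mean removed) plus global
# (series-mean removed) fuzzy terms, Chebyshev distance, no self matches
oracle_fuzzymen <- function(x, m, n, r) {
  nt <- length(x) - m
  term <- function(dim, center) {
    total <- 0
    count <- 0
    for (i in seq_len(nt)) {
      for (j in seq_len(nt)) {
        if (i == j) next
        u <- x[i:(i + dim - 1)]
        v <- x[j:(j + dim - 1)]
        if (center == "local") {
          u <- u - mean(u)
          v <- v - mean(v)
        } else {
          u <- u - mean(x)
          v <- v - mean(x)
        }
        total <- total + exp(-(oracle_chebyshev(u, v)^n) / r)
        count <- count + 1
      }
    }
    total / count
  }
  -log(term(m + 1, "local") / term(m, "local")) -
    log(term(m + 1, "global") / term(m, "global"))
}

# Exhaustive scan of the flexible tolerance grid: smallest grid r whose
# average matches per template at dimension m + 1 reach the quota
oracle_r_scan <- function(x, params, kind, fuzzy, exclude_self, r_max) {
  m <- params$m
  nt <- length(x) - m
  avg_matches <- function(r) {
    per_template <- numeric(nt)
    for (i in seq_len(nt)) {
      s <- 0
      for (j in seq_len(nt)) {
        if (exclude_self && i == j) next
        u <- x[i:(i + m)]
        v <- x[j:(j + m)]
        d <- if (kind == "ranged") oracle_ranged(u, v, params$epsilon) else
          oracle_chebyshev(u, v)
        s <- s + if (fuzzy) exp(-(d^params$n) / r) else as.numeric(d <= r)
      }
      per_template[i] <- s
    }
    mean(per_template)
  }
  r <- params$r_init
  repeat {
    if (avg_matches(r) >= params$min_avg_matches || r >= r_max) return(r)
    r <- min(r + params$r_step, r_max)
  }
}

# confusion counts by per-point classification
oracle_confusion <- function(scores, y, cut, high_is_af = TRUE) {
  tp <- tn <- fp <- fn <- 0
  for (i in seq_along(scores)) {
    pred <- if (high_is_af) scores[i] >= cut else scores[i] <= cut
    if (pred && y[i]) tp <- tp + 1
    if (pred && !y[i]) fp <- fp + 1
    if (!pred && y[i]) fn <- fn + 1
    if (!pred && !y[i]) tn <- tn + 1
  }
  list(tp = tp, tn = tn, fp = fp, fn = fn)
}

# Mann-Whitney AUC by exhaustive pair counting (ties score 1/2)
oracle_auc_pairs <- function(scores, y) {
  pos <- scores[y]
  neg <- scores[!y]
  s <- 0
  for (a in pos) {
    for (b in neg) {
      s <- s + if (a > b) 1 else if (a == b) 0.5 else 0
    }
  }
  s / (length(pos) * length(neg))
}

# short plausible RR segment for randomized checks
rand_rr <- function(n) stats::runif(n, 0.4, 1.2)
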