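test_that("mean similarity matches hand-computed and brute-force values", {
  # degenerate constant series: every distance 0, every similarity 1
  const <- rep(0.8, 10)
  expect_equal(mean_similarity(const, 2, n = 2, r = 0.1), 1)
  expect_equal(mean_similarity(const, 2, n = 2, r = 0.1,
                               distance = "chebyshev",
                               similarity = "heaviside",
                               exclude_self = TRUE), 1)

  # 3-point, m = 1 instance: two dim-2 templates (1,2) and (2,4) at ranged
  # distance ~1/3, one self-pair each; n = 1, r = 0.3
  x <- c(1, 2, 4)
  d <- (2 - 1) / (2 + 1 + 1e-10)
  expect_equal(
    mean_similarity(x, 2, n = 1, r = 0.3, n_templates = 2),
    (2 * 1 + 2 * exp(-d / 0.3)) / 4
  )

  set.seed(42)
  for (i in 1:20) {
    x <- rand_rr(sample(8:15, 1))
    nt <- length(x) - 2
    expect_equal(
      mean_similarity(x, 3, n = 2, r = 0.25, n_templates = nt),
      oracle_mean_similarity(x, 3, 2, 0.25, "ranged", TRUE, FALSE, nt)
    )
    expect_equal(
      mean_similarity(x, 2, r = 0.05, distance = "chebyshev",
                      similarity = "heaviside", exclude_self = TRUE,
                      n_templates = nt),
      oracle_mean_similarity(x, 2, 2, 0.05, "chebyshev", FALSE, TRUE, nt)
    )
  }
})

test_that("Heaviside match fraction cannot grow with template length", {
  set.seed(13)
  for (i in 1:50) {
    x <- rand_rr(sample(10:20, 1))
    m <- sample(1:3, 1)
    nt <- length(x) - m - 1
    bm <- mean_similarity(x, m, r = 0.05, distance = "chebyshev",
                          similarity = "heaviside", exclude_self = TRUE,
                          n_templates = nt)
    am <- mean_similarity(x, m + 1, r = 0.05, distance = "chebyshev",
                          similarity = "heaviside", exclude_self = TRUE,
                          n_templates = nt)
    expect_lte(am, bm)
  }
})

test_that("flexible tolerance search terminates per its definition", {
  const <- rep(0.7, 30)
  expect_equal(flexible_r_search(const)$r, 0.05)

  # quota met at the first grid point
  set.seed(2)
  x <- synth_nsr_rr(30, seed = 2)
  s <- flexible_r_search(x, entropy_params(min_avg_matches = 1))
  expect_equal(s$r, 0.05)
  expect_true(s$met)

  # quota never met: capped at r_max and flagged
  s2 <- flexible_r_search(rand_rr(30),
                          entropy_params(min_avg_matches = 1e6))
  expect_equal(s2$r, 1)
  expect_false(s2$met)
})

test_that("flexible tolerance search equals the exhaustive grid scan", {
  set.seed(314)
  for (i in 1:12) {
    x <- rand_rr(30)
    p <- entropy_params()
    expect_equal(flexible_r_search(x, p)$r,
                 oracle_r_scan(x, p, "ranged", TRUE, FALSE, r_max = 1))
    pc <- entropy_params(r_step = 0.02)
    got <- flexible_r_search(x, pc, distance = "chebyshev",
                             similarity = "heaviside")
    # oracle r_max: max pairwise chebyshev distance at dim m + 1
    nt <- length(x) - pc$m
    dmax <- 0
    for (a in seq_len(nt)) for (b in seq_len(nt)) {
      dmax <- max(dmax, oracle_chebyshev(x[a:(a + 1)], x[b:(b + 1)]))
    }
    expect_equal(got$r,
                 oracle_r_scan(x, pc, "chebyshev", FALSE, TRUE,
                               r_max = max(dmax, pc$r_init)))
  }
})

test_that("sampen agrees with template counting and its limit cases", {
  # strictly periodic alternating series
  x <- rep(c(0.8, 1.0), 15)
  expect_equal(sampen(x, m = 2, r = 0.05)$value, oracle_sampen(x, 2, 0.05))

  expect_equal(sampen(rep(0.8, 20), m = 2, r = 0.05)$value, 0)
  expect_equal(sampen(rand_rr(30), m = 2, r = 1e6)$value, 0)

  # zero matches at the longer length: non-finite, flagged, not coerced
  set.seed(9)
  y <- synth_af_rr(20, seed = 9)
  res <- sampen(y, m = 3, r = 0.001)
  expect_false(is.finite(res$value))
  expect_true(res$flag %in% c("a_zero", "b_zero"))

  expect_error(sampen(c(0.8, 0.9, 1.0), m = 2), "too short")
})

test_that("fuzzymen matches its from-the-definition oracle", {
  expect_equal(fuzzymen(rep(0.9, 25))$value, 0)
  x <- synth_af_rr(30, seed = 77)
  expect_equal(fuzzymen(x, m = 2, n = 2)$value,
               oracle_fuzzymen(as.numeric(x), 2, 2, 0.2 * sd(x)))
})

test_that("fuzzymen increases with dispersion of iid segments", {
  set.seed(55)
  med <- vapply(c(0.01, 0.05, 0.15), function(sigma) {
    vals <- vapply(1:200, function(i) {
      fuzzymen(pmax(rnorm(30, 0.8, sigma), 0.05))$value
    }, numeric(1))
    median(vals[is.finite(vals)])
  }, numeric(1))
  expect_true(all(diff(med) > 0))
})

test_that("cosen decomposes into sampen + log(2r) - log(RRmean)", {
  x <- synth_af_rr(30, seed = 21)
  p <- entropy_params(m = 1)
  step <- max(0.01 * sd(x), 1e-4)
  s <- flexible_r_search(x, entropy_params(m = 1, r_step = step),
                         distance = "chebyshev", similarity = "heaviside")
  expect_equal(cosen(x, p)$value,
               sampen(x, m = 1, r = s$r)$value + log(2 * s$r) - log(mean(x)))

  # constant segment: sampen term 0
  const <- rep(0.8, 30)
  expect_equal(cosen(const)$value, log(2 * 0.05) - log(0.8))

  # rescaling changes the value through both log(RRmean) and the re-searched
  # tolerance; the decomposition must hold at each scale
  x2 <- 2 * x
  s2 <- flexible_r_search(x2, entropy_params(m = 1,
                                             r_step = max(0.01 * sd(x2), 1e-4)),
                          distance = "chebyshev", similarity = "heaviside")
  expect_equal(cosen(x2, p)$value,
               sampen(x2, m = 1, r = s2$r)$value + log(2 * s2$r) -
                 log(mean(x2)))
})

test_that("the heart-rate term vanishes when RRmean is 1 s with w = 1", {
  set.seed(4)
  x <- 1 + c(scale(rand_rr(30))) * 0.1  # mean exactly 1
  x <- x / mean(x)
  res <- entropy_af(x)
  expect_equal(res$value, -log(res$a_m1 / res$b_m) + log(2 * res$r_used))
})

test_that("scaling a segment shifts the detector by exactly -w log(c)", {
  set.seed(6)
  for (w in c(0.5, 1, 1.7)) {
    x <- synth_af_rr(30)
    v0 <- entropy_af(x, entropy_params(w = w))$value
    for (cc in c(0.5, 2, 10)) {
      vc <- entropy_af(cc * as.numeric(x), entropy_params(w = w))$value
      expect_equal(vc - v0, -w * log(cc), tolerance = 1e-6)
    }
  }
})

test_that("w tuning returns the grid maximizer of the training AUC", {
  ds <- synth_dataset(40, 40, window = 30, seed = 99)
  tw <- tune_w(ds, w_grid = seq(0, 2, by = 0.5))
  expect_equal(tw$auc, max(tw$table$auc))
  expect_equal(tw$w, tw$table$w[which.max(tw$table$auc)])
  labels <- vapply(ds, function(s) s$label, character(1))
  p0 <- entropy_params(w = 0)
  part <- vapply(ds, function(s) entropy_af(s, p0)$value, numeric(1))
  hr <- vapply(ds, function(s) -log(mean(s$intervals)), numeric(1))
  expect_equal(tw$auc, auc_mw(part + tw$w * hr, labels))
})

test_that("compute_entropies reports all measures with diagnostics", {
  ds <- synth_dataset(3, 3, window = 30, seed = 8)
  tab <- compute_entropies(ds)
  expect_equal(nrow(tab), 6)
  expect_named(tab, c("segment_id", "start_beat", "n_beats", "rrmean_s",
                      "sampen", "fuzzymen", "cosen", "entropy_af",
                      "r_used_af", "r_used_cosen", "quality_flag", "label"))
  expect_true(all(is.finite(tab$entropy_af)))
  expect_true(all(tab$r_used_af >= 0.05))
  # non-finite comparator values surface in the quality flag, not as zeros
  inf_rows <- !is.finite(tab$sampen)
  if (any(inf_rows)) {
    expect_true(all(grepl("sampen:", tab$quality_flag[inf_rows])))
  }
  sub <- compute_entropies(ds[1:2], measures = "entropy_af")
  expect_true(all(is.na(sub$sampen)))
})
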