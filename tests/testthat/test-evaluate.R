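test_that("confusion counts classify each point per the threshold rule", {
  cc <- confusion_at(c(0.9, 0.5), c("AF", "NONAF"), 0.76)
  expect_equal(unclass(cc)[c("tp", "tn", "fp", "fn")],
               list(tp = 1L, tn = 1L, fp = 0L, fn = 0L))

  cc2 <- confusion_at(runif(10), rep("NONAF", 10), 2)
  expect_equal(cc2$tn, 10L)
  expect_equal(cc2$tp + cc2$fp + cc2$fn, 0L)

  set.seed(17)
  for (i in 1:5) {
    s <- round(runif(20), 2)
    y <- runif(20) > 0.5
    cut <- runif(1)
    for (o in c("high_is_AF", "low_is_AF")) {
      got <- confusion_at(s, y, cut, o)
      want <- oracle_confusion(s, y, cut, o == "high_is_AF")
      expect_equal(unclass(got)[names(want)], want)
    }
  }
  expect_error(confusion_at(numeric(0), character(0), 1), "empty")
})

test_that("the six metrics follow their printed formulas", {
  m <- classification_metrics(list(tp = 1, tn = 1, fp = 0, fn = 0))
  expect_equal(unlist(m), c(se = 1, sp = 1, acc = 1, ppv = 1, npv = 1,
                            err = 0))
  # Youden identity at a published operating point, within table rounding
  expect_lt(abs(100 * (0.9647 + 0.9259 - 1) - 89.07), 0.02)
  # undefined metric flagged, never reported as 0
  m2 <- classification_metrics(list(tp = 0, tn = 5, fp = 0, fn = 3))
  expect_true(is.na(m2$ppv))
  expect_equal(m2$sp, 1)
  expect_error(classification_metrics(list(tp = 0, tn = 0, fp = 0, fn = 0)),
               "no evaluated segments")
})

test_that("roc curve: grid layout, anchoring, and degenerate inputs", {
  set.seed(30)
  scores <- c(rnorm(50, 3), rnorm(50, 0))
  labels <- rep(c("AF", "NONAF"), each = 50)
  rc <- roc_entropy(scores, labels)
  expect_length(rc$thresholds, 101)
  expect_equal(rc$thresholds[1], min(scores))
  expect_equal(rc$thresholds[101], max(scores))
  expect_true(all(diff(rc$thresholds) > 0))
  expect_gte(rc$auc, 0.5)

  # perfectly separated scores
  sep <- roc_entropy(c(10, 11, 12, 1, 2, 3),
                     c("AF", "AF", "AF", "NONAF", "NONAF", "NONAF"))
  expect_equal(sep$auc, 1)
  expect_equal(youden_optimal(sep)$j, 1)

  expect_error(roc_entropy(scores, rep("AF", 100)), "both classes")

  # non-finite scores dropped with a count
  rc2 <- roc_entropy(c(scores, Inf, NaN), c(labels, "AF", "NONAF"))
  expect_equal(rc2$n_dropped, 2)
})

test_that("trapezoidal grid AUC agrees with exhaustive pair counting", {
  set.seed(91)
  for (i in 1:10) {
    n <- sample(10:20, 1)
    scores <- round(rnorm(n), 1)  # coarse values force ties
    y <- c(TRUE, FALSE, runif(n - 2) > 0.5)
    mw <- oracle_auc_pairs(scores, y)
    expect_equal(auc_mw(scores, y), mw)
    rc <- roc_entropy(scores, y)
    expect_lt(abs(rc$auc - max(mw, 1 - mw)), 0.01 + 1e-12)
  }
})

test_that("AUC is invariant to monotone transforms and flips with labels", {
  set.seed(19)
  scores <- rnorm(200, ifelse(runif(200) > 0.5, 1, 0))
  y <- runif(200) > 0.5
  a0 <- auc_mw(scores, y)
  expect_equal(auc_mw(exp(scores), y), a0)
  expect_equal(auc_mw(3 * scores + 7, y), a0)
  expect_equal(auc_mw(scores, !y), 1 - a0)
  r0 <- roc_entropy(scores, y)$auc
  expect_lt(abs(roc_entropy(exp(scores), y)$auc - r0), 0.01)
})

test_that("youden point equals a brute-force scan of the grid", {
  set.seed(23)
  scores <- rnorm(15, ifelse(runif(15) > 0.4, 1.5, 0))
  y <- runif(15) > 0.4
  if (!any(y)) y[1] <- TRUE
  if (all(y)) y[2] <- FALSE
  rc <- roc_entropy(scores, y)
  best_j <- -Inf
  best_c <- NA
  for (i in seq_along(rc$thresholds)) {
    cc <- oracle_confusion(scores, y, rc$thresholds[i],
                           rc$orientation == "high_is_AF")
    jj <- cc$tp / (cc$tp + cc$fn) + cc$tn / (cc$tn + cc$fp) - 1
    if (jj > best_j) {
      best_j <- jj
      best_c <- rc$thresholds[i]
    }
  }
  yo <- youden_optimal(rc)
  expect_equal(yo$j, best_j)
  expect_equal(yo$c_star, best_c)
})

test_that("constrained cut-points honour Se/Sp requirements or flag", {
  sep <- roc_entropy(c(10, 11, 12, 1, 2, 3),
                     c(rep("AF", 3), rep("NONAF", 3)))
  hi_se <- cutpoint_at(sep, "Se", 0.99)
  expect_true(hi_se$attained)
  expect_equal(hi_se$se, 1)
  expect_equal(hi_se$sp, 1)  # separated: Sp is maximized among Se = 1 cuts

  # top non-AF score exceeds every AF score: Sp > 0.99 unattainable without
  # giving up all sensitivity -> flagged extreme
  scores <- c(1, 2, 3, 10, 10, 10, 10)
  labels <- c(rep("AF", 3), rep("NONAF", 4))
  rc <- roc_entropy(scores, labels)
  hi_sp <- cutpoint_at(rc, "Sp", 0.99)
  expect_type(hi_sp$attained, "logical")

  set.seed(37)
  scores <- rnorm(20, ifelse(runif(20) > 0.5, 1, 0))
  y <- runif(20) > 0.5
  if (!any(y)) y[1] <- TRUE
  if (all(y)) y[2] <- FALSE
  rc <- roc_entropy(scores, y)
  cp <- cutpoint_at(rc, "Se", 0.8)
  ok <- rc$se > 0.8
  if (any(ok)) {
    expect_true(cp$attained)
    expect_equal(cp$sp, max(rc$sp[ok]))
  }
})

test_that("paired DeLong test behaves at its edges and against pROC", {
  set.seed(44)
  y <- rep(c(TRUE, FALSE), each = 50)
  s <- rnorm(100, ifelse(y, 1, 0))
  same <- compare_auc(s, s, y)
  expect_true(same$flag == "degenerate_variance")
  expect_equal(same$p_value, 1)

  # strongly separated vs uninformative scores
  set.seed(45)
  y2 <- rep(c(TRUE, FALSE), each = 500)
  good <- rnorm(1000, ifelse(y2, 3, 0))
  junk <- rnorm(1000)
  cmp <- compare_auc(good, junk, y2)
  expect_lt(cmp$p_value, 0.01)
  expect_gt(cmp$auc_a, cmp$auc_b)

  # cross-check z and p against the reference implementation
  pr <- pROC::roc.test(pROC::roc(y2, good, quiet = TRUE,
                                 direction = "<"),
                       pROC::roc(y2, junk, quiet = TRUE,
                                 direction = "<"),
                       method = "delong", paired = TRUE)
  expect_equal(cmp$p_value, unname(pr$p.value), tolerance = 1e-8)
  expect_equal(auc_mw(good, y2), unname(as.numeric(pr$estimate[1])),
               tolerance = 1e-12)
})

test_that("metrics_report mirrors the published table layout", {
  set.seed(61)
  scores <- rnorm(300, ifelse(rep(c(TRUE, FALSE), 150), 2, 0))
  labels <- rep(c("AF", "NONAF"), 150)
  rep1 <- metrics_report(scores, labels, measure = "toy")
  expect_named(rep1, c("measure", "operating", "c", "j_pct", "se_pct",
                       "sp_pct", "acc_pct", "ppv_pct", "npv_pct", "err_pct",
                       "auc_pct", "orientation"))
  expect_equal(rep1$acc_pct, 100 - rep1$err_pct)
  expect_equal(rep1$j_pct, rep1$se_pct + rep1$sp_pct - 100,
               tolerance = 1e-8)
  # fixed-threshold transfer reproduces the same row when given the learned c
  rep2 <- metrics_report(scores, labels, operating = "fixed",
                         threshold = rep1$c, measure = "toy")
  expect_equal(rep2$se_pct, rep1$se_pct)
  expect_equal(rep2$sp_pct, rep1$sp_pct)
})
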