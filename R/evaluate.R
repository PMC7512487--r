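label_is_positive <- function(labels, positive = "AF") {
  if (is.logical(labels)) return(labels)
  as.character(labels) == positive
}

#' Confusion counts at one decision threshold
#'
#' With orientation `"high_is_AF"`, a segment is predicted AF when its score
#' is `>= threshold`; with `"low_is_AF"`, when it is `<= threshold`.
#'
#' @param scores finite numeric scores (entropy values); drop non-finite
#'   values upstream.
#' @param labels class labels; `positive` marks the AF class. Logical vectors
#'   are taken as already-binarized (TRUE = AF).
#' @param threshold decision cut-point `c`.
#' @param orientation `"high_is_AF"` or `"low_is_AF"`.
#' @param positive label string treated as AF.
#' @return object of class `confusion_counts`: list with `tp`, `tn`, `fp`,
#'   `fn`; the four counts partition the data.
#' @examples
#' confusion_at(c(0.9, 0.5), c("AF", "NONAF"), 0.76)
#' @export
confusion_at <- function(scores, labels, threshold,
                         orientation = c("high_is_AF", "low_is_AF"),
                         positive = "AF") {
  orientation <- match.arg(orientation)
  if (length(scores) == 0L) stop("empty input")
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  if (!all(is.finite(scores))) stop("scores must be finite (drop upstream)")
  y <- label_is_positive(labels, positive)
  pred <- if (orientation == "high_is_AF") scores >= threshold else
    scores <= threshold
  structure(
    list(tp = sum(pred & y), tn = sum(!pred & !y),
         fp = sum(pred & !y), fn = sum(!pred & y)),
    class = "confusion_counts"
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d TN=%d FP=%d FN=%d\n",
              x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

#' The six classifier performance metrics
#'
#' Se = TP/(TP+FN), Sp = TN/(TN+FP), Acc = (TP+TN)/total,
#' PPV = TP/(TP+FP), NPV = TN/(TN+FN), Err = (FP+FN)/total.
#' A metric whose denominator is zero is reported as `NA` (undefined), never
#' as 0.
#'
#' @param counts a `confusion_counts` object (or list with tp/tn/fp/fn).
#' @return named list of the six metrics as fractions.
#' @export
classification_metrics <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  total <- tp + tn + fp + fn
  if (total == 0) stop("no evaluated segments")
  frac <- function(num, den) if (den == 0) NA_real_ else num / den
  list(
    se = frac(tp, tp + fn),
    sp = frac(tn, tn + fp),
    acc = (tp + tn) / total,
    ppv = frac(tp, tp + fp),
    npv = frac(tn, tn + fn),
    err = (fp + fn) / total
  )
}

#' Exact Mann-Whitney AUC
#'
#' Probability that a random AF score ranks above a random non-AF score
#' (ties count 1/2), computed from rank sums. Used as the grid-free AUC and
#' as the cross-check for the trapezoidal ROC integration.
#'
#' @inheritParams confusion_at
#' @return AUC in `[0, 1]` for the "high scores are AF" orientation.
#' @export
auc_mw <- function(scores, labels, positive = "AF") {
  y <- label_is_positive(labels, positive)
  ok <- is.finite(scores)
  scores <- scores[ok]; y <- y[ok]
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve on the 1%-of-range threshold grid
#'
#' Thresholds run from the minimum to the maximum score in steps of 1% of
#' the range (101 points). Se and Sp are computed at every threshold; the
#' AUC is the trapezoidal area over `(1 - Sp, Se)` with the curve anchored
#' at (0,0) and (1,1). The orientation (whether high or low scores indicate
#' AF) is chosen so the AUC is at least 0.5 and is recorded. Non-finite
#' scores are dropped with a count.
#'
#' @inheritParams confusion_at
#' @return object of class `af_roc`: list with `thresholds`, `se`, `sp`,
#'   `auc`, `orientation`, `n_pos`, `n_neg`, `n_dropped`.
#' @export
roc_entropy <- function(scores, labels, positive = "AF") {
  y <- label_is_positive(labels, positive)
  ok <- is.finite(scores)
  n_dropped <- sum(!ok)
  scores <- scores[ok]; y <- y[ok]
  if (!any(y) || all(y)) stop("both classes must be present")
  lo <- min(scores); hi <- max(scores)
  if (lo == hi) stop("degenerate scores: zero range")
  thresholds <- seq(lo, hi, length.out = 101L)

  curve_for <- function(orientation) {
    se <- numeric(101L); sp <- numeric(101L)
    for (i in seq_len(101L)) {
      cc <- confusion_at(scores, y, thresholds[i], orientation)
      mm <- classification_metrics(cc)
      se[i] <- mm$se; sp[i] <- mm$sp
    }
    x <- c(0, 1 - sp, 1); yy <- c(0, se, 1)
    ord <- order(x, yy)
    x <- x[ord]; yy <- yy[ord]
    auc <- sum(diff(x) * (utils::head(yy, -1) + utils::tail(yy, -1)) / 2)
    list(se = se, sp = sp, auc = auc, orientation = orientation)
  }

  cv <- curve_for("high_is_AF")
  if (cv$auc < 0.5) cv <- curve_for("low_is_AF")
  structure(
    list(thresholds = thresholds, se = cv$se, sp = cv$sp, auc = cv$auc,
         orientation = cv$orientation, n_pos = sum(y), n_neg = sum(!y),
         n_dropped = n_dropped),
    class = "af_roc"
  )
}

#' @export
print.af_roc <- function(x, ...) {
  cat(sprintf(
    "<af_roc> AUC = %.4f (%s; %d AF vs %d non-AF, %d non-finite dropped)\n",
    x$auc, x$orientation, x$n_pos, x$n_neg, x$n_dropped))
  invisible(x)
}

#' @export
plot.af_roc <- function(x, ...) {
  graphics::plot(c(0, 1 - x$sp, 1), c(0, x$se, 1), type = "l",
                 xlab = "1 - Sp", ylab = "Se",
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Youden-optimal operating point
#'
#' The grid threshold maximizing `J = Se + Sp - 1`; ties break toward the
#' smaller threshold.
#'
#' @param curve an `af_roc` object.
#' @return list with `c_star`, `j`, `se`, `sp` and the grid `index`.
#' @export
youden_optimal <- function(curve) {
  j <- curve$se + curve$sp - 1
  idx <- which.max(j)  # which.max takes the first (smallest threshold) tie
  list(c_star = curve$thresholds[idx], j = j[idx],
       se = curve$se[idx], sp = curve$sp[idx], index = idx)
}

#' Constrained operating point (rule-out / rule-in)
#'
#' Among grid thresholds satisfying `Se > level` (or `Sp > level`), returns
#' the one maximizing the other metric. If the constraint is unattainable on
#' the grid, the threshold coming closest to it is returned with
#' `attained = FALSE`.
#'
#' @param curve an `af_roc` object.
#' @param constraint `"Se"` or `"Sp"`.
#' @param level required level, in (0, 1); the study uses 0.99.
#' @return list with `threshold`, `se`, `sp`, `attained` and `index`.
#' @export
cutpoint_at <- function(curve, constraint = c("Se", "Sp"), level = 0.99) {
  constraint <- match.arg(constraint)
  stopifnot(level > 0, level < 1)
  primary <- if (constraint == "Se") curve$se else curve$sp
  secondary <- if (constraint == "Se") curve$sp else curve$se
  ok <- primary > level
  if (any(ok)) {
    cand <- which(ok)
    idx <- cand[which.max(secondary[cand])]
    attained <- TRUE
  } else {
    best <- which(primary == max(primary))
    idx <- best[which.max(secondary[best])]
    attained <- FALSE
  }
  list(threshold = curve$thresholds[idx], se = curve$se[idx],
       sp = curve$sp[idx], attained = attained, index = idx)
}

# DeLong placement components for one score vector: AUC, per-positive and
# per-negative placements (probability of correct ordering against the other
# class).
delong_placements <- function(scores, y) {
  x1 <- scores[y]; x0 <- scores[!y]
  n1 <- length(x1); n0 <- length(x0)
  # psi(x1_i, x0_j) = 1, 1/2, 0 for >, =, < ; computed via joint ranking
  r_all <- rank(c(x1, x0))
  r1 <- rank(x1); r0 <- rank(x0)
  v10 <- (r_all[seq_len(n1)] - r1) / n0            # mean_j psi per positive
  v01 <- 1 - (r_all[n1 + seq_len(n0)] - r0) / n1   # mean_i psi per negative
  list(auc = mean(v10), v10 = v10, v01 = v01)
}

#' Paired DeLong test comparing two AUCs
#'
#' Two-sided DeLong test for the difference between the AUCs of two score
#' vectors computed on the same segments (paired design). Scores are
#' compared as given ("high is AF" orientation); orient upstream if needed.
#'
#' @param scores_a,scores_b paired score vectors.
#' @inheritParams confusion_at
#' @return list with `p_value`, `auc_a`, `auc_b`, `z` and `flag`
#'   (`"ok"` or `"degenerate_variance"`, in which case `p_value` is 1 when
#'   the AUCs are equal and `NA` otherwise).
#' @export
compare_auc <- function(scores_a, scores_b, labels, positive = "AF") {
  if (length(scores_a) != length(scores_b)) {
    stop("paired scores must have equal length")
  }
  y <- label_is_positive(labels, positive)
  ok <- is.finite(scores_a) & is.finite(scores_b)
  scores_a <- scores_a[ok]; scores_b <- scores_b[ok]; y <- y[ok]
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 < 2L || n0 < 2L) stop("need at least 2 segments per class")
  pa <- delong_placements(scores_a, y)
  pb <- delong_placements(scores_b, y)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  if (!is.finite(var_diff) || var_diff <= .Machine$double.eps) {
    p <- if (pa$auc == pb$auc) 1 else NA_real_
    return(list(p_value = p, auc_a = pa$auc, auc_b = pb$auc, z = NA_real_,
                flag = "degenerate_variance"))
  }
  z <- (pa$auc - pb$auc) / sqrt(var_diff)
  list(p_value = 2 * stats::pnorm(-abs(z)), auc_a = pa$auc, auc_b = pb$auc,
       z = z, flag = "ok")
}

#' Operating-point report in the published table layout
#'
#' Evaluates one score vector at a threshold (Youden-optimal by default, or
#' a constrained or externally supplied cut-point) and reports `c`, `J` and
#' the six metrics as percentages, mirroring the layout used for clinical
#' AF-detector comparisons.
#'
#' @inheritParams confusion_at
#' @param operating `"youden"`, `"se99"`, `"sp99"`, or `"fixed"` (then
#'   `threshold` must be given — the transfer protocol where a cut-point
#'   learned on one dataset is applied unchanged to another).
#' @param threshold cut-point for `operating = "fixed"`.
#' @param measure name echoed in the output row.
#' @return one-row data.frame: `measure`, `operating`, `c`, `j_pct`,
#'   `se_pct`, `sp_pct`, `acc_pct`, `ppv_pct`, `npv_pct`, `err_pct`,
#'   `auc_pct`, `orientation`.
#' @export
metrics_report <- function(scores, labels,
                           operating = c("youden", "se99", "sp99", "fixed"),
                           threshold = NULL, positive = "AF",
                           measure = "entropy") {
  operating <- match.arg(operating)
  curve <- roc_entropy(scores, labels, positive)
  cut <- switch(operating,
    youden = youden_optimal(curve)$c_star,
    se99 = cutpoint_at(curve, "Se", 0.99)$threshold,
    sp99 = cutpoint_at(curve, "Sp", 0.99)$threshold,
    fixed = {
      if (is.null(threshold)) stop("operating = 'fixed' needs a threshold")
      threshold
    })
  ok <- is.finite(scores)
  cc <- confusion_at(scores[ok], labels[ok], cut, curve$orientation, positive)
  mm <- classification_metrics(cc)
  pct <- function(v) round(100 * v, 2)
  data.frame(
    measure = measure, operating = operating, c = cut,
    j_pct = pct(mm$se + mm$sp - 1), se_pct = pct(mm$se), sp_pct = pct(mm$sp),
    acc_pct = pct(mm$acc), ppv_pct = pct(mm$ppv), npv_pct = pct(mm$npv),
    err_pct = pct(mm$err), auc_pct = pct(curve$auc),
    orientation = curve$orientation, stringsAsFactors = FALSE
  )
}
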