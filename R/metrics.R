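# Diagnostic-accuracy metrics and the clinical utility. The utility that the
# optimizer maximizes is the mean of the trapezoidal area under the
# precision-recall curve and the average precision: both emphasize the
# positive predictive value, which proxies the precision of transplant
# referral decisions at ~9% event prevalence where AUC-ROC is deceptively
# high.

check_scored <- function(y, s, need_pos = TRUE, need_both = FALSE) {
  stopifnot(length(y) == length(s), length(y) >= 2)
  if (!all(y %in% c(0, 1))) pp_stop("pp_bad_labels", "labels must be 0/1")
  if (any(!is.finite(s))) pp_stop("pp_bad_scores", "scores must be finite")
  if (need_pos && sum(y == 1) == 0)
    pp_stop("pp_no_positives", "undefined recall: no positive labels")
  if (need_both && (sum(y == 1) == 0 || sum(y == 0) == 0))
    pp_stop("pp_single_class", "metric needs both classes present")
  invisible(TRUE)
}

#' Precision-recall curve
#'
#' One `(recall, precision)` point per distinct score threshold, thresholds
#' descending; a row is predicted positive when its score is at or above the
#' threshold. Tied scores are grouped into a single threshold.
#'
#' @param y binary labels (0/1).
#' @param s risk scores.
#' @return data frame with `threshold`, `recall`, `precision`.
#' @export
pr_curve <- function(y, s) {
  check_scored(y, s)
  thr <- sort(unique(s), decreasing = TRUE)
  P <- sum(y == 1)
  o <- order(s, decreasing = TRUE)
  ys <- y[o]; ss <- s[o]
  # cumulative TP/FP at each distinct threshold (ties grouped)
  grp <- cumsum(!duplicated(ss))
  tp_cum <- cumsum(ys); n_cum <- seq_along(ys)
  last <- which(!duplicated(grp, fromLast = TRUE))
  data.frame(threshold = thr,
             recall = tp_cum[last] / P,
             precision = tp_cum[last] / n_cum[last])
}

#' Area under the precision-recall curve (trapezoidal)
#'
#' The curve is reduced to the maximum precision at each distinct recall and
#' anchored at `(recall = 0, precision = first point's precision)` before
#' trapezoidal integration over recall, making the integral well-defined and
#' monotone in the curve.
#'
#' @inheritParams pr_curve
#' @return scalar in `[0, 1]`.
#' @export
auc_pr <- function(y, s) {
  pc <- pr_curve(y, s)
  pmax_by_recall <- tapply(pc$precision, pc$recall, max)
  r <- as.numeric(names(pmax_by_recall))
  p <- as.numeric(pmax_by_recall)
  o <- order(r)
  r <- c(0, r[o]); p <- c(pc$precision[1], p[o])
  sum(diff(r) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
}

#' Average precision
#'
#' Recall-increment-weighted mean of precisions over the non-interpolated
#' curve: `sum_k (R_k - R_{k-1}) * P_k` with thresholds descending and
#' `R_0 = 0`.
#'
#' @inheritParams pr_curve
#' @return scalar in `[0, 1]`.
#' @export
average_precision <- function(y, s) {
  pc <- pr_curve(y, s)
  sum(diff(c(0, pc$recall)) * pc$precision)
}

#' Clinical utility
#'
#' The mean of [auc_pr()] and [average_precision()].
#'
#' @inheritParams pr_curve
#' @return scalar in `[0, 1]`.
#' @export
clinical_utility <- function(y, s) (auc_pr(y, s) + average_precision(y, s)) / 2

#' Area under the ROC curve
#'
#' Computed as the normalized Mann-Whitney U statistic (ties count half).
#'
#' @inheritParams pr_curve
#' @return scalar in `[0, 1]`.
#' @export
auc_roc <- function(y, s) {
  check_scored(y, s, need_pos = FALSE, need_both = TRUE)
  r <- rank(s)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Youden's J statistic
#'
#' `J = max_c (sensitivity(c) + specificity(c) - 1)` over all cutoffs, a row
#' being predicted positive when its score is at or above the cutoff. Ties
#' are broken toward the lowest cutoff attaining the maximum (favoring
#' sensitivity).
#'
#' @inheritParams pr_curve
#' @return list with `J` and `cutoff`.
#' @export
youden_j <- function(y, s) {
  check_scored(y, s, need_pos = FALSE, need_both = TRUE)
  cuts <- sort(unique(s))
  vals <- vapply(cuts, function(c) {
    pred <- s >= c
    sens <- sum(pred & y == 1) / sum(y == 1)
    spec <- sum(!pred & y == 0) / sum(y == 0)
    sens + spec - 1
  }, numeric(1))
  best <- max(vals)
  list(J = best, cutoff = cuts[which(vals == best)[1]])
}

#' Confusion-matrix summary at a cutoff
#'
#' Rows with score at or above `cutoff` are predicted positive. Ratios with
#' zero denominators are reported as `NA`, not zero.
#'
#' @inheritParams pr_curve
#' @param cutoff scalar in `[0, 1]`.
#' @return named list: `ppv`, `npv`, `sensitivity`, `specificity`, `accuracy`.
#' @export
confusion_at_cutoff <- function(y, s, cutoff) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  pred <- s >= cutoff
  tp <- sum(pred & y == 1); fp <- sum(pred & y == 0)
  tn <- sum(!pred & y == 0); fn <- sum(!pred & y == 1)
  ratio <- function(a, b) if (b == 0) NA_real_ else a / b
  list(ppv = ratio(tp, tp + fp), npv = ratio(tn, tn + fn),
       sensitivity = ratio(tp, tp + fn), specificity = ratio(tn, tn + fp),
       accuracy = (tp + tn) / length(y))
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2pr / (p + r)`; 0 by convention when both are zero.
#'
#' @param ppv precision.
#' @param sensitivity recall.
#' @return scalar in `[0, 1]`.
#' @export
f1_from <- function(ppv, sensitivity) {
  if (is.na(ppv) || is.na(sensitivity)) return(NA_real_)
  if (ppv + sensitivity == 0) return(0)
  2 * ppv * sensitivity / (ppv + sensitivity)
}

#' Brier score
#'
#' Mean squared error of scores against labels; lower is better-calibrated.
#'
#' @inheritParams pr_curve
#' @return scalar in `[0, 1]`.
#' @export
brier <- function(y, s) mean((s - y)^2)
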