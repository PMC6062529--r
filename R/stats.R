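# Cohort-characterization statistics (the baseline-table tests),
# recalibration of external scores, and the single-variable importance
# protocol.

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Probability-mass convention: the p-value sums hypergeometric
#' probabilities of all tables (with the observed margins) no more likely
#' than the observed one. A degenerate (zero) margin gives p = 1.
#'
#' @param table_2x2 2x2 matrix of nonnegative integer counts.
#' @return two-sided p-value.
#' @export
fisher_exact <- function(table_2x2) {
  tb <- as.matrix(table_2x2)
  stopifnot(all(dim(tb) == c(2, 2)), all(tb >= 0), all(tb == round(tb)))
  if (any(rowSums(tb) == 0) || any(colSums(tb) == 0)) return(1)
  stats::fisher.test(tb)$p.value
}

mwu_statistic <- function(x, y) {
  # U for sample x, ties counted half
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Two-sided Mann-Whitney U test
#'
#' Exact permutation enumeration for small samples (all arrangements when
#' `choose(nx + ny, nx)` is modest — this handles ties exactly); otherwise
#' the normal approximation with tie correction and continuity correction.
#'
#' @param x,y numeric samples.
#' @param exact_limit enumerate exactly when the number of arrangements is
#'   at most this (default covers `nx * ny <= 400` in the balanced cases
#'   used for small tables; 2e5 arrangements).
#' @return two-sided p-value.
#' @export
mann_whitney_u <- function(x, y, exact_limit = 2e5) {
  nx <- length(x); ny <- length(y)
  stopifnot(nx > 0, ny > 0)
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1) return(1)
  u_obs <- mwu_statistic(x, y)
  mu <- nx * ny / 2
  if (choose(nx + ny, nx) <= exact_limit) {
    idx <- utils::combn(nx + ny, nx)
    dev_obs <- abs(u_obs - mu)
    hits <- 0
    for (j in seq_len(ncol(idx))) {
      u <- mwu_statistic(pooled[idx[, j]], pooled[-idx[, j]])
      if (abs(u - mu) >= dev_obs - 1e-9) hits <- hits + 1
    }
    return(hits / ncol(idx))
  }
  # normal approximation with tie correction
  n <- nx + ny
  ties <- table(pooled)
  sig2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (abs(u_obs - mu) - 0.5) / sqrt(sig2)
  min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
}

#' Recalibration in the large
#'
#' Shifts all scores by a common intercept on the log-odds scale so their
#' mean matches a target prevalence; strictly monotone, hence
#' rank-preserving.
#'
#' @param scores risk scores in (0, 1).
#' @param target_prevalence target mean risk in (0, 1).
#' @return adjusted scores with `attr(, "delta")` = the log-odds shift.
#' @export
recalibrate_in_large <- function(scores, target_prevalence) {
  if (target_prevalence <= 0 || target_prevalence >= 1)
    pp_stop("pp_bad_target", "target prevalence must lie in (0, 1)")
  z <- pp_logit(scores)
  f <- function(delta) mean(stats::plogis(z + delta)) - target_prevalence
  if (abs(f(0)) < 1e-12) {
    out <- scores
    attr(out, "delta") <- 0
    return(out)
  }
  delta <- stats::uniroot(f, c(-40, 40), tol = 1e-12)$root
  out <- stats::plogis(z + delta)
  attr(out, "delta") <- delta
  out
}

#' Logistic recalibration
#'
#' Maximum-likelihood fit of the outcome on the log-odds of the score
#' (calibration slope and intercept); adjusted scores are the fitted
#' probabilities. Perfect separation is flagged and the slope capped.
#'
#' @param scores risk scores in (0, 1).
#' @param y binary outcomes.
#' @param max_slope cap applied when separation is detected (default 50).
#' @return list with `slope`, `intercept`, `adjusted`, `separation`.
#' @export
logistic_recalibration <- function(scores, y, max_slope = 50) {
  if (length(unique(y)) < 2) pp_stop("pp_single_class", "needs both classes")
  z <- pp_logit(scores)
  if (stats::sd(z) == 0) {
    b0 <- pp_logit(mean(y))
    return(list(slope = 0, intercept = b0,
                adjusted = rep(mean(y), length(y)), separation = FALSE))
  }
  fit <- suppressWarnings(stats::glm(y ~ z, family = stats::binomial()))
  slope <- unname(stats::coef(fit)[2]); intercept <- unname(stats::coef(fit)[1])
  separation <- !fit$converged || abs(slope) > max_slope
  if (separation) {
    slope <- sign(slope) * max_slope
    # refit the intercept for the capped slope
    off <- slope * z
    fit0 <- suppressWarnings(stats::glm(y ~ 1, offset = off,
                                        family = stats::binomial()))
    intercept <- unname(stats::coef(fit0)[1])
  }
  list(slope = slope, intercept = intercept,
       adjusted = stats::plogis(intercept + slope * z),
       separation = separation)
}

#' Single-variable predictive importance
#'
#' Runs a reduced pipeline search (small registry, short budget) on a
#' one-column dataset and reports the cross-validated AUC-ROC or AUC-PR of
#' the best configuration found — the protocol behind per-variable
#' importance rankings, where precision-oriented (AUC-PR) rankings can
#' disagree with discrimination-oriented (AUC-ROC) ones.
#'
#' @param dataset a `pp_dataset`.
#' @param variable covariate name.
#' @param metric `"auc_roc"` or `"auc_pr"`.
#' @param seed integer seed.
#' @param budget optimizer iterations (default 20).
#' @param k_folds cross-validation folds (default 5).
#' @return scalar importance; the metric's chance level for a constant
#'   variable (0.5 for AUC-ROC, the prevalence for AUC-PR).
#' @export
single_variable_importance <- function(dataset, variable,
                                       metric = c("auc_roc", "auc_pr"),
                                       seed = 1, budget = 20, k_folds = 5) {
  metric <- match.arg(metric)
  if (!variable %in% colnames(dataset$X))
    pp_stop("pp_unknown_variable", sprintf("no covariate '%s'", variable))
  x <- dataset$X[, variable, drop = FALSE]
  chance <- if (metric == "auc_roc") 0.5 else mean(dataset$y)
  if (stats::sd(x[, 1], na.rm = TRUE) %in% c(0, NA)) return(chance)
  ds <- labeled_dataset(x, dataset$y)
  reg <- build_default_registry(list(
    imputation = "mean", feature_processing = "none",
    classification = c("logistic", "naive_bayes"), calibration = "none"))
  res <- tryCatch({
    bo <- optimize_pipelines(ds, reg, budget = budget, k_folds = k_folds,
                             seed = seed, n_init = min(5, budget),
                             pool_size = 50)
    pf <- cv_pipeline_metrics(bo$best_config_full %||%
                                pipeline_config(reg, "mean", "none",
                                                bo$best_config$classifier, "none",
                                                classifier_params = bo$best_config$classifier_params),
                              ds, k_folds = k_folds, seed = seed)
    m <- mean(pf[[metric]], na.rm = TRUE)
    if (!is.finite(m)) chance else m
  }, error = function(e) chance)
  res
}
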