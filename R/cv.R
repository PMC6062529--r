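# Cross-validated clinical utility: the objective U(P(theta), D) queried by
# the optimizer. Folds are stratified by outcome and fixed by the seed, so
# every pipeline evaluated within one optimizer run sees the same folds and
# utilities are comparable.

#' Stratified fold assignment
#'
#' @param y binary outcome vector.
#' @param k number of folds.
#' @param seed integer seed for the shuffle.
#' @return integer vector of fold ids in `1..k`.
#' @export
stratified_folds <- function(y, k, seed = 1) {
  if (sum(y == 1) < k)
    pp_stop("pp_too_few_positives",
            sprintf("stratified %d-fold CV needs at least %d positives, got %d",
                    k, k, sum(y == 1)))
  folds <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Cross-validated pipeline metrics
#'
#' Fits the configured pipeline on each training fold and evaluates the
#' held-out fold. Returns per-fold area under the precision-recall curve,
#' average precision, clinical utility, AUC-ROC and Brier score.
#'
#' @param config a `pp_config`.
#' @param dataset a `pp_dataset`.
#' @param k_folds number of stratified folds.
#' @param seed integer seed (governs folds and per-fold pipeline fits).
#' @param folds optional precomputed fold vector (overrides `k_folds`/seed).
#' @return data frame, one row per fold.
#' @export
cv_pipeline_metrics <- function(config, dataset, k_folds = 10, seed = 1,
                                folds = NULL) {
  y <- dataset$y
  if (is.null(folds)) folds <- stratified_folds(y, k_folds, seed)
  k <- max(folds)
  seeds <- pp_child_seeds(seed + 1L, k)
  out <- lapply(seq_len(k), function(f) {
    tr <- folds != f; te <- !tr
    fit <- assemble_and_fit(config,
                            labeled_dataset(dataset$X[tr, , drop = FALSE], y[tr]),
                            seed = seeds[f])
    s <- predict_pipeline(fit, dataset$X[te, , drop = FALSE])
    yt <- y[te]
    data.frame(fold = f,
               auc_pr = auc_pr(yt, s),
               average_precision = average_precision(yt, s),
               utility = clinical_utility(yt, s),
               auc_roc = if (length(unique(yt)) > 1) auc_roc(yt, s) else NA_real_,
               brier = brier(yt, s))
  })
  do.call(rbind, out)
}

#' Cross-validated clinical utility
#'
#' @inheritParams cv_pipeline_metrics
#' @return a `pp_utility` list: `utility` (mean over folds), `sd`, `auc_pr`,
#'   `average_precision`, `per_fold` (data frame), `k`.
#' @export
cv_utility <- function(config, dataset, k_folds = 10, seed = 1, folds = NULL) {
  pf <- cv_pipeline_metrics(config, dataset, k_folds, seed, folds)
  structure(list(utility = mean(pf$utility), sd = stats::sd(pf$utility),
                 auc_pr = mean(pf$auc_pr),
                 average_precision = mean(pf$average_precision),
                 per_fold = pf, k = nrow(pf)),
            class = "pp_utility")
}

#' @export
print.pp_utility <- function(x, ...) {
  cat(sprintf("clinical utility: %.4f (sd %.4f over %d folds; AUC-PR %.4f, AP %.4f)\n",
              x$utility, x$sd, x$k, x$auc_pr, x$average_precision))
  invisible(x)
}

#' Metrics report across models
#'
#' One row per model per metric with the fold mean and a normal-approximation
#' 95% confidence interval over folds.
#'
#' @param per_fold_list named list of per-fold data frames from
#'   [cv_pipeline_metrics()].
#' @return data frame with `model`, `metric`, `mean`, `ci_lo`, `ci_hi`.
#' @export
metrics_report <- function(per_fold_list) {
  rows <- list()
  for (model in names(per_fold_list)) {
    pf <- per_fold_list[[model]]
    for (metric in setdiff(names(pf), "fold")) {
      v <- pf[[metric]][is.finite(pf[[metric]])]
      m <- mean(v); se <- stats::sd(v) / sqrt(length(v))
      rows[[length(rows) + 1]] <- data.frame(
        model = model, metric = metric, mean = m,
        ci_lo = m - 1.96 * se, ci_hi = m + 1.96 * se)
    }
  }
  do.call(rbind, rows)
}
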