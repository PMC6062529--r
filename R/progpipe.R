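# The user-facing model interface: one fitting function returning a classed
# object, with the usual methods.

#' Fit an automatically configured prognostic model
#'
#' Runs the decoupled Gaussian-process Bayesian pipeline search on the data,
#' builds the probability-of-best ensemble ("super-pipeline"), prunes
#' members below the weight threshold, refits the survivors on the full
#' dataset, and cross-validates the resulting ensemble for reporting.
#'
#' @param data a `pp_dataset` from [labeled_dataset()], or a data frame
#'   containing the outcome column.
#' @param outcome name of the binary outcome column when `data` is a data
#'   frame.
#' @param registry component registry (default [build_default_registry()]).
#' @param budget Bayesian-optimization iterations (study default 200).
#' @param kappa exploration weight of the acquisition (default 2).
#' @param k_folds stratified cross-validation folds for utility evaluation
#'   (study default 10).
#' @param weight_threshold ensemble inclusion threshold (default 0.01).
#' @param n_draws posterior draws for the probability-of-best weights.
#' @param seed integer seed controlling the entire run.
#' @param evaluate_cv cross-validate the final ensemble configuration for
#'   the report (default TRUE).
#' @return a `progpipe` object with components `ensemble`, `search`
#'   (the optimization run), `cv_metrics` and `utility`.
#' @export
progpipe <- function(data, outcome = "y", registry = build_default_registry(),
                     budget = 200, kappa = 2, k_folds = 10,
                     weight_threshold = 0.01, n_draws = 1000, seed = 1,
                     evaluate_cv = TRUE) {
  dataset <- if (inherits(data, "pp_dataset")) data else {
    stopifnot(outcome %in% names(data))
    labeled_dataset(data[, setdiff(names(data), outcome), drop = FALSE],
                    data[[outcome]])
  }
  seeds <- pp_child_seeds(seed, 3)
  bo <- optimize_pipelines(dataset, registry, budget = budget, kappa = kappa,
                           k_folds = k_folds, seed = seeds[1])
  ens <- finalize_ensemble(bo, dataset, threshold = weight_threshold,
                           n_draws = n_draws, seed = seeds[2])
  cv <- NULL; util <- NA_real_
  if (evaluate_cv) {
    cv <- cv_ensemble_metrics(ens, dataset, k_folds = k_folds, seed = seeds[3])
    util <- mean(cv$utility)
  }
  structure(list(ensemble = ens, search = bo, cv_metrics = cv, utility = util,
                 dataset_info = list(n = nrow(dataset$X), d = ncol(dataset$X),
                                     prevalence = mean(dataset$y)),
                 seed = seed, budget = budget, kappa = kappa,
                 k_folds = k_folds, weight_threshold = weight_threshold,
                 call = match.call()),
            class = "progpipe")
}

#' Cross-validate a fixed ensemble configuration
#'
#' Refits the ensemble's member pipelines (fixed configs and weights) on
#' each training fold and evaluates the weighted prediction on the held-out
#' fold.
#'
#' @param ensemble a `pp_ensemble`.
#' @param dataset a `pp_dataset`.
#' @param k_folds stratified folds.
#' @param seed integer seed.
#' @return per-fold metrics data frame (as [cv_pipeline_metrics()]).
#' @export
cv_ensemble_metrics <- function(ensemble, dataset, k_folds = 10, seed = 1) {
  folds <- stratified_folds(dataset$y, k_folds, seed)
  seeds <- pp_child_seeds(seed + 1L, k_folds)
  out <- lapply(seq_len(k_folds), function(f) {
    tr <- folds != f
    dtr <- labeled_dataset(dataset$X[tr, , drop = FALSE], dataset$y[tr])
    fits <- lapply(ensemble$members, function(mb)
      tryCatch(assemble_and_fit(mb$config, dtr, seed = seeds[f]),
               error = function(e) NULL))
    ok <- !vapply(fits, is.null, logical(1))
    w <- ensemble$weights[ok] / sum(ensemble$weights[ok])
    p <- vapply(fits[ok], function(ft)
      predict_pipeline(ft, dataset$X[!tr, , drop = FALSE]),
      numeric(sum(!tr)))
    s <- drop(matrix(p, ncol = sum(ok)) %*% w)
    yt <- dataset$y[!tr]
    data.frame(fold = f, auc_pr = auc_pr(yt, s),
               average_precision = average_precision(yt, s),
               utility = clinical_utility(yt, s),
               auc_roc = if (length(unique(yt)) > 1) auc_roc(yt, s) else NA_real_,
               brier = brier(yt, s))
  })
  do.call(rbind, out)
}

#' @export
print.progpipe <- function(x, ...) {
  cat("Automatically configured prognostic model\n")
  cat(sprintf("  data: %d patients, %d covariates, prevalence %.3f\n",
              x$dataset_info$n, x$dataset_info$d, x$dataset_info$prevalence))
  cat(sprintf("  search: %d iterations, best explored utility %.4f\n",
              nrow(x$search$trace), x$search$best_utility))
  print(x$ensemble)
  if (!is.na(x$utility))
    cat(sprintf("  cross-validated clinical utility: %.4f\n", x$utility))
  invisible(x)
}

#' @export
summary.progpipe <- function(object, ...) {
  out <- list(model = object,
              report = if (!is.null(object$cv_metrics))
                metrics_report(list(ensemble = object$cv_metrics)) else NULL)
  class(out) <- "summary.progpipe"
  out
}

#' @export
print.summary.progpipe <- function(x, ...) {
  print(x$model)
  if (!is.null(x$report)) {
    cat("\ncross-validated metrics (mean, normal-approximation 95% CI over folds):\n")
    print(x$report, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Predict risk scores or risk groups
#'
#' @param object a `progpipe` model.
#' @param newdata covariate rows (data frame or matrix; missing allowed).
#' @param type `"risk"` for calibrated scores in `[0, 1]`, `"group"` for
#'   risk-stratum labels.
#' @param strata a `pp_strata` used when `type = "group"`.
#' @param ... unused.
#' @export
predict.progpipe <- function(object, newdata, type = c("risk", "group"),
                             strata = risk_strata(), ...) {
  type <- match.arg(type)
  s <- predict_ensemble(object$ensemble, newdata)
  if (type == "risk") s else assign_group(s, strata)
}

#' @export
plot.progpipe <- function(x, ...) {
  tr <- x$search$trace
  graphics::plot(tr$iteration, tr$best_so_far, type = "s", lwd = 2,
                 xlab = "iteration", ylab = "best explored clinical utility",
                 main = "Bayesian pipeline search progress", ...)
  graphics::points(tr$iteration, tr$utility, pch = 20,
                   col = ifelse(tr$random_probe, "grey60", "steelblue"))
  invisible(x)
}

#' @rdname explain
#' @export
explain.progpipe <- function(object, dataset, strata = risk_strata(),
                             min_support = 0.2, min_confidence = 0.8,
                             max_len = 3, forced_cuts = c(), ...) {
  explain(object$ensemble, dataset, strata, min_support, min_confidence,
          max_len, forced_cuts)
}
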