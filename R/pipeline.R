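# A single pipeline: impute -> transform -> classify -> calibrate,
# producing a risk score in [0, 1] for a covariate row that may itself
# contain missing entries.

#' Construct a labeled dataset
#'
#' @param X covariate matrix or data frame (numeric; `NA` = missing).
#' @param y binary outcome vector (0/1), same length as `nrow(X)`.
#' @return a `pp_dataset` with the covariates, outcome and missingness mask.
#' @export
labeled_dataset <- function(X, y) {
  X <- as.matrix(as.data.frame(X))
  storage.mode(X) <- "double"
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0L, 1L)))
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  structure(list(X = X, y = y, missing = is.na(X)), class = "pp_dataset")
}

#' @export
print.pp_dataset <- function(x, ...) {
  cat(sprintf("labeled dataset: %d patients, %d covariates, prevalence %.3f, %.1f%% missing cells\n",
              nrow(x$X), ncol(x$X), mean(x$y), 100 * mean(x$missing)))
  invisible(x)
}

#' Fit a configured pipeline
#'
#' Stages are applied in order imputation, feature processing,
#' classification, calibration. When a calibrator other than `"none"` is
#' configured, the training fold is split 80/20 (stratified, seeded): the
#' first three stages are fit on the 80% part and the calibration map on the
#' held-out 20%, so the calibrator never sees its own classifier's training
#' rows.
#'
#' @param config a `pp_config` from [pipeline_config()] or [sample_config()].
#' @param dataset a `pp_dataset`.
#' @param seed integer controlling all pipeline randomness.
#' @return a `pp_fitted` object; score new rows with [predict_pipeline()].
#' @export
assemble_and_fit <- function(config, dataset, seed = 1) {
  X <- dataset$X; y <- dataset$y
  if (length(unique(y)) < 2) pp_stop("pp_single_class", "outcome has a single class")
  check_imputable(X)
  seeds <- pp_child_seeds(seed, 4)

  use_cal <- config$calibrator != "none"
  if (use_cal) {
    idx_cal <- with_seed(seeds[1], {
      pos <- which(y == 1); neg <- which(y == 0)
      c(sample(pos, max(1, floor(0.2 * length(pos)))),
        sample(neg, max(1, floor(0.2 * length(neg)))))
    })
    # keep both classes in the model part; otherwise fall back to no split
    if (length(unique(y[-idx_cal])) < 2) { use_cal <- FALSE; idx_cal <- integer(0) }
  } else idx_cal <- integer(0)
  idx_fit <- if (length(idx_cal)) setdiff(seq_along(y), idx_cal) else seq_along(y)

  imputer <- fit_imputer(config$imputer, config$imputer_params,
                         X[idx_fit, , drop = FALSE], seed = seeds[2])
  Xi <- imputer$transform(X[idx_fit, , drop = FALSE])
  if (!all(is.finite(Xi)))
    pp_stop("pp_nonfinite", "non-finite values after imputation")
  processor <- fit_processor(config$processor, config$processor_params, Xi, y[idx_fit])
  Xp <- processor$transform(Xi)
  classifier <- fit_classifier(config$classifier, config$classifier_params,
                               Xp, y[idx_fit], seed = seeds[3])
  calibrator <- if (use_cal) {
    Xc <- processor$transform(imputer$transform(X[idx_cal, , drop = FALSE]))
    fit_calibrator(config$calibrator, classifier$predict_prob(Xc), y[idx_cal])
  } else fit_calibrator("none")

  structure(list(config = config, imputer = imputer, processor = processor,
                 classifier = classifier, calibrator = calibrator,
                 schema = colnames(X), seed = seed),
            class = "pp_fitted")
}

#' Score new covariate rows with a fitted pipeline
#'
#' @param fitted a `pp_fitted` from [assemble_and_fit()].
#' @param X new covariate rows (missing entries allowed).
#' @return risk scores in `[0, 1]`.
#' @export
predict_pipeline <- function(fitted, X) {
  X <- as.matrix(as.data.frame(X))
  if (!is.null(fitted$schema) && !is.null(colnames(X)) &&
      !identical(colnames(X), fitted$schema)) {
    missing_cols <- setdiff(fitted$schema, colnames(X))
    if (length(missing_cols))
      pp_stop("pp_schema_mismatch",
              paste("missing columns:", paste(missing_cols, collapse = ", ")))
    X <- X[, fitted$schema, drop = FALSE]
  }
  s <- fitted$classifier$predict_prob(
    fitted$processor$transform(fitted$imputer$transform(X)))
  s <- fitted$calibrator$calibrate(s)
  s[!is.finite(s)] <- 0.5
  pmin(pmax(as.numeric(s), 0), 1)
}
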