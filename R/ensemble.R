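# The final "super-pipeline": explored pipelines weighted by the posterior
# probability that each has the highest clinical utility, pruned at a weight
# threshold, and refit to the full dataset.

#' Probability-of-best weights from a Gaussian posterior
#'
#' Draws joint samples from N(mu, Sigma) and returns, for each component,
#' the fraction of draws in which it attains the maximum; exact ties split
#' their draw's weight equally.
#'
#' @param mu posterior mean vector.
#' @param Sigma posterior covariance matrix (or a vector of variances).
#' @param n_draws Monte-Carlo draws.
#' @param seed integer seed.
#' @return weight vector summing to 1.
#' @export
prob_best_gaussian <- function(mu, Sigma, n_draws = 1000, seed = 1) {
  m <- length(mu)
  if (m == 1) return(1)
  if (is.vector(Sigma) || is.null(dim(Sigma))) Sigma <- diag(Sigma, m)
  # draw via eigendecomposition so near-singular posteriors are handled
  ei <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE)
  lam <- pmax(ei$values, 0)
  A <- ei$vectors %*% (sqrt(lam) * t(ei$vectors))
  Z <- with_seed(seed, matrix(stats::rnorm(n_draws * m), n_draws, m))
  draws <- sweep(Z %*% A, 2, mu, "+")
  w <- numeric(m)
  mx <- draws[cbind(seq_len(n_draws), max.col(draws, ties.method = "first"))]
  for (i in seq_len(n_draws)) {
    tied <- which(draws[i, ] == mx[i])
    w[tied] <- w[tied] + 1 / length(tied)
  }
  w / n_draws
}

#' Probability-of-best weights for explored configurations
#'
#' Samples the joint Gaussian-process posterior (correlated across the
#' explored points — the probability-of-best event is joint) and counts
#' argmax frequencies.
#'
#' @param surrogate the fitted `pp_surrogate` over the explored space.
#' @param explored_configs list of `pp_config`s that were explored.
#' @param n_draws posterior draws.
#' @param seed integer seed.
#' @return weight vector over the configs, summing to 1.
#' @export
prob_best_weights <- function(surrogate, explored_configs, n_draws = 1000, seed = 1) {
  stopifnot(length(explored_configs) >= 1)
  if (length(explored_configs) == 1) return(1)
  enc <- lapply(explored_configs, function(cfg) encode_config(surrogate$schema, cfg))
  post <- gp_posterior(surrogate, enc, full_cov = TRUE)
  prob_best_gaussian(post$mu, post$cov, n_draws, seed)
}

#' Prune and renormalize ensemble weights
#'
#' Drops members with weight below `threshold` and renormalizes; if every
#' member falls below the threshold, the single maximum-weight member is
#' kept with weight 1.
#'
#' @param weights weight vector summing to 1.
#' @param threshold inclusion threshold (default 0.01).
#' @return named numeric: pruned weights, with `attr(, "kept")` giving the
#'   indices retained.
#' @export
prune_normalize <- function(weights, threshold = 0.01) {
  keep <- which(weights >= threshold)
  if (!length(keep)) keep <- which.max(weights)
  w <- weights[keep] / sum(weights[keep])
  attr(w, "kept") <- keep
  w
}

#' Build the final ensemble from a completed optimization run
#'
#' Weights come from the cross-validation-era posterior (before refitting);
#' members below the threshold are pruned; the surviving pipelines — each
#' completed with the decoupled optimal imputer and calibrator — are refit
#' on the full dataset.
#'
#' @param bo a `pp_bo` from [optimize_pipelines()].
#' @param dataset the full `pp_dataset`.
#' @param threshold weight-inclusion threshold (default 0.01).
#' @param n_draws posterior draws for the weights.
#' @param seed integer seed.
#' @return a `pp_ensemble`.
#' @export
finalize_ensemble <- function(bo, dataset, threshold = 0.01, n_draws = 1000,
                              seed = 1) {
  w_all <- prob_best_weights(bo$surrogates$mf, bo$explored$configs, n_draws, seed)
  w <- prune_normalize(w_all, threshold)
  kept <- attr(w, "kept")
  reg <- bo$registry
  imp <- bo$best_imputer$config
  members <- list()
  weights <- numeric(0)
  seeds <- pp_child_seeds(seed + 1L, length(kept))
  for (i in seq_along(kept)) {
    cfg_mf <- bo$explored$configs[[kept[i]]]
    cfg <- pipeline_config(reg, imp$imputer, cfg_mf$processor, cfg_mf$classifier,
                           bo$best_calibrator$name,
                           imputer_params = imp$imputer_params,
                           processor_params = cfg_mf$processor_params,
                           classifier_params = cfg_mf$classifier_params)
    fit <- tryCatch(assemble_and_fit(cfg, dataset, seed = seeds[i]),
                    error = function(e) NULL)
    if (is.null(fit)) {
      warning(sprintf("ensemble member %d failed to refit; dropped", kept[i]))
      next
    }
    members[[length(members) + 1]] <- list(config = cfg, fitted = fit)
    weights <- c(weights, w[i])
  }
  if (!length(members)) pp_stop("pp_empty_ensemble", "no ensemble member could be refit")
  weights <- weights / sum(weights)
  structure(list(members = members, weights = weights, threshold = threshold,
                 weights_all = w_all, seed = seed, schema = colnames(dataset$X),
                 imputer = imp$imputer, calibrator = bo$best_calibrator$name),
            class = "pp_ensemble")
}

#' Predict ensemble risk scores
#'
#' Weighted arithmetic mean of the member pipelines' calibrated risks.
#'
#' @param ensemble a `pp_ensemble`.
#' @param X new covariate rows (missing entries allowed).
#' @return risk scores in `[0, 1]`.
#' @export
predict_ensemble <- function(ensemble, X) {
  p <- vapply(ensemble$members,
              function(mb) predict_pipeline(mb$fitted, X),
              numeric(nrow(as.data.frame(X))))
  drop(matrix(p, ncol = length(ensemble$members)) %*% ensemble$weights)
}

#' @export
print.pp_ensemble <- function(x, ...) {
  cat(sprintf("prognostic ensemble: %d member(s), weight threshold %.3g\n",
              length(x$members), x$threshold))
  for (i in seq_along(x$members)) {
    cat(sprintf("  w=%.3f ", x$weights[i]))
    print(x$members[[i]]$config)
  }
  invisible(x)
}

#' Serialize ensemble structure as a flat manifest
#'
#' Configs as flat key-value records plus weights and seeds; used for the
#' model archive and for byte-identity checks between runs.
#'
#' @param ensemble a `pp_ensemble`.
#' @return character vector of `key=value` lines.
#' @export
ensemble_manifest <- function(ensemble) {
  lines <- c(sprintf("n_members=%d", length(ensemble$members)),
             sprintf("threshold=%.17g", ensemble$threshold),
             sprintf("seed=%d", ensemble$seed))
  for (i in seq_along(ensemble$members)) {
    rec <- serialize_config(ensemble$members[[i]]$config)
    lines <- c(lines,
               sprintf("member%d.weight=%.17g", i, ensemble$weights[i]),
               paste0(sprintf("member%d.", i), names(rec), "=", rec))
  }
  lines
}
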