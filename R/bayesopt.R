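# Decoupled Bayesian optimization over the pipeline space. The clinical
# utility is approximated as the sum of three independent terms — one for
# the (classification, feature-processing) pair, one for the imputer, one
# for the calibrator — and each term gets its own Gaussian-process surrogate
# and upper-confidence-bound acquisition. Each iteration proposes one point
# per surrogate, evaluates the corresponding utilities by cross-validation
# (memoized per configuration), and updates the posteriors.

config_key <- function(config) paste(serialize_config(config), collapse = "|")

#' Propose the next configuration for one surrogate
#'
#' Maximizes the acquisition over a random candidate pool drawn uniformly
#' from the stage space (the space is mostly categorical, so pool search is
#' used instead of gradient ascent). Ties are broken at random.
#'
#' @param surrogate a `pp_surrogate`.
#' @param registry a `pp_registry`.
#' @param pool_size candidates to draw.
#' @param kappa exploration weight.
#' @return the proposed `pp_config` (non-varying stages take registry defaults).
#' @export
propose_next <- function(surrogate, registry, pool_size = 500, kappa = 2) {
  stages <- surrogate$schema$stages
  pool <- lapply(seq_len(pool_size), function(i) sample_config(registry, stages))
  keys <- vapply(pool, config_key, character(1))
  keep <- !duplicated(keys)
  pool <- pool[keep]
  enc <- lapply(pool, function(cfg) encode_config(surrogate$schema, cfg))
  post <- gp_posterior(surrogate, enc)
  a <- acquisition(post$mu, post$sd, kappa)
  best <- which(a == max(a))
  pool[[if (length(best) > 1) sample(best, 1) else best]]
}

bo_reference <- function(registry) {
  # fixed reference components used when scoring imputers and calibrators in
  # isolation (the decoupling assumption licenses a fixed reference)
  has <- function(st, nm) any(vapply(registry[[st]], function(c) c$name == nm, logical(1)))
  list(imputer = if (has("imputation", "mean")) "mean" else registry$imputation[[1]]$name,
       processor = if (has("feature_processing", "none")) "none" else registry$feature_processing[[1]]$name,
       classifier = if (has("classification", "logistic")) "logistic" else registry$classification[[1]]$name,
       calibrator = if (has("calibration", "none")) "none" else registry$calibration[[1]]$name)
}

#' Run the decoupled Bayesian pipeline search
#'
#' @param dataset a `pp_dataset`.
#' @param registry a `pp_registry`.
#' @param budget total number of iterations (including the initial random
#'   probes).
#' @param kappa exploration weight of the acquisition.
#' @param k_folds inner stratified cross-validation folds for each utility
#'   evaluation (folds are fixed across the whole run).
#' @param seed integer seed controlling the entire run.
#' @param n_init initial random probes before the first surrogate fit.
#' @param pool_size acquisition candidate-pool size.
#' @param refit_every refit kernel parameters by marginal likelihood every
#'   this many iterations.
#' @param utility_fn optional evaluator override `function(config) -> utility`
#'   (used to optimize against synthetic planted landscapes); default is
#'   cross-validated clinical utility for the pipeline surrogate and
#'   imputer surrogate, and one minus the Brier score for the calibrator
#'   surrogate.
#' @return a `pp_bo` object: `trace` data frame, the three surrogates, the
#'   explored (classifier, processor) configurations with utilities, and the
#'   decoupled optima (`best_config`, `best_imputer`, `best_calibrator`).
#' @export
optimize_pipelines <- function(dataset, registry, budget = 200, kappa = 2,
                               k_folds = 10, seed = 1, n_init = 5,
                               pool_size = 500, refit_every = 5,
                               utility_fn = NULL) {
  stopifnot(budget >= 1)
  n_init <- min(n_init, budget)
  folds <- if (is.null(utility_fn)) stratified_folds(dataset$y, k_folds, seed) else NULL
  seeds <- pp_child_seeds(seed, budget + 10L)

  sur <- list(
    mf  = new_surrogate(encode_schema(registry, c("feature_processing", "classification"))),
    imp = new_surrogate(encode_schema(registry, "imputation")),
    cal = new_surrogate(encode_schema(registry, "calibration")))
  ref <- bo_reference(registry)
  cache <- new.env(parent = emptyenv())

  eval_cached <- function(config, kind) {
    key <- paste0(kind, "::", config_key(config))
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- tryCatch({
      if (!is.null(utility_fn)) utility_fn(config)
      else if (kind == "cal") {
        pf <- cv_pipeline_metrics(config, dataset, folds = folds, seed = seed)
        1 - mean(pf$brier)
      } else {
        cv_utility(config, dataset, folds = folds, seed = seed)$utility
      }
    }, error = function(e) 0)
    if (!is.finite(val)) val <- 0
    cache[[key]] <- val
    val
  }

  explored <- list(configs = list(), utilities = numeric(0))
  imp_configs <- list()
  cal_configs <- list()
  trace <- list()

  for (it in seq_len(budget)) {
    random_probe <- it <= n_init
    step <- with_seed(seeds[it], {
      if (random_probe) {
        cfg_mf <- sample_config(registry, c("feature_processing", "classification"))
        cfg_imp <- sample_config(registry, "imputation")
        cfg_cal <- sample_config(registry, "calibration")
      } else {
        cfg_mf <- propose_next(sur$mf, registry, pool_size, kappa)
        cfg_imp <- propose_next(sur$imp, registry, min(pool_size, 100), kappa)
        cfg_cal <- propose_next(sur$cal, registry, length(registry$calibration) * 2, kappa)
      }
      list(mf = cfg_mf, imp = cfg_imp, cal = cfg_cal)
    })

    # pipelines actually evaluated: varying block + fixed reference elsewhere
    pl_mf <- pipeline_config(registry, ref$imputer, step$mf$processor,
                             step$mf$classifier, ref$calibrator,
                             processor_params = step$mf$processor_params,
                             classifier_params = step$mf$classifier_params)
    pl_imp <- pipeline_config(registry, step$imp$imputer, ref$processor,
                              ref$classifier, ref$calibrator,
                              imputer_params = step$imp$imputer_params)
    pl_cal <- pipeline_config(registry, ref$imputer, ref$processor,
                              ref$classifier, step$cal$calibrator)

    u_mf <- eval_cached(pl_mf, "mf")
    u_imp <- eval_cached(pl_imp, "imp")
    u_cal <- eval_cached(pl_cal, "cal")

    enc_mf <- encode_config(sur$mf$schema, step$mf)
    acq <- if (random_probe) NA_real_ else {
      p <- gp_posterior(sur$mf, list(enc_mf))
      acquisition(p$mu, p$sd, kappa)[1]
    }

    sur$mf <- surrogate_add(sur$mf, enc_mf, u_mf, key = config_key(pl_mf))
    if (!config_key(pl_imp) %in% sur$imp$keys)
      imp_configs[[length(imp_configs) + 1]] <- step$imp
    sur$imp <- surrogate_add(sur$imp, encode_config(sur$imp$schema, step$imp),
                             u_imp, key = config_key(pl_imp))
    if (!config_key(pl_cal) %in% sur$cal$keys)
      cal_configs[[length(cal_configs) + 1]] <- step$cal
    sur$cal <- surrogate_add(sur$cal, encode_config(sur$cal$schema, step$cal),
                             u_cal, key = config_key(pl_cal))

    if (it %% refit_every == 0) {
      sur$mf <- surrogate_fit_params(sur$mf)
      sur$imp <- surrogate_fit_params(sur$imp)
      sur$cal <- surrogate_fit_params(sur$cal)
    }

    explored$configs[[length(explored$configs) + 1]] <- step$mf
    explored$utilities <- c(explored$utilities, u_mf)
    trace[[it]] <- data.frame(
      iteration = it, random_probe = random_probe,
      classifier = step$mf$classifier, processor = step$mf$processor,
      imputer = step$imp$imputer, calibrator = step$cal$calibrator,
      theta = paste(serialize_config(step$mf), collapse = ";"),
      utility = u_mf, utility_imputer = u_imp, utility_calibrator = u_cal,
      acquisition = acq, best_so_far = NA_real_)
  }

  trace <- do.call(rbind, trace)
  trace$best_so_far <- cummax(trace$utility)

  best_mf_i <- which.max(explored$utilities)
  best_imp_i <- which.max(sur$imp$y)
  best_cal_i <- which.max(sur$cal$y)

  structure(list(
    trace = trace, surrogates = sur, explored = explored, registry = registry,
    reference = ref, folds = folds, seed = seed, kappa = kappa,
    best_config = explored$configs[[best_mf_i]],
    best_utility = explored$utilities[best_mf_i],
    best_imputer = list(name = imp_configs[[best_imp_i]]$imputer,
                        config = imp_configs[[best_imp_i]],
                        utility = sur$imp$y[best_imp_i]),
    best_calibrator = list(name = cal_configs[[best_cal_i]]$calibrator,
                           utility = sur$cal$y[best_cal_i])
  ), class = "pp_bo")
}

#' @export
print.pp_bo <- function(x, ...) {
  cat(sprintf("Bayesian pipeline search: %d iterations, best utility %.4f\n",
              nrow(x$trace), x$best_utility))
  cat("  best pipeline block: ")
  print(x$best_config)
  cat(sprintf("  best imputer: %s (utility %.4f); best calibrator: %s (1 - Brier %.4f)\n",
              x$best_imputer$name, x$best_imputer$utility,
              x$best_calibrator$name, x$best_calibrator$utility))
  invisible(x)
}

#' Write an optimization trace as CSV
#'
#' @param bo a `pp_bo`.
#' @param path output file.
#' @export
write_trace <- function(bo, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed=%d kappa=%g iterations=%d", bo$seed, bo$kappa,
                     nrow(bo$trace)), con)
  utils::write.csv(bo$trace, con, row.names = FALSE)
  invisible(path)
}
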