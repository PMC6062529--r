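# Pipeline search space: component registries and hyper-parameter domains.
#
# A pipeline is the ordered chain imputation -> feature processing ->
# classification -> calibration. Each stage draws its component from a
# registry of ComponentSpec entries; each component declares a (possibly
# empty) hyper-parameter domain. The calibration methods carry no
# hyper-parameters.

#' Declare a pipeline component
#'
#' @param name identifier, unique within its stage.
#' @param stage one of `"imputation"`, `"feature_processing"`,
#'   `"classification"`, `"calibration"`.
#' @param hyperparams list of dimensions created by [hp_num()], [hp_int()]
#'   or [hp_cat()].
#' @return a `pp_component` object.
#' @export
component_spec <- function(name, stage, hyperparams = list()) {
  stopifnot(is.character(name), length(name) == 1, stage %in% pp_stages)
  nm <- vapply(hyperparams, function(h) h$name, character(1))
  if (anyDuplicated(nm)) pp_stop("pp_bad_component", "duplicate hyper-parameter names")
  for (h in hyperparams) validate_dimension(h)
  structure(list(name = name, stage = stage, hyperparams = hyperparams),
            class = "pp_component")
}

#' Hyper-parameter dimensions
#'
#' `hp_num` declares a continuous dimension with finite bounds (optionally
#' log-scaled), `hp_int` an integer dimension, `hp_cat` a categorical one.
#'
#' @param name dimension name.
#' @param lower,upper finite bounds (inclusive).
#' @param default default value; must lie in the domain.
#' @param log sample/encode on the log scale.
#' @param levels character vector of admissible levels.
#' @return a dimension descriptor list.
#' @export
hp_num <- function(name, lower, upper, default, log = FALSE) {
  list(name = name, kind = "continuous", lower = lower, upper = upper,
       default = default, log = log)
}

#' @rdname hp_num
#' @export
hp_int <- function(name, lower, upper, default, log = FALSE) {
  list(name = name, kind = "integer", lower = as.integer(lower),
       upper = as.integer(upper), default = as.integer(default), log = log)
}

#' @rdname hp_num
#' @export
hp_cat <- function(name, levels, default) {
  list(name = name, kind = "categorical", levels = levels, default = default)
}

validate_dimension <- function(h) {
  if (h$kind == "categorical") {
    if (length(h$levels) < 1) pp_stop("pp_bad_domain", "categorical dimension needs >= 1 level")
    if (!h$default %in% h$levels) pp_stop("pp_bad_domain", "default outside levels")
  } else {
    if (!is.finite(h$lower) || !is.finite(h$upper) || h$lower > h$upper)
      pp_stop("pp_bad_domain", sprintf("dimension '%s' needs finite ordered bounds", h$name))
    if (h$default < h$lower || h$default > h$upper)
      pp_stop("pp_bad_domain", sprintf("default of '%s' outside bounds", h$name))
  }
  invisible(TRUE)
}

hp_in_domain <- function(h, value) {
  if (h$kind == "categorical") return(value %in% h$levels)
  if (!is.finite(value)) return(FALSE)
  value >= h$lower && value <= h$upper
}

#' Build the default component registry
#'
#' Seven imputation algorithms (mean, median, most-frequent,
#' expectation-maximization, matrix completion, chained equations,
#' random-forest iterative), five feature processors (identity,
#' standardization, PCA, feature agglomeration, univariate selection), six
#' classifiers (regularized logistic regression, random forest, gradient
#' boosting, extreme gradient boosting, bagged trees, naive Bayes) and three
#' calibration methods (sigmoid regression, isotonic regression, none).
#' Menus are extensible: registries are plain lists of [component_spec()]
#' entries and stages may be subset via `stage_filter`.
#'
#' @param stage_filter optional named list restricting stages to the named
#'   components, e.g. `list(classification = c("logistic", "random_forest"))`.
#' @return a `pp_registry` object.
#' @export
build_default_registry <- function(stage_filter = NULL) {
  imput <- list(
    component_spec("mean", "imputation"),
    component_spec("median", "imputation"),
    component_spec("most_frequent", "imputation"),
    component_spec("em", "imputation",
                   list(hp_int("max_iter", 5, 50, 20))),
    component_spec("matrix_completion", "imputation",
                   list(hp_int("rank", 1, 10, 3),
                        hp_num("shrink", 0.01, 10, 1, log = TRUE))),
    component_spec("chained_equations", "imputation",
                   list(hp_int("n_iter", 1, 10, 5))),
    component_spec("rf_iterative", "imputation",
                   list(hp_int("n_iter", 1, 5, 3),
                        hp_int("num_trees", 10, 100, 50, log = TRUE)))
  )
  proc <- list(
    component_spec("none", "feature_processing"),
    component_spec("standardize", "feature_processing"),
    component_spec("pca", "feature_processing",
                   list(hp_int("n_components", 2, 100, 20, log = TRUE))),
    component_spec("agglomeration", "feature_processing",
                   list(hp_int("n_clusters", 2, 50, 10, log = TRUE))),
    component_spec("select_k_best", "feature_processing",
                   list(hp_int("k", 2, 100, 20, log = TRUE)))
  )
  clf <- list(
    component_spec("logistic", "classification",
                   list(hp_num("lambda", 1e-4, 1, 1e-2, log = TRUE),
                        hp_num("alpha", 0, 1, 0))),
    component_spec("random_forest", "classification",
                   list(hp_int("num_trees", 10, 1000, 200, log = TRUE),
                        hp_num("mtry_frac", 0.1, 1, 0.3),
                        hp_int("min_node", 1, 20, 5))),
    component_spec("gradient_boosting", "classification",
                   list(hp_int("nrounds", 10, 500, 100, log = TRUE),
                        hp_num("eta", 0.01, 0.5, 0.1, log = TRUE),
                        hp_int("max_depth", 1, 8, 3))),
    component_spec("xgboost", "classification",
                   list(hp_int("nrounds", 10, 500, 150, log = TRUE),
                        hp_num("eta", 0.01, 0.5, 0.1, log = TRUE),
                        hp_int("max_depth", 1, 8, 4),
                        hp_num("reg_lambda", 1e-2, 10, 1, log = TRUE),
                        hp_num("subsample", 0.5, 1, 1))),
    component_spec("bagging", "classification",
                   list(hp_int("n_bags", 5, 50, 10, log = TRUE),
                        hp_num("cp", 1e-4, 0.1, 0.01, log = TRUE))),
    component_spec("naive_bayes", "classification",
                   list(hp_num("laplace", 0, 5, 1)))
  )
  cal <- list(
    component_spec("sigmoid", "calibration"),
    component_spec("isotonic", "calibration"),
    component_spec("none", "calibration")
  )
  reg <- structure(list(imputation = imput, feature_processing = proc,
                        classification = clf, calibration = cal),
                   class = "pp_registry")
  if (!is.null(stage_filter)) {
    for (st in names(stage_filter)) {
      keep <- vapply(reg[[st]], function(cs) cs$name %in% stage_filter[[st]], logical(1))
      if (!any(keep)) pp_stop("pp_bad_registry", sprintf("stage '%s' emptied by filter", st))
      reg[[st]] <- reg[[st]][keep]
    }
  }
  reg
}

#' Compact registry for large-cohort screening runs
#'
#' Mean/median imputation, identity/standardization processing, regularized
#' logistic regression plus a gradient-boosting component with a bounded
#' domain (10-150 rounds, depth 1-4), and none/sigmoid calibration. Keeps a
#' full search affordable on cohorts of several thousand patients while
#' retaining one linear and one tree-based learner.
#'
#' @return a `pp_registry`.
#' @export
screening_registry <- function() {
  reg <- build_default_registry(list(
    imputation = c("mean", "median"),
    feature_processing = c("none", "standardize"),
    classification = "logistic",
    calibration = c("none", "sigmoid")))
  reg$classification <- c(reg$classification, list(
    component_spec("gradient_boosting", "classification",
                   list(hp_int("nrounds", 10, 150, 60, log = TRUE),
                        hp_num("eta", 0.05, 0.3, 0.1, log = TRUE),
                        hp_int("max_depth", 1, 4, 3)))))
  reg
}

registry_component <- function(registry, stage, name) {
  for (cs in registry[[stage]]) if (cs$name == name) return(cs)
  pp_stop("pp_unknown_component",
          sprintf("component '%s' not in stage '%s'", name, stage))
}

#' Number of pipelines expressible by a registry
#'
#' The product of the four stage sizes. Also accepts a plain vector of stage
#' sizes, e.g. `count_pipelines(c(7, 14, 20, 3))`.
#'
#' @param registry a `pp_registry` or a numeric vector of stage sizes.
#' @return integer count.
#' @export
count_pipelines <- function(registry) {
  if (is.numeric(registry)) return(prod(registry))
  prod(vapply(pp_stages, function(st) length(registry[[st]]), numeric(1)))
}

default_params <- function(cs) {
  p <- lapply(cs$hyperparams, function(h) h$default)
  names(p) <- vapply(cs$hyperparams, function(h) h$name, character(1))
  p
}

sample_params <- function(cs) {
  p <- lapply(cs$hyperparams, function(h) {
    if (h$kind == "categorical") return(sample(h$levels, 1))
    if (isTRUE(h$log)) {
      lo <- log(max(h$lower, 1e-12)); hi <- log(h$upper)
      v <- exp(stats::runif(1, lo, hi))
    } else v <- stats::runif(1, h$lower, h$upper)
    if (h$kind == "integer") v <- as.integer(round(v))
    min(max(v, h$lower), h$upper)
  })
  names(p) <- vapply(cs$hyperparams, function(h) h$name, character(1))
  p
}

#' Construct a pipeline configuration
#'
#' @param registry a `pp_registry`.
#' @param imputer,processor,classifier,calibrator component names.
#' @param imputer_params,processor_params,classifier_params named lists of
#'   hyper-parameter values; defaults are filled in for omitted dimensions.
#' @return a `pp_config` object.
#' @export
pipeline_config <- function(registry, imputer, processor, classifier, calibrator,
                            imputer_params = list(), processor_params = list(),
                            classifier_params = list()) {
  fill <- function(stage, name, given) {
    cs <- registry_component(registry, stage, name)
    p <- default_params(cs)
    for (nm in names(given)) {
      hs <- cs$hyperparams[vapply(cs$hyperparams, function(h) h$name, character(1)) == nm]
      if (!length(hs)) pp_stop("pp_bad_config", sprintf("unknown hyper-parameter '%s'", nm))
      v <- given[[nm]]
      if (hs[[1]]$kind == "integer") v <- as.integer(round(v))
      if (!hp_in_domain(hs[[1]], v))
        pp_stop("pp_bad_config", sprintf("'%s' = %s outside its domain", nm, format(v)))
      p[[nm]] <- v
    }
    p
  }
  structure(list(
    imputer = imputer, imputer_params = fill("imputation", imputer, imputer_params),
    processor = processor,
    processor_params = fill("feature_processing", processor, processor_params),
    classifier = classifier,
    classifier_params = fill("classification", classifier, classifier_params),
    calibrator = registry_component(registry, "calibration", calibrator)$name
  ), class = "pp_config")
}

#' Draw a uniformly random pipeline configuration
#'
#' One component uniformly at random per stage; hyper-parameters uniform
#' within their domains (log-uniform for log-flagged dimensions). Uses the
#' current RNG state.
#'
#' @param registry a `pp_registry`.
#' @param stages optional character vector restricting which stages are
#'   randomized (others take the first registry entry with defaults).
#' @return a `pp_config`.
#' @export
sample_config <- function(registry, stages = pp_stages) {
  pick <- function(stage) {
    if (stage %in% stages) registry[[stage]][[sample.int(length(registry[[stage]]), 1)]]
    else registry[[stage]][[1]]
  }
  ci <- pick("imputation"); cf <- pick("feature_processing")
  cm <- pick("classification"); cc <- pick("calibration")
  par <- function(cs, stage) if (stage %in% stages) sample_params(cs) else default_params(cs)
  structure(list(
    imputer = ci$name, imputer_params = par(ci, "imputation"),
    processor = cf$name, processor_params = par(cf, "feature_processing"),
    classifier = cm$name, classifier_params = par(cm, "classification"),
    calibrator = cc$name
  ), class = "pp_config")
}

#' Serialize a configuration to a flat key-value record
#'
#' @param config a `pp_config`.
#' @return named character vector; invertible via [parse_config()].
#' @export
serialize_config <- function(config) {
  out <- c(imputer = config$imputer, processor = config$processor,
           classifier = config$classifier, calibrator = config$calibrator)
  add <- function(prefix, params) {
    if (!length(params)) return(character(0))
    v <- vapply(params, function(x) format(x, digits = 17), character(1))
    names(v) <- paste0(prefix, ".", names(params))
    v
  }
  c(out, add("imputer", config$imputer_params),
    add("processor", config$processor_params),
    add("classifier", config$classifier_params))
}

#' @rdname serialize_config
#' @param record named character vector from [serialize_config()].
#' @param registry the registry the record refers to.
#' @export
parse_config <- function(record, registry) {
  grab <- function(prefix, cs) {
    keys <- paste0(prefix, ".", vapply(cs$hyperparams, function(h) h$name, character(1)))
    p <- list()
    for (i in seq_along(keys)) {
      if (!keys[i] %in% names(record)) next
      h <- cs$hyperparams[[i]]
      v <- record[[keys[i]]]
      p[[h$name]] <- if (h$kind == "categorical") v else as.numeric(v)
    }
    p
  }
  pipeline_config(registry,
    imputer = record[["imputer"]], processor = record[["processor"]],
    classifier = record[["classifier"]], calibrator = record[["calibrator"]],
    imputer_params = grab("imputer", registry_component(registry, "imputation", record[["imputer"]])),
    processor_params = grab("processor", registry_component(registry, "feature_processing", record[["processor"]])),
    classifier_params = grab("classifier", registry_component(registry, "classification", record[["classifier"]])))
}

#' @export
print.pp_config <- function(x, ...) {
  fmt <- function(p) if (!length(p)) "" else
    paste0(" (", paste(names(p), vapply(p, function(v) format(v, digits = 3), character(1)),
                       sep = "=", collapse = ", "), ")")
  cat("pipeline: ", x$imputer, fmt(x$imputer_params), " -> ",
      x$processor, fmt(x$processor_params), " -> ",
      x$classifier, fmt(x$classifier_params), " -> ", x$calibrator, "\n", sep = "")
  invisible(x)
}

#' @export
print.pp_registry <- function(x, ...) {
  cat("pipeline component registry:\n")
  for (st in pp_stages)
    cat(sprintf("  %-20s %2d: %s\n", st, length(x[[st]]),
                paste(vapply(x[[st]], function(c) c$name, character(1)), collapse = ", ")))
  cat(sprintf("  total pipelines: %d\n", count_pipelines(x)))
  invisible(x)
}
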