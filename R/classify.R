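# Classification and calibration stages. Classifiers are established
# learners behind a uniform fit/predict-probability contract; calibration
# maps raw classifier scores to calibrated risks.

as_feature_df <- function(X) {
  df <- as.data.frame(as.matrix(X))
  names(df) <- paste0("v", seq_len(ncol(df)))
  df
}

#' Fit a classification component
#'
#' @param name classifier name from the registry.
#' @param params named list of hyper-parameter values.
#' @param X complete numeric training matrix.
#' @param y binary outcome vector (0/1).
#' @param seed integer seed controlling all classifier randomness.
#' @return object with a `$predict_prob(Xnew)` closure returning P(y = 1).
#' @export
fit_classifier <- function(name, params = list(), X, y, seed = 1) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  y <- as.integer(y)
  if (length(unique(y)) < 2) pp_stop("pp_single_class", "outcome has a single class")
  d <- ncol(X)
  predict_prob <- switch(name,
    logistic = {
      # glmnet needs >= 2 columns; pad a zero column for 1-d inputs
      pad <- d < 2
      Xg <- if (pad) cbind(X, 0) else X
      fit <- glmnet::glmnet(Xg, factor(y), family = "binomial",
                            alpha = params$alpha %||% 0,
                            lambda = params$lambda %||% 1e-2)
      function(Xn) {
        Xn <- as.matrix(Xn)
        if (pad) Xn <- cbind(Xn, 0)
        drop(stats::predict(fit, Xn, type = "response"))
      }
    },
    random_forest = {
      df <- as_feature_df(X); df$.y <- factor(y, levels = c(0, 1))
      fit <- ranger::ranger(dependent.variable.name = ".y", data = df,
                            probability = TRUE,
                            num.trees = params$num_trees %||% 200,
                            mtry = max(1, floor((params$mtry_frac %||% 0.3) * d)),
                            min.node.size = params$min_node %||% 5,
                            seed = seed, num.threads = 1)
      function(Xn) {
        p <- stats::predict(fit, as_feature_df(Xn), num.threads = 1)$predictions
        p[, "1"]
      }
    },
    gradient_boosting = ,
    xgboost = {
      fit <- xgboost::xgboost(
        X, factor(y, levels = c(0, 1)), objective = "binary:logistic",
        nrounds = params$nrounds %||% 100,
        learning_rate = params$eta %||% 0.1,
        max_depth = params$max_depth %||% 3,
        reg_lambda = params$reg_lambda %||% 1,
        subsample = params$subsample %||% 1,
        nthreads = 1, seed = seed, verbosity = 0)
      function(Xn) {
        p <- stats::predict(fit, as.matrix(Xn), type = "response")
        if (is.matrix(p)) p[, "1"] else as.numeric(p)
      }
    },
    bagging = {
      n_bags <- params$n_bags %||% 10
      df <- as_feature_df(X); df$.y <- factor(y, levels = c(0, 1))
      seeds <- pp_child_seeds(seed, n_bags)
      trees <- lapply(seq_len(n_bags), function(b) with_seed(seeds[b], {
        idx <- sample.int(nrow(df), nrow(df), replace = TRUE)
        rpart::rpart(.y ~ ., data = df[idx, , drop = FALSE], method = "class",
                     control = rpart::rpart.control(cp = params$cp %||% 0.01))
      }))
      function(Xn) {
        dfn <- as_feature_df(Xn)
        p <- vapply(trees, function(tr) stats::predict(tr, dfn)[, "1"],
                    numeric(nrow(dfn)))
        rowMeans(matrix(p, nrow = nrow(dfn)))
      }
    },
    naive_bayes = {
      df <- as_feature_df(X)
      fit <- e1071::naiveBayes(df, factor(y, levels = c(0, 1)),
                               laplace = params$laplace %||% 1)
      function(Xn) {
        p <- stats::predict(fit, as_feature_df(Xn), type = "raw", threshold = 1e-3)
        p[, "1"]
      }
    },
    pp_stop("pp_unknown_component", sprintf("unknown classifier '%s'", name))
  )
  structure(list(name = name, predict_prob = predict_prob), class = "pp_classifier")
}

#' Fit a calibration component
#'
#' Sigmoid (Platt-style logistic regression on the score logit), isotonic
#' regression, or the identity. Calibrators have no hyper-parameters.
#'
#' @param name `"sigmoid"`, `"isotonic"` or `"none"`.
#' @param scores raw classifier scores on the calibration split.
#' @param y binary outcomes on the calibration split.
#' @return object with a `$calibrate(scores)` closure.
#' @export
fit_calibrator <- function(name, scores = NULL, y = NULL) {
  calibrate <- switch(name,
    none = function(s) s,
    sigmoid = {
      if (length(unique(y)) < 2) function(s) s else {
        z <- pp_logit(scores)
        fit <- suppressWarnings(stats::glm(y ~ z, family = stats::binomial()))
        function(s) as.numeric(stats::predict(fit, data.frame(z = pp_logit(s)),
                                              type = "response"))
      }
    },
    isotonic = {
      if (length(unique(y)) < 2) function(s) s else {
        o <- order(scores)
        iso <- stats::isoreg(scores[o], y[o])
        xs <- iso$x; ys <- iso$yf
        # collapse tied abscissae so approxfun gets strictly increasing knots
        agg <- tapply(ys, xs, mean)
        fn <- stats::approxfun(as.numeric(names(agg)), as.numeric(agg), rule = 2,
                               ties = "ordered")
        function(s) pmin(pmax(fn(s), 0), 1)
      }
    },
    pp_stop("pp_unknown_component", sprintf("unknown calibrator '%s'", name))
  )
  structure(list(name = name, calibrate = calibrate), class = "pp_calibrator")
}
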