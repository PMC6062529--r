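make_schema <- function() {
  reg <- small_registry(clfs = c("logistic", "random_forest"),
                        procs = c("none", "pca"))
  list(reg = reg,
       schema = encode_schema(reg, c("feature_processing", "classification")))
}

test_that("the mixed kernel behaves like a covariance", {
  sc <- make_schema()
  reg <- sc$reg
  p <- list(var = 0.5, lengthscale = 0.7, catweight = 1.5, noise = 1e-4)
  a <- encode_config(sc$schema, pipeline_config(reg, "mean", "none", "logistic", "none"))
  b <- encode_config(sc$schema, pipeline_config(reg, "mean", "pca", "random_forest", "none",
                                                classifier_params = list(num_trees = 500)))
  expect_equal(kernel(a, a, p), p$var)       # k(x,x) = signal variance
  expect_equal(kernel(a, b, p), kernel(b, a, p))
  # fully disjoint categorical blocks vanish as the overlap weight grows
  p_inf <- p; p_inf$catweight <- 1e6
  expect_lt(kernel(a, b, p_inf), 1e-12)
  # 3-point Gram is positive semidefinite
  cc <- encode_config(sc$schema, pipeline_config(reg, "mean", "pca", "logistic", "none"))
  K <- outer(1:3, 1:3, Vectorize(function(i, j)
    kernel(list(a, b, cc)[[i]], list(a, b, cc)[[j]], p)))
  expect_true(all(eigen(K, symmetric = TRUE, only.values = TRUE)$values > -1e-10))
})

test_that("the GP posterior interpolates and matches a direct solve", {
  sc <- make_schema()
  reg <- sc$reg
  sur <- new_surrogate(sc$schema,
                       list(var = 0.25, lengthscale = 0.5, catweight = 1,
                            noise = 1e-9))
  a <- encode_config(sc$schema, pipeline_config(reg, "mean", "none", "logistic", "none"))
  b <- encode_config(sc$schema, pipeline_config(reg, "mean", "pca", "logistic", "none",
                                                processor_params = list(n_components = 5)))
  # prior: mean zero, sd = sqrt(signal variance)
  pr <- posterior(sur, a)
  expect_equal(pr$mu, 0)
  expect_equal(pr$sd, 0.5)
  # one (nearly) noise-free observation: interpolation
  sur1 <- surrogate_add(sur, a, 0.62)
  p1 <- posterior(sur1, a)
  expect_equal(p1$mu, 0.62, tolerance = 1e-6)
  expect_lt(p1$sd, 1e-3)
  expect_lt(p1$sd^2, 1e-6 * sur$params$var)  # posterior var << prior var
  # two observations: agree with an explicit 2x2 linear-algebra oracle
  sur2 <- surrogate_add(sur1, b, 0.4)
  q <- encode_config(sc$schema, pipeline_config(reg, "mean", "pca", "logistic", "none",
                                                processor_params = list(n_components = 20)))
  post <- posterior(sur2, q)
  pp <- sur2$params
  K <- matrix(c(kernel(a, a, pp), kernel(a, b, pp),
                kernel(b, a, pp), kernel(b, b, pp)), 2) +
    diag(pp$noise + 1e-8, 2)
  ks <- c(kernel(q, a, pp), kernel(q, b, pp))
  ybar <- mean(c(0.62, 0.4))  # centered zero-mean GP
  mu_oracle <- ybar + drop(ks %*% solve(K, c(0.62, 0.4) - ybar))
  sd_oracle <- sqrt(pp$var - drop(ks %*% solve(K, ks)))
  expect_equal(post$mu, mu_oracle, tolerance = 1e-10)
  expect_equal(post$sd, sd_oracle, tolerance = 1e-6)
})

test_that("the acquisition is the optimistic bound", {
  expect_equal(acquisition(0.4, 0.2, 0), 0.4)
  expect_equal(acquisition(0.5, 0.1, 2), 0.7)
  sig <- seq(0, 1, by = 0.1)
  expect_true(all(diff(acquisition(0.3, sig, 1.5)) >= 0))
  expect_error(acquisition(0.3, -0.1, 1))
})

test_that("proposals exploit the posterior and respect the seed", {
  reg <- small_registry(clfs = "logistic")
  schema <- encode_schema(reg, c("feature_processing", "classification"))
  sur <- new_surrogate(schema)
  # one-point space: that point is proposed
  set.seed(1)
  prop <- propose_next(sur, reg, pool_size = 10)
  expect_equal(prop$classifier, "logistic")
  # with kappa = 0, the proposal sits in the high-utility region once the
  # posterior mean is informative (one high and one low observation)
  reg2 <- small_registry(clfs = c("logistic", "random_forest"))
  schema2 <- encode_schema(reg2, c("feature_processing", "classification"))
  sur2 <- new_surrogate(schema2, list(var = 0.04, lengthscale = 0.5,
                                      catweight = 2, noise = 1e-6))
  hi <- pipeline_config(reg2, "mean", "none", "random_forest", "none")
  lo <- pipeline_config(reg2, "mean", "none", "logistic", "none")
  sur2 <- surrogate_add(sur2, encode_config(schema2, hi), 0.9)
  sur2 <- surrogate_add(sur2, encode_config(schema2, lo), 0.2)
  set.seed(2)
  pool_prop <- propose_next(sur2, reg2, pool_size = 400, kappa = 0)
  expect_equal(pool_prop$classifier, "random_forest")
  set.seed(3); p1 <- propose_next(sur2, reg2, pool_size = 50)
  set.seed(3); p2 <- propose_next(sur2, reg2, pool_size = 50)
  expect_identical(serialize_config(p1), serialize_config(p2))
})

test_that("the best explored utility never decreases along the trace", {
  reg <- small_registry(clfs = c("logistic", "naive_bayes"),
                        procs = c("none", "standardize"))
  land <- planted_landscape(reg, list(classifier = "naive_bayes",
                                      processor = "standardize"), margin = 0.1)
  ds <- make_separable(40, 1)
  bo <- optimize_pipelines(ds, reg, budget = 12, seed = 5,
                           utility_fn = land$utility_fn, pool_size = 60)
  expect_true(all(diff(bo$trace$best_so_far) >= 0))
  expect_equal(nrow(bo$trace), 12)
  # budget 1: a single random probe
  bo1 <- optimize_pipelines(ds, reg, budget = 1, seed = 5,
                            utility_fn = land$utility_fn)
  expect_equal(nrow(bo1$trace), 1)
  expect_true(bo1$trace$random_probe[1])
})

test_that("decoupled search equals joint exhaustive search for additive utility", {
  reg <- build_default_registry(list(
    imputation = c("mean", "median"),
    feature_processing = c("none", "standardize"),
    classification = c("logistic", "naive_bayes"),
    calibration = c("none", "sigmoid")))
  vals <- list(imputation = c(mean = 0.02, median = 0.08),
               feature_processing = c(none = 0.05, standardize = 0.01),
               classification = c(logistic = 0.3, naive_bayes = 0.42),
               calibration = c(none = 0.07, sigmoid = 0.01))
  additive <- function(cfg)
    vals$imputation[[cfg$imputer]] + vals$feature_processing[[cfg$processor]] +
    vals$classification[[cfg$classifier]] + vals$calibration[[cfg$calibrator]]
  # oracle: enumerate all 16 joint pipelines
  grid <- expand.grid(i = names(vals$imputation), f = names(vals$feature_processing),
                      m = names(vals$classification), c = names(vals$calibration),
                      stringsAsFactors = FALSE)
  joint <- apply(grid, 1, function(r)
    vals$imputation[[r["i"]]] + vals$feature_processing[[r["f"]]] +
      vals$classification[[r["m"]]] + vals$calibration[[r["c"]]])
  best_joint <- grid[which.max(joint), ]
  ds <- make_separable(40, 1)
  bo <- optimize_pipelines(ds, reg, budget = 25, seed = 7,
                           utility_fn = additive, pool_size = 100)
  expect_equal(bo$best_config$classifier, best_joint$m)
  expect_equal(bo$best_config$processor, best_joint$f)
  expect_equal(bo$best_imputer$name, best_joint$i)
  expect_equal(bo$best_calibrator$name, best_joint$c)
})
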