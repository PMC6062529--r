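test_that("generated prevalence lands in the binomial envelope", {
  spec <- generator_spec(n = 4064, prevalence = 0.094, seed = 7, n_noise = 0)
  rec <- generate_registry(spec)
  ev <- sum(label_outcome(rec))
  bounds <- qbinom(c(0.005, 0.995), 4064, 0.094)
  expect_gte(ev, bounds[1])
  expect_lte(ev, bounds[2])
  # exact-event planting hits the count exactly
  spec2 <- generator_spec(n = 1000, prevalence = 0.094, exact_events = 94,
                          seed = 7, n_noise = 0)
  expect_equal(sum(label_outcome(generate_registry(spec2))), 94)
})

test_that("the generator is deterministic and honors the missingness profile", {
  spec <- generator_spec(n = 300, seed = 5, n_noise = 3)
  a <- generate_registry(spec)
  b <- generate_registry(spec)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_registry_csv(a, f1); write_registry_csv(b, f2)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical CSV
  # observed missingness near the configured spirometric rates
  expect_lt(abs(mean(is.na(a$fev1pp_ym4)) - 0.31), 0.08)
  expect_lt(abs(mean(is.na(a$fev1pp_y0)) - 0.044), 0.04)
  # zero missingness when the profile is switched off
  spec0 <- generator_spec(n = 200, seed = 5, n_noise = 0)
  spec0$miss_fev1[] <- 0
  spec0$miss_anthro[] <- 0
  expect_equal(sum(is.na(generate_registry(spec0))), 0)
})

test_that("severity-dependent missingness is more frequent among events", {
  spec <- generator_spec(n = 10000, seed = 9, n_noise = 0, mar_coef = 0.8)
  rec <- generate_registry(spec)
  y <- label_outcome(rec)
  miss_rate <- function(v) tapply(is.na(v), y, mean)
  r <- miss_rate(rec$fev1pp_ym4)
  expect_gt(r[["1"]], r[["0"]])
})

test_that("prevalence converges to the specification with n", {
  devs <- sapply(c(1000, 10000, 50000), function(n) {
    spec <- generator_spec(n = n, prevalence = 0.094, seed = 3, n_noise = 0)
    abs(mean(label_outcome(generate_registry(spec))) - 0.094)
  })
  expect_lt(devs[3], devs[1] + 0.005)
  expect_lt(devs[3], 0.005)
})

test_that("generated records pass cohort validation end to end", {
  spec <- generator_spec(n = 250, seed = 21, n_noise = 2,
                         n_pediatric = 20, n_prior_lt = 5, n_lost = 10)
  rec <- generate_registry(spec)
  out <- assemble_cohort(rec)
  expect_equal(out$flow$n_final, 250)
  expect_s3_class(out$dataset, "pp_dataset")
  expect_true(all(c("homozygous", "f508del", "g551d") %in%
                    colnames(out$dataset$X)))
})

test_that("planted landscapes expose their argmax and tolerate noise", {
  reg <- small_registry(clfs = c("logistic", "naive_bayes", "bagging"),
                        procs = c("none", "pca"))
  land <- planted_landscape(reg, list(classifier = "bagging", processor = "pca"),
                            margin = 0.1)
  expect_equal(unname(which.max(land$base)),
               which(names(land$base) == "bagging|pca"))
  gaps <- land$base["bagging|pca"] - land$base[names(land$base) != "bagging|pca"]
  expect_true(all(gaps >= 0.1 - 1e-12))
  # noiseless oracle returns the base exactly
  cfg <- pipeline_config(reg, "mean", "pca", "bagging", "none")
  expect_equal(land$utility_fn(cfg), unname(land$base[["bagging|pca"]]))
  # with noise, evaluation means recover the base (CLT)
  land_n <- planted_landscape(reg, list(classifier = "bagging", processor = "pca"),
                              margin = 0.1, noise_sd = 0.02)
  set.seed(2)
  evals <- replicate(100, land_n$utility_fn(cfg))
  expect_lt(abs(mean(evals) - land$base[["bagging|pca"]]), 0.01)
  # label-isomorphic registries give the same base spread
  reg2 <- small_registry(clfs = c("logistic", "naive_bayes", "xgboost"),
                         procs = c("none", "pca"))
  land2 <- planted_landscape(reg2, list(classifier = "xgboost", processor = "pca"),
                             margin = 0.1)
  expect_equal(sort(unname(land2$base)), sort(unname(land$base)))
})

test_that("planted-rule datasets honor noise, seed, and conflict checks", {
  rules <- planted_three_rules()
  pd1 <- planted_rules_dataset(rules, n = 800, noise = 0.05, seed = 3)
  pd2 <- planted_rules_dataset(rules, n = 800, noise = 0.05, seed = 3)
  expect_identical(pd1, pd2)
  confs <- vapply(rules, function(r)
    rule_stats(r, pd1$data, pd1$labels)$confidence, numeric(1))
  expect_true(all(abs(confs - 0.95) < 0.04))
  conflicting <- list(
    list(antecedent = list(list(variable = "a", level = "1")), consequent = "x"),
    list(antecedent = list(list(variable = "a", level = "1")), consequent = "y"))
  expect_error(planted_rules_dataset(conflicting, n = 50, seed = 1),
               class = "pp_conflicting_rules")
})
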