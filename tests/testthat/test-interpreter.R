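test_that("MDL discretization accepts informative cuts and rejects weak ones", {
  expect_equal(mdl_discretize(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 6.5)
  expect_length(mdl_discretize(c(1, 2, 3, 4), c(1, 1, 1, 1)), 0)
  expect_length(mdl_discretize(rep(2, 8), c(0, 1, 0, 1, 0, 1, 0, 1)), 0)
  # 12-point set where every candidate cut's gain falls below the MDL bound:
  # alternating labels carry almost no information at any cut
  x <- 1:12
  lab <- rep(c(0, 1), 6)
  ent <- function(l) { p <- table(l) / length(l); -sum(p[p > 0] * log2(p[p > 0])) }
  # hand evaluation of the Fayyad-Irani inequality at every cut position
  rejected <- sapply(1:11, function(k) {
    l <- lab[1:k]; r <- lab[(k + 1):12]
    gain <- ent(lab) - (k * ent(l) + (12 - k) * ent(r)) / 12
    delta <- log2(3^2 - 2) -
      (2 * ent(lab) - length(unique(l)) * ent(l) - length(unique(r)) * ent(r))
    gain <= (log2(11) + delta) / 12
  })
  expect_true(all(rejected))
  expect_length(mdl_discretize(x, lab), 0)
})

test_that("dataset discretization honors forced cuts and binary pass-through", {
  df <- data.frame(fev1pp_y0 = c(25, 35, 28, 60, NA),
                   oxygen = c(1, 0, 1, 0, 1),
                   weight = c(40, 55, 42, 70, 65))
  lab <- c("high", "low", "high", "low", "low")
  disc <- discretize_dataset(df, lab, forced_cuts = c(fev1pp_y0 = 30))
  expect_setequal(unique(na.omit(disc$fev1pp_y0)), c("<30", ">=30"))
  expect_equal(disc$fev1pp_y0[1:4], c("<30", ">=30", "<30", ">=30"))
  expect_true(is.na(disc$fev1pp_y0[5]))
  expect_equal(disc$oxygen, as.character(df$oxygen))  # binary unchanged
  # interval membership matches a row-by-row check
  cuts <- mdl_discretize(df$weight, lab)
  if (length(cuts)) {
    lev <- cut(df$weight, c(-Inf, cuts, Inf), right = FALSE, dig.lab = 6)
    expect_equal(disc$weight, as.character(lev))
  } else {
    expect_true(all(disc$weight == "all"))
  }
  expect_warning(discretize_dataset(df["weight"], lab,
                                    forced_cuts = c(weight = 500)),
                 "outside observed range")
})

test_that("MDL cuts are invariant to monotone transforms (as partitions)", {
  set.seed(4)
  x <- rnorm(200)
  lab <- as.integer(x + rnorm(200, 0, 0.4) > 0)
  cuts_x <- mdl_discretize(x, lab)
  cuts_t <- mdl_discretize(exp(x), lab)  # strictly monotone transform
  # same induced partition of the observations
  part_x <- findInterval(x, cuts_x)
  part_t <- findInterval(exp(x), cuts_t)
  expect_equal(part_x, part_t)
})

test_that("rule statistics count as the brute-force oracle does", {
  set.seed(12)
  df <- data.frame(a = sample(c("x", "y"), 20, TRUE),
                   b = sample(c("0", "1"), 20, TRUE),
                   stringsAsFactors = FALSE)
  lab <- sample(c("high", "low"), 20, TRUE)
  rule <- list(antecedent = list(list(variable = "a", level = "x"),
                                 list(variable = "b", level = "1")),
               consequent = "high")
  st <- rule_stats(rule, df, lab)
  m <- df$a == "x" & df$b == "1"
  expect_equal(st$support, mean(lab == "high"))
  expect_equal(st$confidence, sum(m & lab == "high") / sum(m))
  expect_equal(st$standard_support, mean(m & lab == "high"))
  # counting example: 10 matches, 8 with the label, prevalence 0.2
  df2 <- data.frame(a = c(rep("x", 10), rep("y", 40)), stringsAsFactors = FALSE)
  lab2 <- c(rep("high", 8), rep("low", 2), rep("high", 2), rep("low", 38))
  st2 <- rule_stats(list(antecedent = list(list(variable = "a", level = "x")),
                         consequent = "high"), df2, lab2)
  expect_equal(st2$confidence, 0.8)
  expect_equal(st2$support, 0.2)
  # no matching row: confidence undefined
  st3 <- rule_stats(list(antecedent = list(list(variable = "a", level = "zz")),
                         consequent = "high"), df2, lab2)
  expect_true(is.na(st3$confidence))
})

test_that("planted rules are recovered and reported stats re-check", {
  rules <- planted_three_rules()
  pd <- planted_rules_dataset(rules, n = 5000, noise = 0.05, seed = 3)
  mined <- mine_rules(pd$data, pd$labels, 0.2, 0.8, 3)
  expect_length(mined$rules, 3)
  got <- vapply(mined$rules, rule_antecedent_key, character(1))
  want <- vapply(rules, rule_antecedent_key, character(1))
  expect_setequal(got, want)
  # measured confidence near the planted 1 - noise
  for (r in mined$rules) {
    expect_gte(r$confidence, 0.9)
    st <- rule_stats(r, pd$data, pd$labels)  # brute-force re-check
    expect_equal(r$confidence, st$confidence)
    expect_equal(r$support, st$support)
  }
  # impossible thresholds yield an empty set
  expect_length(mine_rules(pd$data, pd$labels, 1.01, 1.01, 3)$rules, 0)
  # planted noise-free confidence is exactly 1
  pd0 <- planted_rules_dataset(rules, n = 1500, noise = 0, seed = 5)
  for (r in rules)
    expect_equal(rule_stats(r, pd0$data, pd0$labels)$confidence, 1)
})

test_that("risk-group assignment follows the half-open convention", {
  st <- risk_strata()
  expect_equal(assign_group(0.04, st), "low")
  expect_equal(assign_group(0.05, st), "moderate")  # boundary goes up
  expect_equal(assign_group(0.33, st), "high")
  expect_equal(assign_group(1.0, st), "very high")  # closed upper end
  expect_equal(assign_group(c(0, 0.049999, 0.5), st),
               c("low", "low", "very high"))
})

test_that("explain recovers the rule behind a threshold model, predictions untouched", {
  set.seed(8)
  n <- 400
  X <- cbind(marker = rnorm(n), other = rnorm(n))
  ens <- structure(list(
    members = list(list(config = NULL, fitted = structure(list(
      imputer = list(transform = function(X) X),
      processor = list(transform = function(X) X),
      classifier = list(predict_prob = function(X)
        ifelse(X[, 1] > 0, 0.6, 0.01)),
      calibrator = list(calibrate = function(s) s),
      schema = NULL), class = "pp_fitted"))),
    weights = 1), class = "pp_ensemble")
  before <- predict_ensemble(ens, X)
  st <- risk_strata(c(0.05, 0.33, 0.5))
  rules <- explain(ens, labeled_dataset(X, rep(c(0L, 1L), n / 2)), strata = st,
                   min_support = 0.2, min_confidence = 0.9, max_len = 2)
  after <- predict_ensemble(ens, X)
  expect_identical(before, after)  # the interpreter never alters predictions
  expect_gte(length(rules$rules), 2)
  for (r in rules$rules) {
    expect_length(r$antecedent, 1)  # single-condition rules suffice
    expect_equal(r$antecedent[[1]]$variable, "marker")
    expect_gte(r$confidence, 0.9)
  }
  # single-interval strata: every rule lands in that group with confidence 1
  one <- structure(list(breakpoints = numeric(0), labels = "all"),
                   class = "pp_strata")
  r1 <- explain(ens, labeled_dataset(X, rep(c(0L, 1L), n / 2)), strata = one,
                min_support = 0.2, min_confidence = 0.8, max_len = 1)
  for (r in r1$rules) {
    expect_equal(r$consequent, "all")
    expect_equal(r$confidence, 1)
  }
  # text rendering contract
  if (length(rules$rules))
    expect_match(format_rule(rules$rules[[1]]), "^IF .* THEN .* \\(c=.*s=.*\\)$")
})
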