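test_that("cohort assembly reproduces the printed patient flow", {
  spec <- generator_spec(n = 4064, prevalence = 0.094, exact_events = 382,
                         n_pediatric = 300, n_prior_lt = 114, n_lost = 354,
                         n_noise = 0, seed = 17)
  rec <- generate_registry(spec)
  out <- assemble_cohort(rec)
  expect_equal(out$flow$n_initial, 4532)
  expect_equal(out$flow$n_prior_transplant_excluded, 114)
  expect_equal(out$flow$n_lost_excluded, 354)
  expect_equal(out$flow$n_final, 4064)
  expect_equal(out$flow$n_events, 382)
  expect_equal(round(100 * out$flow$n_events / out$flow$n_final, 1), 9.4)
  # arithmetic identity
  expect_equal(out$flow$n_final,
               out$flow$n_initial - out$flow$n_prior_transplant_excluded -
                 out$flow$n_lost_excluded)
})

test_that("each filter removes exactly the handcrafted records it should", {
  rec <- handcrafted_records()
  out <- assemble_cohort(rec)
  # manual application: drop H02 (age 17), H03 (prior LT), H04 (lost)
  expect_setequal(out$records$id, c("H01", "H05", "H06"))
  expect_equal(out$flow$n_initial, 5)
  expect_equal(out$dataset$y, c(1L, 1L, 0L))
  # empty input: all-zero flow
  empty <- assemble_cohort(rec[0, ])
  expect_equal(empty$flow$n_final, 0)
  expect_equal(empty$flow$n_events, 0)
})

test_that("outcome and decline labels follow their definitions", {
  rec <- data.frame(death_3y = c(1, 0, 1, 0), lt_3y = c(0, 1, 1, 0))
  expect_equal(label_outcome(rec), c(1L, 1L, 1L, 0L))
  dec <- data.frame(fev1pp_y0 = c(35, 28, 35, 40),
                    fev1pp_h3 = c(25, 25, 25, NA),
                    lt_3y = c(0, 0, 1, 0))
  expect_equal(label_decline(dec), c(TRUE, FALSE, FALSE, NA))
})

test_that("the FEV1 referral criterion uses a strict threshold", {
  expect_equal(fev1_criterion(29.9), 1L)
  expect_equal(fev1_criterion(30.0), 0L)
  expect_equal(fev1_criterion(35, threshold = 40), 1L)
  expect_true(is.na(fev1_criterion(NA)))
  v <- c(25, 31, 29, NA, 50)
  expect_equal(sum(fev1_criterion(v), na.rm = TRUE), 2)
})

test_that("genotype encoding follows the class map and is symmetric", {
  g <- encode_genotype("F508del", "F508del")
  expect_equal(g[1, "homozygous"], c(homozygous = 1L))
  expect_equal(unname(g[1, c("f508del", "g551d")]), c(1L, 0L))
  expect_equal(unname(g[1, paste0("class", 1:6)]), c(0L, 1L, 1L, 0L, 0L, 1L))
  g2 <- encode_genotype("G551D", "G542X")
  expect_equal(unname(g2[1, c("homozygous", "f508del", "g551d")]), c(0L, 0L, 1L))
  expect_equal(unname(g2[1, paste0("class", 1:6)]), c(1L, 0L, 1L, 0L, 0L, 0L))
  expect_warning(g3 <- encode_genotype("mystery", "mystery"), "not in class map")
  expect_equal(unname(g3[1, ]), c(1L, rep(0L, 8)))
  # symmetric in allele order
  expect_equal(encode_genotype("G551D", "F508del"),
               suppressWarnings(encode_genotype("F508del", "G551D")))
})

test_that("Fisher exact reproduces printed baseline-table p-values", {
  expect_equal(round(fisher_exact(matrix(c(2027, 1655, 192, 190), 2, byrow = TRUE)), 3),
               0.075)  # gender
  expect_equal(round(fisher_exact(matrix(c(48, 3634, 11, 371), 2, byrow = TRUE)), 3),
               0.022)  # hemoptysis
  expect_equal(round(fisher_exact(matrix(c(123, 3559, 4, 378), 2, byrow = TRUE)), 3),
               0.012)  # nasal polyps
  expect_equal(fisher_exact(matrix(c(0, 5, 0, 7), 2)), 1)  # degenerate margin
  expect_equal(fisher_exact(matrix(c(3, 1, 1, 3), 2, byrow = TRUE)), 0.4857143,
               tolerance = 1e-6)
})

test_that("Fisher exact equals hypergeometric enumeration on small tables", {
  brute_fisher <- function(tb) {
    m <- rowSums(tb); k <- colSums(tb)
    p_obs <- dhyper(tb[1, 1], m[1], m[2], k[1])
    xs <- max(0, k[1] - m[2]):min(k[1], m[1])
    ps <- dhyper(xs, m[1], m[2], k[1])
    sum(ps[ps <= p_obs * (1 + 1e-7)])
  }
  set.seed(13)
  for (i in 1:30) {
    tb <- matrix(rpois(4, 4), 2)
    if (any(rowSums(tb) == 0) || any(colSums(tb) == 0)) next
    expect_equal(fisher_exact(tb), brute_fisher(tb), tolerance = 1e-7,
                 info = paste(tb, collapse = ","))
  }
})

test_that("Mann-Whitney test enumerates exactly and approximates at scale", {
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(mann_whitney_u(c(1, 2, 3), c(10, 11, 12)), 0.1)  # 2/20 arrangements
  expect_equal(mann_whitney_u(rep(2, 4), rep(2, 5)), 1)  # all identical
  set.seed(19)
  x <- rnorm(60); y <- rnorm(70, 0.4)
  p_pkg <- mann_whitney_u(x, y)
  p_ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  expect_lt(abs(p_pkg - p_ref), 0.01)
})

test_that("recalibration in the large matches the target and preserves ranks", {
  set.seed(23)
  s <- plogis(rnorm(500, -1))
  adj <- recalibrate_in_large(s, 0.094)
  expect_equal(mean(adj), 0.094, tolerance = 1e-8)
  expect_equal(order(adj), order(s))  # rank order preserved exactly
  # already at the target: unchanged
  s2 <- c(0.05, 0.1, 0.15)
  adj2 <- recalibrate_in_large(s2, 0.1)
  expect_equal(as.numeric(adj2), s2, tolerance = 1e-9)
  expect_equal(attr(adj2, "delta"), 0)
  # constant scores move to the target exactly
  adj3 <- recalibrate_in_large(rep(0.2, 10), 0.094)
  expect_equal(as.numeric(adj3), rep(0.094, 10), tolerance = 1e-8)
  expect_error(recalibrate_in_large(s, 1.2), class = "pp_bad_target")
})

test_that("logistic recalibration recovers slope 1 / intercept 0 on calibrated scores", {
  set.seed(29)
  n <- 10000
  s <- plogis(rnorm(n, -2, 1.2))
  y <- rbinom(n, 1, s)
  fit <- logistic_recalibration(s, y)
  expect_lt(abs(fit$slope - 1), 0.1)
  expect_lt(abs(fit$intercept), 0.1)
  expect_false(fit$separation)
  # adjusted scores are a monotone function of the inputs
  o <- order(s)
  expect_true(all(diff(fit$adjusted[o]) >= -1e-12))
  # uninformative constant scores: intercept-only fit at the prevalence
  fit0 <- logistic_recalibration(rep(0.3, 100), rep(c(0L, 1L), c(80, 20)))
  expect_equal(fit0$slope, 0)
  expect_equal(unique(fit0$adjusted), 0.2, tolerance = 1e-9)
})

test_that("single-variable importance separates signal from noise", {
  set.seed(31)
  n <- 300
  y <- rbinom(n, 1, 0.25)
  X <- cbind(oracle_copy = y + rnorm(n, 0, 0.01), pure_noise = rnorm(n))
  ds <- labeled_dataset(X, y)
  imp_sig <- single_variable_importance(ds, "oracle_copy", "auc_roc",
                                        seed = 3, budget = 4, k_folds = 3)
  imp_noise <- single_variable_importance(ds, "pure_noise", "auc_roc",
                                          seed = 3, budget = 4, k_folds = 3)
  expect_gte(imp_sig, 0.95)
  expect_lt(abs(imp_noise - 0.5), 0.12)
  pr_noise <- single_variable_importance(ds, "pure_noise", "auc_pr",
                                         seed = 3, budget = 4, k_folds = 3)
  expect_lt(abs(pr_noise - mean(y)), 0.12)
  # constant column sits at the chance level by definition
  Xc <- cbind(flat = rep(1, n), X)
  expect_equal(single_variable_importance(labeled_dataset(Xc, y), "flat",
                                          "auc_roc", seed = 1), 0.5)
})
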