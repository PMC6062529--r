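# Shared fixtures, built in code at test time.

# tiny separable two-class dataset: one informative column + noise
make_separable <- function(n = 120, seed = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  x1 <- y * 3 + rnorm(n, 0, 0.3)
  X <- cbind(signal = x1, noise1 = rnorm(n), noise2 = rnorm(n))
  labeled_dataset(X, y)
}

# small fast registry for search tests
small_registry <- function(clfs = c("logistic", "naive_bayes"),
                           procs = "none", imps = "mean",
                           cals = "none") {
  build_default_registry(list(imputation = imps, feature_processing = procs,
                              classification = clfs, calibration = cals))
}

# handcrafted registry records covering every cohort filter
handcrafted_records <- function() {
  base <- data.frame(
    id = sprintf("H%02d", 1:6),
    age = c(30, 17, 45, 52, 25, 60),
    prior_lt = c(0, 0, 1, 0, 0, 0),
    lost_fu = c(0, 0, 0, 1, 0, 0),
    death_3y = c(1, 0, 0, 0, 0, 0),
    lt_3y = c(0, 0, 0, 0, 1, 0),
    fev1pp_y0 = c(25, 80, 40, 55, 32, 90),
    fev1pp_ym1 = c(28, 82, 42, 56, 35, 91),
    fev1pp_ym2 = c(30, 84, 44, 57, 38, 92),
    fev1pp_ym3 = c(33, 85, 45, 58, 40, 93),
    fev1pp_ym4 = c(35, 86, 46, 59, 42, 94),
    fev1pp_h3 = c(NA, 78, 35, 50, 25, 88),
    allele_a = rep("F508del", 6),
    allele_b = c("F508del", "G551D", "other", "F508del", "G542X", "R117H"),
    oxygen_therapy = c(1, 0, 0, 0, 1, 0),
    stringsAsFactors = FALSE)
  base
}

# planted rules reused by interpreter tests
planted_three_rules <- function() {
  list(
    list(antecedent = list(list(variable = "fev1", level = "<30"),
                           list(variable = "oxy", level = "1")),
         consequent = "high"),
    list(antecedent = list(list(variable = "iv", level = "1")),
         consequent = "moderate"),
    list(antecedent = list(list(variable = "fev1", level = ">=30"),
                           list(variable = "oxy", level = "0")),
         consequent = "low"))
}

rule_antecedent_key <- function(rule) {
  paste(sort(vapply(rule$antecedent,
                    function(c) paste0(c$variable, "=", c$level), character(1))),
        collapse = "&")
}
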