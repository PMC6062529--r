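# Synthetic registry-like data. A single latent severity factor drives the
# spirometric trajectory, the comorbidity/treatment flags and the outcome,
# reproducing the heavy inter-correlation of the real risk factors (FEV1%,
# oxygen therapy, IV antibiotics). Oxygen therapy carries an outcome effect
# beyond FEV1 so that precision-oriented (AUC-PR) variable importance can
# diverge from discrimination-oriented (AUC-ROC) importance.

#' Specification of a synthetic registry cohort
#'
#' Defaults emulate the study cohort: n = 4064 analysis-eligible adults,
#' event prevalence 9.4%, spirometric-trajectory missingness rates
#' 31.0/20.0/15.5/6.2/4.4% (oldest to baseline year) and anthropometric
#' missingness 2.1/1.4/2.9%.
#'
#' @param n analysis-eligible adult records.
#' @param prevalence marginal event probability.
#' @param exact_events optional integer: plant exactly this many events
#'   (weighted sampling without replacement by model probability).
#' @param n_pediatric,n_prior_lt,n_lost extra records excluded by the
#'   age / prior-transplant / lost-to-follow-up filters.
#' @param n_noise uninformative standard-normal covariates appended to
#'   approximate the width of the real variable set.
#' @param effects outcome log-odds effects: `severity` (per latent SD),
#'   `oxygen` (on top of severity), `fev1_low` (FEV1% < 30 indicator).
#' @param mar_coef severity coefficient of the missingness log-odds
#'   (0 = missing completely at random).
#' @param seed integer seed; the specification object plus seed fully
#'   determines the output.
#' @return a `pp_genspec`.
#' @export
generator_spec <- function(n = 4064, prevalence = 0.094, exact_events = NULL,
                           n_pediatric = 0, n_prior_lt = 0, n_lost = 0,
                           n_noise = 60,
                           effects = list(severity = 2.4, oxygen = 1.2,
                                          fev1_low = 1.0),
                           mar_coef = 0, seed = 1) {
  stopifnot(prevalence > 0, prevalence < 1, n >= 1)
  structure(list(n = n, prevalence = prevalence, exact_events = exact_events,
                 n_pediatric = n_pediatric, n_prior_lt = n_prior_lt,
                 n_lost = n_lost, n_noise = n_noise, effects = effects,
                 mar_coef = mar_coef, seed = seed,
                 miss_fev1 = c(ym4 = 0.310, ym3 = 0.200, ym2 = 0.155,
                               ym1 = 0.062, y0 = 0.044),
                 miss_anthro = c(height = 0.021, weight = 0.014, bmi = 0.029)),
            class = "pp_genspec")
}

rbern <- function(logit) stats::rbinom(length(logit), 1, stats::plogis(logit))

clamp_fev <- function(x) pmin(pmax(x, 5), 180)

gen_block <- function(m, spec, role = c("cohort", "pediatric", "prior_lt", "lost")) {
  role <- match.arg(role)
  if (m == 0) return(NULL)
  Z <- stats::rnorm(m)
  age <- if (role == "pediatric") stats::runif(m, 2, 17.5)
         else pmin(18 + stats::rgamma(m, shape = 2, scale = 6), 80)
  height <- stats::rnorm(m, 167, 9)
  weight <- pmax(stats::rnorm(m, 62 - 3 * Z, 9), 30)
  bmi <- weight / (height / 100)^2
  fev_m4 <- clamp_fev(78 - 12 * Z + stats::rnorm(m, 0, 8))
  step <- function(prev) clamp_fev(prev - 2 - 1.6 * pmax(Z, 0) + stats::rnorm(m, 0, 5))
  fev_m3 <- step(fev_m4); fev_m2 <- step(fev_m3)
  fev_m1 <- step(fev_m2); fev_y0 <- step(fev_m1)
  fev1_l <- pmax(fev_y0 / 100 * stats::rnorm(m, 3.4, 0.35), 0.2)
  oxygen <- rbern(-3.2 + 1.7 * Z)
  flags <- cbind(
    oxygen_therapy = oxygen,
    iv_antibiotics = rbern(-0.5 + 1.1 * Z),
    inhaled_antibiotics = rbern(0.4 + 0.5 * Z),
    diabetes = rbern(-1.1 + 0.6 * Z),
    cfrd = rbern(-0.9 + 0.7 * Z),
    chronic_pseudomonas = rbern(0.2 + 0.6 * Z),
    b_cepacia = rbern(-3.0 + 0.5 * Z),
    niv = rbern(-3.1 + 1.3 * Z),
    dnase = rbern(0.3 + 0.6 * Z),
    oral_corticosteroids = rbern(-2.2 + 0.9 * Z),
    osteoporosis = rbern(-2.5 + 0.8 * Z),
    depression = rbern(-2.6 + 0.5 * Z))
  allele_pool <- c("F508del", "G551D", "R117H", "G542X", "621+1G->T",
                   "N1303K", "W1282X", "other")
  allele_freq <- c(0.70, 0.04, 0.03, 0.03, 0.02, 0.02, 0.02, 0.14)
  allele_a <- sample(allele_pool, m, replace = TRUE, prob = allele_freq)
  allele_b <- sample(allele_pool, m, replace = TRUE, prob = allele_freq)
  df <- data.frame(age = age, height = height, weight = weight, bmi = bmi,
                   fev1_l = fev1_l, fev1pp_y0 = fev_y0, fev1pp_ym1 = fev_m1,
                   fev1pp_ym2 = fev_m2, fev1pp_ym3 = fev_m3,
                   fev1pp_ym4 = fev_m4, flags,
                   allele_a = allele_a, allele_b = allele_b,
                   stringsAsFactors = FALSE)
  if (spec$n_noise > 0) {
    noise <- matrix(stats::rnorm(m * spec$n_noise), m, spec$n_noise)
    colnames(noise) <- sprintf("biomarker_%02d", seq_len(spec$n_noise))
    df <- cbind(df, noise)
  }
  df$.Z <- Z
  df$prior_lt <- as.integer(role == "prior_lt")
  df$lost_fu <- as.integer(role == "lost")
  df
}

#' Generate a synthetic registry cohort
#'
#' @param spec a `pp_genspec` from [generator_spec()].
#' @return data frame of records in the cohort CSV dialect, with attribute
#'   `"latent"` holding the latent severity of the analysis-eligible block.
#' @export
generate_registry <- function(spec) {
  stopifnot(inherits(spec, "pp_genspec"))
  with_seed(spec$seed, {
    blocks <- list(gen_block(spec$n, spec, "cohort"),
                   gen_block(spec$n_pediatric, spec, "pediatric"),
                   gen_block(spec$n_prior_lt, spec, "prior_lt"),
                   gen_block(spec$n_lost, spec, "lost"))
    df <- do.call(rbind, Filter(Negate(is.null), blocks))
    Z <- df$.Z
    ef <- spec$effects
    lin <- ef$severity * Z + ef$oxygen * df$oxygen_therapy +
           ef$fev1_low * as.numeric(df$fev1pp_y0 < 30)
    # root-find the intercept so the analysis-eligible block hits the
    # target marginal prevalence
    eligible <- df$prior_lt == 0 & df$lost_fu == 0 & df$age >= 18
    g <- function(b0) mean(stats::plogis(b0 + lin[eligible])) - spec$prevalence
    if (g(-30) > 0 || g(30) < 0)
      pp_stop("pp_unattainable", "prevalence unattainable under the effect sizes")
    b0 <- stats::uniroot(g, c(-30, 30), tol = 1e-10)$root
    p <- stats::plogis(b0 + lin)
    if (!is.null(spec$exact_events)) {
      k <- spec$exact_events
      ev <- rep(0L, nrow(df))
      idx <- which(eligible)
      pick <- sample(idx, k, prob = p[idx])
      ev[pick] <- 1L
    } else {
      ev <- stats::rbinom(nrow(df), 1, p)
    }
    # split the composite endpoint: most events are deaths, some transplants
    lt <- ev * stats::rbinom(nrow(df), 1, 0.3)
    death <- ev * as.integer(lt == 0 | stats::rbinom(nrow(df), 1, 0.1) == 1)
    df$death_3y <- as.integer(death == 1)
    df$lt_3y <- as.integer(lt == 1)
    # horizon FEV1%: continued decline, steeper for severe / event patients
    df$fev1pp_h3 <- clamp_fev(df$fev1pp_y0 - 6 - 5 * pmax(Z, 0) - 8 * ev +
                                stats::rnorm(nrow(df), 0, 6))
    df$id <- sprintf("P%06d", seq_len(nrow(df)))
    # missingness
    apply_missing <- function(col, rate) {
      if (rate <= 0) return(df[[col]])
      lg <- pp_logit(rep(rate, nrow(df))) + spec$mar_coef * Z
      miss <- rbern(lg) == 1
      out <- df[[col]]
      out[miss] <- NA
      out
    }
    for (k in names(spec$miss_fev1))
      df[[paste0("fev1pp_", k)]] <- apply_missing(paste0("fev1pp_", k),
                                                  spec$miss_fev1[[k]])
    for (k in names(spec$miss_anthro))
      df[[k]] <- apply_missing(k, spec$miss_anthro[[k]])
    latent <- Z
    df$.Z <- NULL
    ord <- c(registry_required_columns,
             setdiff(names(df), registry_required_columns))
    df <- df[, ord]
    attr(df, "latent") <- latent
    df
  })
}

#' Write / read the cohort CSV dialect
#'
#' Header row, empty cell = missing.
#'
#' @param records data frame of records.
#' @param path file path.
#' @export
write_registry_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_registry_csv
#' @export
read_registry_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
}

#' Planted utility landscape over a registry
#'
#' Assigns a deterministic base utility to every (classifier, processor)
#' combination, with `best_combo` exceeding all others by at least `margin`;
#' optional Gaussian evaluation noise. The true argmax is exposed for
#' assertions; the returned `utility_fn` plugs into
#' [optimize_pipelines()]'s `utility_fn`.
#'
#' @param registry a `pp_registry`.
#' @param best_combo list with `classifier` and `processor` names.
#' @param margin gap between the best and second-best combination.
#' @param noise_sd evaluation noise standard deviation.
#' @return list with `utility_fn`, `argmax`, `base` (named base utilities).
#' @export
planted_landscape <- function(registry, best_combo, margin = 0.1, noise_sd = 0) {
  clfs <- vapply(registry$classification, function(c) c$name, character(1))
  procs <- vapply(registry$feature_processing, function(c) c$name, character(1))
  if (!best_combo$classifier %in% clfs || !best_combo$processor %in% procs)
    pp_stop("pp_bad_combo", "best_combo not in registry")
  combos <- expand.grid(classifier = clfs, processor = procs,
                        stringsAsFactors = FALSE)
  key <- paste(combos$classifier, combos$processor, sep = "|")
  best_key <- paste(best_combo$classifier, best_combo$processor, sep = "|")
  base_top <- 0.8
  # deterministic, label-independent spread below (best - margin)
  i <- seq_len(nrow(combos))
  spread <- (i * 0.6180339887) %% 1
  base <- 0.35 + spread * (base_top - margin - 0.35)
  base[key == best_key] <- base_top
  names(base) <- key
  utility_fn <- function(config) {
    k <- paste(config$classifier, config$processor, sep = "|")
    u <- base[[k]]
    if (noise_sd > 0) u <- u + stats::rnorm(1, 0, noise_sd)
    u
  }
  list(utility_fn = utility_fn, argmax = best_combo, base = base)
}

#' Planted-rule dataset for interpreter recovery tests
#'
#' Each planted rule claims an equal share of the covered rows; a covered
#' row satisfies its rule's antecedent exactly and receives the rule's
#' consequent with probability `1 - noise`. Background rows are forced to
#' violate every planted antecedent and are labeled from the marginal group
#' distribution.
#'
#' @param rules list of rules, each `list(antecedent = list(list(variable,
#'   level)), consequent = group)`; antecedents must not conflict (identical
#'   antecedent, different consequent).
#' @param n rows.
#' @param noise probability a covered row gets a wrong label.
#' @param seed integer seed.
#' @param cover_frac total fraction of rows covered by planted rules.
#' @return list with `data` (discretized data frame), `labels`, `rules`.
#' @export
planted_rules_dataset <- function(rules, n = 5000, noise = 0, seed = 1,
                                  cover_frac = 0.75) {
  ante_key <- function(r) paste(sort(vapply(r$antecedent, function(c)
    paste0(c$variable, "=", c$level), character(1))), collapse = "&")
  keys <- vapply(rules, ante_key, character(1))
  cons <- vapply(rules, function(r) r$consequent, character(1))
  if (any(duplicated(keys) & !duplicated(paste(keys, cons))))
    pp_stop("pp_conflicting_rules", "identical antecedents with different consequents")
  vars <- unique(unlist(lapply(rules, function(r)
    vapply(r$antecedent, function(c) c$variable, character(1)))))
  levels_of <- lapply(vars, function(v) {
    lv <- unique(unlist(lapply(rules, function(r) {
      m <- vapply(r$antecedent, function(c) c$variable, character(1)) == v
      vapply(r$antecedent[m], function(c) c$level, character(1))
    })))
    c(lv, "other")
  })
  names(levels_of) <- vars
  groups <- unique(cons)
  with_seed(seed, {
    assign_rule <- sample(c(seq_along(rules), NA),
                          n, replace = TRUE,
                          prob = c(rep(cover_frac / length(rules), length(rules)),
                                   1 - cover_frac))
    data <- as.data.frame(lapply(vars, function(v)
      sample(levels_of[[v]], n, replace = TRUE)), col.names = vars,
      stringsAsFactors = FALSE)
    labels <- character(n)
    for (i in seq_len(n)) {
      r <- assign_rule[i]
      own_vars <- if (is.na(r)) character(0) else
        vapply(rules[[r]]$antecedent, function(c) c$variable, character(1))
      if (!is.na(r))
        for (cond in rules[[r]]$antecedent) data[i, cond$variable] <- cond$level
      # every row must violate every planted antecedent except its own,
      # so measured confidence equals the planted 1 - noise
      for (j in seq_along(rules)) {
        if (!is.na(r) && j == r) next
        matches <- all(vapply(rules[[j]]$antecedent, function(cond)
          data[i, cond$variable] == cond$level, logical(1)))
        if (!matches) next
        free <- Filter(function(cond) !cond$variable %in% own_vars,
                       rules[[j]]$antecedent)
        if (!length(free))
          pp_stop("pp_conflicting_rules",
                  sprintf("rule %d's antecedent is implied by rule %d's", j, r))
        cond <- free[[sample.int(length(free), 1)]]
        data[i, cond$variable] <- sample(
          setdiff(levels_of[[cond$variable]], cond$level), 1)
      }
      if (!is.na(r)) {
        wrong <- setdiff(groups, rules[[r]]$consequent)
        labels[i] <- if (length(wrong) && stats::runif(1) < noise)
          sample(wrong, 1)
        else rules[[r]]$consequent
      } else {
        labels[i] <- sample(groups, 1)
      }
    }
    list(data = data, labels = labels, rules = rules)
  })
}
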