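# Risk strata and the associative-classifier interpreter: mines
# class-association rules "C1 AND ... AND Cl => risk group" against the
# ensemble's own risk-group assignments. The interpreter explains
# predictions; it never alters them.

#' Define risk strata over [0, 1]
#'
#' Ordered breakpoints partition `[0, 1]` into half-open intervals
#' `[0, r1), [r1, r2), ..., [r_{M-1}, 1]` (the last interval is closed).
#' The default strata divide the population into low (<5%), moderate
#' (5-30%), high (30-50%) and very-high (>50%) risk groups.
#'
#' @param breakpoints strictly increasing values in (0, 1).
#' @param labels one label per interval (`length(breakpoints) + 1`).
#' @return a `pp_strata`.
#' @export
risk_strata <- function(breakpoints = c(0.05, 0.33, 0.5),
                        labels = NULL) {
  stopifnot(all(diff(breakpoints) > 0), all(breakpoints > 0 & breakpoints < 1))
  m <- length(breakpoints) + 1
  if (is.null(labels))
    labels <- if (m == 4) c("low", "moderate", "high", "very high")
              else paste0("group", seq_len(m))
  stopifnot(length(labels) == m)
  structure(list(breakpoints = breakpoints, labels = labels), class = "pp_strata")
}

#' Assign a risk score to its stratum
#'
#' Half-open convention: a score equal to a breakpoint belongs to the upper
#' interval; 1.0 falls in the last (closed) group.
#'
#' @param score risk score(s) in `[0, 1]`.
#' @param strata a `pp_strata`.
#' @return character vector of group labels.
#' @export
assign_group <- function(score, strata) {
  stopifnot(all(score >= 0 & score <= 1))
  idx <- findInterval(score, c(0, strata$breakpoints), rightmost.closed = FALSE)
  strata$labels[idx]
}

match_antecedent <- function(antecedent, data) {
  m <- rep(TRUE, nrow(data))
  for (cond in antecedent)
    m <- m & !is.na(data[[cond$variable]]) & data[[cond$variable]] == cond$level
  m
}

#' Support and confidence of an association rule
#'
#' Confidence is the fraction of antecedent-matching rows whose risk group
#' equals the consequent. Support follows the group-prevalence definition
#' (the prevalence of the consequent risk group); the conventional
#' antecedent-and-consequent support is reported alongside as
#' `standard_support`.
#'
#' @param rule list with `antecedent` (list of `list(variable, level)`) and
#'   `consequent` (group label).
#' @param data discretized covariate data frame.
#' @param labels risk-group label per row.
#' @return list with `support`, `confidence`, `standard_support`, `n_match`.
#' @export
rule_stats <- function(rule, data, labels) {
  m <- match_antecedent(rule$antecedent, data)
  hit <- m & labels == rule$consequent
  list(support = mean(labels == rule$consequent),
       confidence = if (!any(m)) NA_real_ else sum(hit) / sum(m),
       standard_support = mean(hit),
       n_match = sum(m))
}

#' Mine class-association rules by greedy antecedent growth
#'
#' For every risk group whose prevalence meets `min_support`, antecedents
#' are grown greedily one condition at a time (the condition maximizing
#' confidence; ties broken by higher standard support, then
#' lexicographically) up to `max_len` conditions; the shortest antecedent
#' along the path meeting both thresholds is emitted (longer,
#' antecedent-subsumed rules are dropped).
#'
#' @param data discretized covariate data frame.
#' @param labels risk-group label per row.
#' @param min_support minimum group prevalence (default 0.2).
#' @param min_confidence minimum rule confidence (default 0.8).
#' @param max_len maximum antecedent length (default 3).
#' @return a `pp_rules` object (possibly empty).
#' @export
mine_rules <- function(data, labels, min_support = 0.2, min_confidence = 0.8,
                       max_len = 3) {
  labels <- as.character(labels)
  conds <- list()
  for (nm in names(data)) {
    lv <- sort(unique(data[[nm]][!is.na(data[[nm]])]))
    for (l in lv) conds[[length(conds) + 1]] <- list(variable = nm, level = l)
  }
  rules <- list()
  for (grp in sort(unique(labels))) {
    if (mean(labels == grp) < min_support) next
    ante <- list()
    used <- character(0)
    for (k in seq_len(max_len)) {
      best <- NULL
      for (cond in conds) {
        id <- paste0(cond$variable, "=", cond$level)
        if (cond$variable %in% used) next
        cand <- c(ante, list(cond))
        st <- rule_stats(list(antecedent = cand, consequent = grp), data, labels)
        if (is.na(st$confidence)) next
        better <- is.null(best) ||
          st$confidence > best$st$confidence + 1e-12 ||
          (abs(st$confidence - best$st$confidence) <= 1e-12 &&
             (st$standard_support > best$st$standard_support + 1e-12 ||
              (abs(st$standard_support - best$st$standard_support) <= 1e-12 &&
                 id < best$id)))
        if (better) best <- list(cond = cond, st = st, id = id)
      }
      if (is.null(best)) break
      ante <- c(ante, list(best$cond))
      used <- c(used, best$cond$variable)
      if (best$st$confidence >= min_confidence && best$st$support >= min_support) {
        rules[[length(rules) + 1]] <- list(
          antecedent = ante, consequent = grp,
          confidence = best$st$confidence, support = best$st$support,
          standard_support = best$st$standard_support, n_match = best$st$n_match)
        break  # shorter rule subsumes any longer extension
      }
    }
  }
  structure(list(rules = rules, min_support = min_support,
                 min_confidence = min_confidence, max_len = max_len),
            class = "pp_rules")
}

format_rule <- function(rule) {
  conds <- vapply(rule$antecedent,
                  function(c) paste0(c$variable, " = ", c$level), character(1))
  sprintf("IF %s THEN %s (c=%.3f, s=%.3f)",
          paste(conds, collapse = " AND "), rule$consequent,
          rule$confidence, rule$support)
}

#' @export
print.pp_rules <- function(x, ...) {
  cat(sprintf("association rules (confidence >= %.2f, support >= %.2f): %d rule(s)\n",
              x$min_confidence, x$min_support, length(x$rules)))
  for (r in x$rules) cat(" ", format_rule(r), "\n")
  invisible(x)
}

#' Export rules as a data frame / CSV
#'
#' @param rules a `pp_rules`.
#' @param path optional CSV path; when given, the table is also written there.
#' @return data frame with pipe-delimited antecedents, consequent,
#'   confidence, support and standard support.
#' @export
rules_table <- function(rules, path = NULL) {
  df <- if (!length(rules$rules)) {
    data.frame(antecedent = character(0), consequent = character(0),
               confidence = numeric(0), support = numeric(0),
               standard_support = numeric(0))
  } else {
    do.call(rbind, lapply(rules$rules, function(r) data.frame(
      antecedent = paste(vapply(r$antecedent,
                                function(c) paste0(c$variable, "=", c$level),
                                character(1)), collapse = "|"),
      consequent = r$consequent, confidence = r$confidence,
      support = r$support, standard_support = r$standard_support)))
  }
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}

#' Explain a fitted model's risk predictions
#'
#' Predicts on the dataset, assigns risk groups, discretizes the covariates
#' against those groups (MDL cuts, with the FEV1%-predicted 30% referral
#' threshold forced where such a column is named), and mines association
#' rules. The predictions themselves are returned untouched.
#'
#' @param object a fitted model (`pp_ensemble` or `progpipe`).
#' @param ... passed to methods.
#' @export
explain <- function(object, ...) UseMethod("explain")

#' @rdname explain
#' @param dataset a `pp_dataset` (or data frame of covariates).
#' @param strata a `pp_strata` (default [risk_strata()]).
#' @param min_support,min_confidence,max_len rule thresholds.
#' @param forced_cuts named numeric vector of forced discretization
#'   thresholds (e.g. `c(fev1pp_y0 = 30)`).
#' @export
explain.pp_ensemble <- function(object, dataset, strata = risk_strata(),
                                min_support = 0.2, min_confidence = 0.8,
                                max_len = 3, forced_cuts = c(), ...) {
  X <- if (inherits(dataset, "pp_dataset")) dataset$X else as.matrix(dataset)
  scores <- predict_ensemble(object, X)
  groups <- assign_group(scores, strata)
  disc <- discretize_dataset(as.data.frame(X), groups, forced_cuts)
  rules <- mine_rules(disc, groups, min_support, min_confidence, max_len)
  rules$scores <- scores
  rules$groups <- groups
  rules
}
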