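# Study-design machinery for registry-style cohorts: assembly filters in
# flow-chart order, outcome labels (composite endpoint and pulmonary
# decline), CFTR genotype encoding, and the FEV1%-predicted referral
# baseline.

#' Required record columns of the cohort CSV dialect
#'
#' Header row; empty cell = missing. `fev1pp_y0` is the baseline FEV1%
#' predicted, `fev1pp_ym1..ym4` the four prior years, `fev1pp_h3` the value
#' at the 3-year horizon (for the decline label). Any additional numeric
#' columns are treated as free covariates.
#' @export
registry_required_columns <- c(
  "id", "age", "prior_lt", "lost_fu", "death_3y", "lt_3y",
  "fev1pp_y0", "fev1pp_ym1", "fev1pp_ym2", "fev1pp_ym3", "fev1pp_ym4",
  "fev1pp_h3", "allele_a", "allele_b")

validate_records <- function(records) {
  miss <- setdiff(registry_required_columns, names(records))
  if (length(miss))
    pp_stop("pp_bad_records", paste("missing columns:", paste(miss, collapse = ", ")))
  fcols <- grep("^fev1pp", names(records), value = TRUE)
  for (f in fcols) {
    v <- records[[f]]
    if (any(!is.na(v) & (v <= 0 | v >= 200)))
      pp_stop("pp_bad_records", sprintf("%s outside (0, 200)", f))
  }
  if (any(records$age < 0)) pp_stop("pp_bad_records", "negative age")
  invisible(TRUE)
}

#' Composite-endpoint outcome label
#'
#' 1 if the patient died or underwent a lung transplant within the horizon
#' (a transplant followed by death still counts once).
#'
#' @param records data frame with `death_3y` and `lt_3y` flags.
#' @param horizon_years kept for the record; the flags already encode the
#'   3-year horizon of the registry extract.
#' @return integer 0/1 vector.
#' @export
label_outcome <- function(records, horizon_years = 3) {
  as.integer(records$death_3y == 1 | records$lt_3y == 1)
}

#' Pulmonary-decline label
#'
#' TRUE when baseline FEV1% predicted exceeded 30, the horizon value fell
#' below 30, and no transplant occurred; NA (excluded from decline analyses)
#' when the horizon value is missing.
#'
#' @param records data frame with `fev1pp_y0`, `fev1pp_h3`, `lt_3y`.
#' @return logical vector with NA for unobserved horizons.
#' @export
label_decline <- function(records) {
  ifelse(is.na(records$fev1pp_h3), NA,
         records$fev1pp_y0 > 30 & records$fev1pp_h3 < 30 & records$lt_3y == 0)
}

#' FEV1%-predicted referral criterion
#'
#' The guideline baseline: flag a patient once FEV1% predicted drops below
#' the threshold (strict `<`, default 30%).
#'
#' @param fev1_pct FEV1% predicted value(s).
#' @param threshold referral threshold (default 30).
#' @return integer 0/1, NA where the measurement is missing.
#' @export
fev1_criterion <- function(fev1_pct, threshold = 30) {
  ifelse(is.na(fev1_pct), NA_integer_, as.integer(fev1_pct < threshold))
}

default_cftr_classes <- function() {
  path <- system.file("extdata", "cftr_classes.csv", package = "progpipe")
  if (path == "") path <- "inst/extdata/cftr_classes.csv"
  utils::read.csv(path, stringsAsFactors = FALSE)
}

normalize_mutation <- function(m) {
  m <- trimws(as.character(m))
  up <- toupper(m)
  up[up %in% c("DF508", "DELTAF508", "ΔF508", "F508DEL")] <- "F508DEL"
  up
}

#' Encode a CFTR genotype as 9 binary features
#'
#' Flags: homozygous (both alleles carry the same mutation), carriage of
#' F508del, carriage of G551D, and one flag per functional class I-VI (set
#' when any carried mutation belongs to that class). Mutations absent from
#' the class map contribute no class flags (with a warning).
#'
#' @param allele_a,allele_b mutation names (vectors of equal length).
#' @param class_map data frame with `mutation` and `class` columns; default
#'   is the bundled exemplary class table.
#' @return matrix with columns `homozygous`, `f508del`, `g551d`,
#'   `class1..class6`.
#' @export
encode_genotype <- function(allele_a, allele_b, class_map = default_cftr_classes()) {
  a <- normalize_mutation(allele_a); b <- normalize_mutation(allele_b)
  map_mut <- normalize_mutation(class_map$mutation)
  known <- unique(map_mut)
  unknown <- setdiff(unique(c(a, b)), known)
  if (length(unknown))
    warning(paste("mutations not in class map:", paste(unknown, collapse = ", ")))
  classes_of <- function(m) unique(class_map$class[map_mut == m])
  n <- length(a)
  out <- matrix(0L, n, 9,
                dimnames = list(NULL, c("homozygous", "f508del", "g551d",
                                        paste0("class", 1:6))))
  for (i in seq_len(n)) {
    out[i, "homozygous"] <- as.integer(a[i] == b[i])
    out[i, "f508del"] <- as.integer("F508DEL" %in% c(a[i], b[i]))
    out[i, "g551d"] <- as.integer("G551D" %in% c(a[i], b[i]))
    cl <- unique(c(classes_of(a[i]), classes_of(b[i])))
    out[i, 3 + cl] <- 1L
  }
  out
}

#' Assemble an analysis cohort from registry records
#'
#' Filters are applied in flow-chart order: age at baseline, prior
#' transplant, lost to follow-up. The composite outcome label is attached
#' and genotype strings are expanded into the 9 binary features; `id`,
#' filter flags, outcome fields and the horizon FEV1% are excluded from the
#' covariate matrix.
#'
#' @param records data frame in the cohort CSV dialect.
#' @param min_age age filter threshold in years (default 18).
#' @param age_inclusive keep patients aged exactly `min_age` (default TRUE).
#' @param horizon_years outcome horizon (default 3).
#' @return list with `dataset` (a `pp_dataset`), `flow` (a `pp_flow`), and
#'   the filtered `records`.
#' @export
assemble_cohort <- function(records, min_age = 18, age_inclusive = TRUE,
                            horizon_years = 3) {
  if (nrow(records) == 0) {
    flow <- flow_counts(0, 0, 0, 0)
    return(list(dataset = NULL, flow = flow, records = records))
  }
  validate_records(records)
  adult <- if (age_inclusive) records$age >= min_age else records$age > min_age
  r1 <- records[adult, , drop = FALSE]
  prior <- r1$prior_lt == 1
  r2 <- r1[!prior, , drop = FALSE]
  lost <- r2$lost_fu == 1
  r3 <- r2[!lost, , drop = FALSE]
  y <- label_outcome(r3, horizon_years)
  flow <- flow_counts(nrow(r1), sum(prior), sum(lost), sum(y))
  gen <- suppressWarnings(encode_genotype(r3$allele_a, r3$allele_b))
  drop_cols <- c("id", "age", "prior_lt", "lost_fu", "death_3y", "lt_3y",
                 "fev1pp_h3", "allele_a", "allele_b")
  covars <- r3[, setdiff(names(r3), drop_cols), drop = FALSE]
  covars <- covars[, vapply(covars, is.numeric, logical(1)), drop = FALSE]
  X <- cbind(age = r3$age, as.matrix(covars), gen)
  list(dataset = labeled_dataset(X, y), flow = flow, records = r3)
}

flow_counts <- function(n_initial, n_prior, n_lost, n_events) {
  structure(list(n_initial = n_initial,
                 n_prior_transplant_excluded = n_prior,
                 n_lost_excluded = n_lost,
                 n_final = n_initial - n_prior - n_lost,
                 n_events = n_events),
            class = "pp_flow")
}

#' @export
print.pp_flow <- function(x, ...) {
  cat(sprintf(paste0(
    "cohort flow\n",
    "  %6d patients passing the age filter\n",
    "  -%5d prior lung transplant\n",
    "  -%5d lost to follow-up\n",
    "  =%5d analysis cohort (%d events, prevalence %.1f%%)\n"),
    x$n_initial, x$n_prior_transplant_excluded, x$n_lost_excluded,
    x$n_final, x$n_events,
    if (x$n_final > 0) 100 * x$n_events / x$n_final else 0))
  invisible(x)
}
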