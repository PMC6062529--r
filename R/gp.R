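# Gaussian-process surrogate over pipeline configurations. The input space
# is mixed: a categorical block (component identities per stage) and a
# continuous block (hyper-parameters normalized to [0, 1], log-scaled
# dimensions normalized on the log scale; dimensions belonging to inactive
# components sit at the domain midpoint). The kernel is the product of a
# Matérn-5/2 kernel on the continuous block and an exponentiated-overlap
# kernel exp(-w * #mismatches) on the categorical block, so k(x, x) equals
# the signal variance and the Gram matrix is positive semidefinite.

#' Build the encoding schema for a set of pipeline stages
#'
#' @param registry a `pp_registry`.
#' @param stages which stages vary in this surrogate's input space.
#' @return a `pp_encoding` schema describing both blocks.
#' @export
encode_schema <- function(registry, stages) {
  dims <- list()
  for (st in stages) for (cs in registry[[st]]) for (h in cs$hyperparams) {
    dims[[length(dims) + 1]] <- list(stage = st, component = cs$name,
                                     name = h$name, kind = h$kind,
                                     lower = h$lower, upper = h$upper,
                                     levels = h$levels,
                                     log = isTRUE(h$log))
  }
  structure(list(stages = stages, dims = dims), class = "pp_encoding")
}

stage_slot <- function(config, stage) {
  switch(stage, imputation = config$imputer, feature_processing = config$processor,
         classification = config$classifier, calibration = config$calibrator)
}

stage_params <- function(config, stage) {
  switch(stage, imputation = config$imputer_params,
         feature_processing = config$processor_params,
         classification = config$classifier_params, calibration = list())
}

#' Encode a configuration as a point in a surrogate's input space
#'
#' @param schema a `pp_encoding` from [encode_schema()].
#' @param config a `pp_config`.
#' @return list with `cat` (character vector) and `cont` (numeric in `[0,1]`).
#' @export
encode_config <- function(schema, config) {
  cat_block <- vapply(schema$stages, function(st) stage_slot(config, st), character(1))
  cont <- vapply(schema$dims, function(d) {
    if (stage_slot(config, d$stage) != d$component) return(0.5)
    v <- stage_params(config, d$stage)[[d$name]]
    if (is.null(v)) return(0.5)
    if (d$kind == "categorical") {
      i <- match(v, d$levels)
      return(if (length(d$levels) > 1) (i - 1) / (length(d$levels) - 1) else 0.5)
    }
    if (d$log) {
      lo <- log(max(d$lower, 1e-12))
      (log(max(v, 1e-12)) - lo) / max(log(d$upper) - lo, 1e-12)
    } else {
      (v - d$lower) / max(d$upper - d$lower, 1e-12)
    }
  }, numeric(1))
  list(cat = unname(cat_block), cont = unname(cont))
}

matern52 <- function(r) (1 + sqrt(5) * r + 5 * r^2 / 3) * exp(-sqrt(5) * r)

#' Kernel between encoded configuration points
#'
#' @param a,b encoded points from [encode_config()] (same schema).
#' @param params kernel parameters: `var` (signal variance), `lengthscale`,
#'   `catweight` (categorical mismatch penalty).
#' @return scalar covariance; `kernel(a, a, params)` equals `params$var`.
#' @export
kernel <- function(a, b, params) {
  if (length(a$cat) != length(b$cat) || length(a$cont) != length(b$cont))
    pp_stop("pp_schema_mismatch", "encoded points use different schemas")
  r <- sqrt(sum((a$cont - b$cont)^2)) / params$lengthscale
  mism <- sum(a$cat != b$cat)
  params$var * matern52(r) * exp(-params$catweight * mism)
}

gram <- function(cont_a, cat_a, cont_b, cat_b, params) {
  # cont_*: n x d numeric; cat_*: n x m character
  na <- nrow(cont_a); nb <- nrow(cont_b)
  D2 <- outer(rowSums(cont_a^2), rep(1, nb)) +
        outer(rep(1, na), rowSums(cont_b^2)) - 2 * tcrossprod(cont_a, cont_b)
  D2[D2 < 0] <- 0
  R <- sqrt(D2) / params$lengthscale
  M <- matrix(0L, na, nb)
  if (ncol(cat_a) > 0)
    for (j in seq_len(ncol(cat_a)))
      M <- M + outer(cat_a[, j], cat_b[, j], "!=")
  params$var * matern52(R) * exp(-params$catweight * M)
}

default_gp_params <- function() {
  list(var = 0.04, lengthscale = 0.5, catweight = 1, noise = 1e-4)
}

#' Create an empty surrogate state
#'
#' @param schema a `pp_encoding`.
#' @param params kernel parameters (list with `var`, `lengthscale`,
#'   `catweight`, `noise`); defaults are refit from data during optimization.
#' @return a `pp_surrogate`.
#' @export
new_surrogate <- function(schema, params = default_gp_params()) {
  structure(list(schema = schema, params = params,
                 cont = matrix(numeric(0), 0, length(schema$dims)),
                 cat = matrix(character(0), 0, length(schema$stages)),
                 y = numeric(0), keys = character(0)),
            class = "pp_surrogate")
}

#' Add an observation to a surrogate
#'
#' @param surrogate a `pp_surrogate`.
#' @param enc encoded point.
#' @param value observed utility.
#' @param key optional identity key (duplicate keys are skipped).
#' @return updated surrogate.
#' @export
surrogate_add <- function(surrogate, enc, value, key = NULL) {
  if (!is.null(key) && key %in% surrogate$keys) return(surrogate)
  surrogate$cont <- rbind(surrogate$cont, enc$cont)
  surrogate$cat <- rbind(surrogate$cat, enc$cat)
  surrogate$y <- c(surrogate$y, value)
  surrogate$keys <- c(surrogate$keys, key %||% paste0("obs", length(surrogate$y)))
  surrogate
}

surrogate_chol <- function(surrogate, jitter = 1e-8) {
  n <- length(surrogate$y)
  K <- gram(surrogate$cont, surrogate$cat, surrogate$cont, surrogate$cat,
            surrogate$params) + diag(surrogate$params$noise + jitter, n)
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (!is.null(L)) return(L)
  for (i in 0:6) {
    L <- tryCatch(chol(K + diag(jitter * 10^i, n)), error = function(e) NULL)
    if (!is.null(L)) return(L)
  }
  pp_stop("pp_singular_gram", "Gram matrix singular even after jitter")
}

#' Gaussian-process posterior at encoded points
#'
#' Standard GP regression with observation noise; the prior mean is the
#' running mean of the observed utilities (zero with no observations).
#'
#' @param surrogate a `pp_surrogate`.
#' @param enc_list list of encoded points (or a single encoded point).
#' @param full_cov also return the posterior covariance matrix.
#' @return list with `mu`, `sd` (and `cov` when `full_cov`).
#' @export
gp_posterior <- function(surrogate, enc_list, full_cov = FALSE) {
  if (!is.null(enc_list$cont)) enc_list <- list(enc_list)
  m <- length(enc_list)
  Qc <- do.call(rbind, lapply(enc_list, function(e) e$cont))
  Qk <- do.call(rbind, lapply(enc_list, function(e) e$cat))
  p <- surrogate$params
  n <- length(surrogate$y)
  Kss <- gram(Qc, Qk, Qc, Qk, p)
  if (n == 0) {
    out <- list(mu = rep(0, m), sd = rep(sqrt(p$var), m))
    if (full_cov) out$cov <- Kss
    return(out)
  }
  # zero-mean GP on internally centered observations (the running mean is
  # restored on output), the usual stabilization of a GP(0, K) surrogate
  mu0 <- mean(surrogate$y)
  L <- surrogate_chol(surrogate)
  Ks <- gram(Qc, Qk, surrogate$cont, surrogate$cat, p)  # m x n
  alpha <- backsolve(L, forwardsolve(t(L), surrogate$y - mu0))
  V <- forwardsolve(t(L), t(Ks))                         # n x m
  mu <- mu0 + drop(Ks %*% alpha)
  cov <- Kss - crossprod(V)
  var_diag <- pmax(diag(cov), 0)
  out <- list(mu = mu, sd = sqrt(var_diag))
  if (full_cov) out$cov <- (cov + t(cov)) / 2
  out
}

#' @rdname gp_posterior
#' @param point a single encoded point.
#' @export
posterior <- function(surrogate, point) {
  p <- gp_posterior(surrogate, list(point))
  list(mu = p$mu[1], sd = p$sd[1])
}

gp_neg_loglik <- function(logpar, surrogate) {
  p <- list(var = exp(logpar[1]), lengthscale = exp(logpar[2]),
            catweight = exp(logpar[3]), noise = exp(logpar[4]))
  n <- length(surrogate$y)
  K <- gram(surrogate$cont, surrogate$cat, surrogate$cont, surrogate$cat, p) +
       diag(p$noise + 1e-8, n)
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(1e10)
  yc <- surrogate$y - mean(surrogate$y)
  a <- backsolve(L, forwardsolve(t(L), yc))
  as.numeric(0.5 * sum(yc * a) + sum(log(diag(L))) + 0.5 * n * log(2 * pi))
}

#' Refit kernel parameters by marginal-likelihood maximization
#'
#' @param surrogate a `pp_surrogate` with at least 3 observations.
#' @return surrogate with updated parameters.
#' @export
surrogate_fit_params <- function(surrogate) {
  if (length(surrogate$y) < 3) return(surrogate)
  start <- log(unlist(surrogate$params))
  lower <- log(c(var = 1e-6, lengthscale = 0.05, catweight = 0.05, noise = 1e-8))
  upper <- log(c(var = 4, lengthscale = 20, catweight = 20, noise = 0.25))
  fit <- tryCatch(
    stats::optim(pmin(pmax(start, lower), upper), gp_neg_loglik,
                 surrogate = surrogate, method = "L-BFGS-B",
                 lower = lower, upper = upper),
    error = function(e) NULL)
  if (is.null(fit)) return(surrogate)
  p <- exp(fit$par)
  surrogate$params <- list(var = p[["var"]], lengthscale = p[["lengthscale"]],
                           catweight = p[["catweight"]], noise = p[["noise"]])
  surrogate
}

#' Upper-confidence-bound acquisition
#'
#' `mu + kappa * sigma`: an optimistic bound on utility, so maximizing it
#' balances exploitation (high posterior mean) and exploration (high
#' posterior uncertainty).
#'
#' @param mu posterior mean(s).
#' @param sigma posterior standard deviation(s), nonnegative.
#' @param kappa exploration weight (default 2).
#' @return acquisition value(s).
#' @export
acquisition <- function(mu, sigma, kappa = 2) {
  stopifnot(all(sigma >= 0))
  mu + kappa * sigma
}
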