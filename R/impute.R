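# Imputation stage. Every imputer is fit on the training covariate matrix
# and returns a transform applicable to new rows with missing entries.
# Model-based imputers (EM, matrix completion, chained equations, iterative
# random forest) are implemented as lightweight standard algorithms on a
# numeric covariate matrix.

col_mode <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  tb <- table(x)
  as.numeric(names(tb)[which.max(tb)])
}

check_imputable <- function(X) {
  all_na <- vapply(seq_len(ncol(X)), function(j) all(is.na(X[, j])), logical(1))
  if (any(all_na))
    pp_stop("pp_all_missing",
            paste("column(s) entirely missing:",
                  paste(colnames(X)[all_na], collapse = ", ")))
  invisible(TRUE)
}

# Conditional-Gaussian fill-in: for each row, missing block = conditional
# mean given the observed block under N(mu, Sigma).
gaussian_conditional_impute <- function(X, mu, Sigma, ridge = 1e-6) {
  d <- ncol(X)
  Sr <- Sigma + diag(ridge * mean(diag(Sigma)) + 1e-12, d)
  for (i in seq_len(nrow(X))) {
    m <- which(is.na(X[i, ]))
    if (!length(m)) next
    o <- setdiff(seq_len(d), m)
    if (!length(o)) { X[i, m] <- mu[m]; next }
    W <- tryCatch(solve(Sr[o, o, drop = FALSE], t(Sr[m, o, drop = FALSE])),
                  error = function(e) NULL)
    X[i, m] <- if (is.null(W)) mu[m]
               else mu[m] + drop(crossprod(W, X[i, o] - mu[o]))
  }
  X
}

fit_imputer_em <- function(X, max_iter = 20, tol = 1e-4) {
  mu <- colMeans(X, na.rm = TRUE)
  Xf <- X
  for (j in seq_len(ncol(X))) Xf[is.na(X[, j]), j] <- mu[j]
  Sigma <- stats::cov(Xf)
  for (it in seq_len(max_iter)) {
    Xi <- gaussian_conditional_impute(X, mu, Sigma)
    mu_new <- colMeans(Xi)
    Sigma_new <- stats::cov(Xi)
    delta <- max(abs(mu_new - mu)) / (max(abs(mu)) + 1e-9)
    mu <- mu_new; Sigma <- Sigma_new
    if (delta < tol) break
  }
  list(mu = mu, Sigma = Sigma)
}

# Iterative soft-thresholded SVD completion (soft-impute style).
fit_imputer_softsvd <- function(X, rank = 3, shrink = 1, max_iter = 30, tol = 1e-4) {
  miss <- is.na(X)
  mu <- colMeans(X, na.rm = TRUE)
  sdv <- apply(X, 2, stats::sd, na.rm = TRUE); sdv[!is.finite(sdv) | sdv == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  Z[miss] <- 0
  for (it in seq_len(max_iter)) {
    sv <- svd(Z)
    dshr <- pmax(sv$d - shrink, 0)
    r <- min(rank, sum(dshr > 0), length(dshr))
    if (r < 1) { Zhat <- matrix(0, nrow(Z), ncol(Z)) } else {
      Zhat <- sv$u[, 1:r, drop = FALSE] %*% (dshr[1:r] * t(sv$v[, 1:r, drop = FALSE]))
    }
    Znew <- Z; Znew[miss] <- Zhat[miss]
    if (max(abs(Znew - Z)) < tol) { Z <- Znew; break }
    Z <- Znew
  }
  Xc <- sweep(sweep(Z, 2, sdv, "*"), 2, mu, "+")
  # Summarize the completed matrix as a Gaussian for transforming new rows.
  list(mu = colMeans(Xc), Sigma = stats::cov(Xc), completed = Xc)
}

# Chained-equations: per-column ridge regressions on the other columns,
# cycled n_iter times; final coefficient vectors transform new rows.
fit_imputer_chained <- function(X, n_iter = 5, ridge = 1e-3) {
  d <- ncol(X)
  mu <- colMeans(X, na.rm = TRUE)
  Xc <- X
  for (j in seq_len(d)) Xc[is.na(X[, j]), j] <- mu[j]
  models <- vector("list", d)
  miss_cols <- which(colSums(is.na(X)) > 0)
  for (it in seq_len(max(1, n_iter))) {
    for (j in miss_cols) {
      obs <- !is.na(X[, j])
      A <- cbind(1, Xc[obs, -j, drop = FALSE])
      b <- Xc[obs, j]
      AtA <- crossprod(A) + diag(ridge, ncol(A))
      beta <- tryCatch(solve(AtA, crossprod(A, b)), error = function(e) NULL)
      if (is.null(beta)) next
      models[[j]] <- drop(beta)
      pred <- drop(cbind(1, Xc[!obs, -j, drop = FALSE]) %*% beta)
      Xc[!obs, j] <- pred
    }
  }
  list(mu = mu, models = models, completed = Xc)
}

fit_imputer_rf <- function(X, n_iter = 3, num_trees = 50, seed = 1) {
  d <- ncol(X)
  mu <- colMeans(X, na.rm = TRUE)
  Xc <- X
  for (j in seq_len(d)) Xc[is.na(X[, j]), j] <- mu[j]
  models <- vector("list", d)
  miss_cols <- which(colSums(is.na(X)) > 0)
  seeds <- pp_child_seeds(seed, max(1, n_iter) * max(1, length(miss_cols)))
  k <- 0
  for (it in seq_len(max(1, n_iter))) {
    for (j in miss_cols) {
      k <- k + 1
      obs <- !is.na(X[, j])
      if (sum(obs) < 5 || stats::sd(Xc[obs, j]) == 0) next
      df <- as.data.frame(Xc[, -j, drop = FALSE])
      names(df) <- paste0("v", seq_len(ncol(df)))
      df$.target <- Xc[, j]
      fit <- ranger::ranger(dependent.variable.name = ".target",
                            data = df[obs, , drop = FALSE],
                            num.trees = num_trees, seed = seeds[k],
                            num.threads = 1)
      models[[j]] <- fit
      if (any(!obs))
        Xc[!obs, j] <- stats::predict(fit, df[!obs, , drop = FALSE],
                                      num.threads = 1)$predictions
    }
  }
  list(mu = mu, models = models, completed = Xc)
}

#' Fit an imputation component
#'
#' @param name imputer name from the registry.
#' @param params named list of hyper-parameter values.
#' @param X numeric training matrix (may contain `NA`).
#' @param seed integer seed for stochastic imputers.
#' @return object with a `$transform(Xnew)` closure returning a complete matrix.
#' @export
fit_imputer <- function(name, params = list(), X, seed = 1) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  check_imputable(X)
  fill_by <- function(stat) {
    v <- apply(X, 2, stat)
    function(Xn) {
      Xn <- as.matrix(Xn); storage.mode(Xn) <- "double"
      for (j in seq_len(ncol(Xn))) Xn[is.na(Xn[, j]), j] <- v[j]
      Xn
    }
  }
  transform <- switch(name,
    mean = fill_by(function(x) mean(x, na.rm = TRUE)),
    median = fill_by(function(x) stats::median(x, na.rm = TRUE)),
    most_frequent = fill_by(col_mode),
    em = {
      fit <- fit_imputer_em(X, max_iter = params$max_iter %||% 20)
      function(Xn) {
        Xn <- as.matrix(Xn); storage.mode(Xn) <- "double"
        gaussian_conditional_impute(Xn, fit$mu, fit$Sigma)
      }
    },
    matrix_completion = {
      fit <- fit_imputer_softsvd(X, rank = params$rank %||% 3,
                                 shrink = params$shrink %||% 1)
      function(Xn) {
        Xn <- as.matrix(Xn); storage.mode(Xn) <- "double"
        gaussian_conditional_impute(Xn, fit$mu, fit$Sigma)
      }
    },
    chained_equations = {
      fit <- fit_imputer_chained(X, n_iter = params$n_iter %||% 5)
      function(Xn) chained_transform(Xn, fit)
    },
    rf_iterative = {
      fit <- fit_imputer_rf(X, n_iter = params$n_iter %||% 3,
                            num_trees = params$num_trees %||% 50, seed = seed)
      function(Xn) rf_transform(Xn, fit)
    },
    pp_stop("pp_unknown_component", sprintf("unknown imputer '%s'", name))
  )
  structure(list(name = name, transform = transform), class = "pp_imputer")
}

chained_transform <- function(Xn, fit) {
  Xn <- as.matrix(Xn); storage.mode(Xn) <- "double"
  miss <- is.na(Xn)
  Xc <- Xn
  for (j in seq_len(ncol(Xc))) Xc[miss[, j], j] <- fit$mu[j]
  for (j in which(colSums(miss) > 0)) {
    beta <- fit$models[[j]]
    if (is.null(beta)) next
    rows <- which(miss[, j])
    Xc[rows, j] <- drop(cbind(1, Xc[rows, -j, drop = FALSE]) %*% beta)
  }
  Xc
}

rf_transform <- function(Xn, fit) {
  Xn <- as.matrix(Xn); storage.mode(Xn) <- "double"
  miss <- is.na(Xn)
  Xc <- Xn
  for (j in seq_len(ncol(Xc))) Xc[miss[, j], j] <- fit$mu[j]
  for (j in which(colSums(miss) > 0)) {
    mod <- fit$models[[j]]
    if (is.null(mod)) next
    rows <- which(miss[, j])
    df <- as.data.frame(Xc[rows, -j, drop = FALSE])
    names(df) <- paste0("v", seq_len(ncol(df)))
    Xc[rows, j] <- stats::predict(mod, df, num.threads = 1)$predictions
  }
  Xc
}

`%||%` <- function(a, b) if (is.null(a)) b else a
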