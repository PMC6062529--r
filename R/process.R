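# Feature-processing stage: transforms fit on the imputed training matrix.
# Supervised selection sees the outcome; the others do not.

#' Fit a feature-processing component
#'
#' @param name processor name from the registry.
#' @param params named list of hyper-parameter values.
#' @param X complete numeric training matrix (post-imputation).
#' @param y binary outcome (used only by supervised selection).
#' @return object with a `$transform(Xnew)` closure.
#' @export
fit_processor <- function(name, params = list(), X, y = NULL) {
  X <- as.matrix(X)
  d <- ncol(X)
  transform <- switch(name,
    none = function(Xn) as.matrix(Xn),
    standardize = {
      mu <- colMeans(X)
      sdv <- apply(X, 2, stats::sd); sdv[!is.finite(sdv) | sdv == 0] <- 1
      function(Xn) sweep(sweep(as.matrix(Xn), 2, mu), 2, sdv, "/")
    },
    pca = {
      k <- max(1, min(params$n_components %||% 20, d, nrow(X) - 1))
      pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = k)
      function(Xn) stats::predict(pc, as.matrix(Xn))[, seq_len(k), drop = FALSE]
    },
    agglomeration = {
      k <- max(1, min(params$n_clusters %||% 10, d))
      mu <- colMeans(X)
      sdv <- apply(X, 2, stats::sd); sdv[!is.finite(sdv) | sdv == 0] <- 1
      groups <- if (d <= k) seq_len(d) else {
        Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
        cm <- suppressWarnings(stats::cor(Z))
        cm[!is.finite(cm)] <- 0
        hc <- stats::hclust(stats::as.dist(1 - abs(cm)), method = "average")
        stats::cutree(hc, k = k)
      }
      function(Xn) {
        Z <- sweep(sweep(as.matrix(Xn), 2, mu), 2, sdv, "/")
        out <- vapply(sort(unique(groups)), function(g)
          rowMeans(Z[, groups == g, drop = FALSE]), numeric(nrow(Z)))
        matrix(out, nrow = nrow(Z))
      }
    },
    select_k_best = {
      if (is.null(y)) pp_stop("pp_bad_config", "supervised selection needs the outcome")
      k <- max(1, min(params$k %||% 20, d))
      # absolute two-sample t statistic per column
      score <- vapply(seq_len(d), function(j) {
        a <- X[y == 1, j]; b <- X[y == 0, j]
        s <- sqrt(stats::var(a) / max(length(a), 1) + stats::var(b) / max(length(b), 1))
        if (!is.finite(s) || s == 0) 0 else abs(mean(a) - mean(b)) / s
      }, numeric(1))
      keep <- order(score, decreasing = TRUE)[seq_len(k)]
      keep <- sort(keep)
      function(Xn) as.matrix(Xn)[, keep, drop = FALSE]
    },
    pp_stop("pp_unknown_component", sprintf("unknown processor '%s'", name))
  )
  structure(list(name = name, transform = transform), class = "pp_processor")
}
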