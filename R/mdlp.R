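# Minimum-description-length discretization (recursive entropy-based binary
# splitting; a candidate cut is accepted only when its information gain
# clears the MDL coding cost of announcing the split).

entropy2 <- function(labels) {
  p <- table(labels) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

entropy_counts <- function(C) {
  # row-wise entropy (bits) of a matrix of class counts
  n <- rowSums(C)
  P <- C / ifelse(n == 0, 1, n)
  L <- ifelse(P > 0, log2(P), 0)
  -rowSums(P * L)
}

mdlp_best_cut <- function(x, labels) {
  o <- order(x)
  x <- x[o]; labels <- labels[o]
  n <- length(x)
  if (length(unique(x)) < 2) return(NULL)
  cls <- sort(unique(labels))
  Y <- outer(labels, cls, "==") * 1L
  cum <- apply(Y, 2, cumsum)
  if (is.null(dim(cum))) cum <- matrix(cum, ncol = length(cls))
  # candidate boundaries: last index of each distinct value except the max
  idx <- which(x[-n] != x[-1])
  if (!length(idx)) return(NULL)
  left <- cum[idx, , drop = FALSE]
  right <- matrix(cum[n, ], length(idx), length(cls), byrow = TRUE) - left
  ent_all <- entropy2(labels)
  eL <- entropy_counts(left); eR <- entropy_counts(right)
  gain <- ent_all - (idx * eL + (n - idx) * eR) / n
  b <- which.max(gain)
  cut <- (x[idx[b]] + x[idx[b] + 1]) / 2
  k <- length(cls)
  k1 <- sum(left[b, ] > 0); k2 <- sum(right[b, ] > 0)
  # Fayyad-Irani acceptance criterion
  delta <- log2(3^k - 2) - (k * ent_all - k1 * eL[b] - k2 * eR[b])
  if (gain[b] <= (log2(n - 1) + delta) / n) return(NULL)
  list(cut = cut, gain = gain[b])
}

#' MDL discretization cut points
#'
#' Recursive entropy-minimizing binary splits, each accepted only if its
#' information gain exceeds the minimum-description-length bound; cut points
#' lie at midpoints between adjacent observed values.
#'
#' @param values numeric vector (`NA` dropped pairwise with labels).
#' @param class_labels class labels aligned with `values`.
#' @return sorted numeric vector of cut points (possibly empty).
#' @export
mdl_discretize <- function(values, class_labels) {
  keep <- !is.na(values) & !is.na(class_labels)
  values <- values[keep]; class_labels <- as.character(class_labels)[keep]
  if (length(unique(values)) < 2) return(numeric(0))
  recurse <- function(x, labels) {
    if (length(unique(labels)) < 2 || length(unique(x)) < 2) return(numeric(0))
    best <- mdlp_best_cut(x, labels)
    if (is.null(best)) return(numeric(0))
    li <- x <= best$cut
    c(recurse(x[li], labels[li]), best$cut, recurse(x[!li], labels[!li]))
  }
  sort(recurse(values, class_labels))
}

#' Discretize a covariate table against class labels
#'
#' Continuous columns are replaced by interval labels from their MDL cuts;
#' binary (0/1) columns pass through as `"0"`/`"1"`; forced cuts (e.g. the
#' FEV1% predicted 30% referral threshold) override the MDL output for the
#' named columns, yielding the two levels `"<c"` and `">=c"`.
#'
#' @param data data frame of covariates.
#' @param class_labels class labels (one per row) driving the MDL cuts.
#' @param forced_cuts named numeric vector of forced thresholds.
#' @return data frame of character columns (NA rows stay NA).
#' @export
discretize_dataset <- function(data, class_labels, forced_cuts = c()) {
  out <- data
  for (nm in names(data)) {
    x <- data[[nm]]
    if (!is.numeric(x)) { out[[nm]] <- as.character(x); next }
    if (nm %in% names(forced_cuts)) {
      cut_at <- forced_cuts[[nm]]
      rng <- range(x, na.rm = TRUE)
      if (is.finite(rng[1]) && (cut_at <= rng[1] || cut_at > rng[2]))
        warning(sprintf("forced cut %g for '%s' outside observed range [%g, %g]",
                        cut_at, nm, rng[1], rng[2]))
      out[[nm]] <- ifelse(is.na(x), NA_character_,
                          ifelse(x < cut_at, paste0("<", cut_at),
                                 paste0(">=", cut_at)))
      next
    }
    if (is_binary_col(x)) { out[[nm]] <- as.character(as.integer(x)); next }
    cuts <- mdl_discretize(x, class_labels)
    if (!length(cuts)) {
      out[[nm]] <- ifelse(is.na(x), NA_character_, "all")
    } else {
      br <- c(-Inf, cuts, Inf)
      out[[nm]] <- as.character(cut(x, breaks = br, right = FALSE,
                                    dig.lab = 6))
    }
  }
  out
}
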