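#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

pp_stages <- c("imputation", "feature_processing", "classification", "calibration")

pp_stop <- function(class, msg) {
  stop(structure(class = c(class, "pp_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# Clamp probabilities away from 0/1 so logit transforms stay finite.
pp_clip01 <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

pp_logit <- function(p) stats::qlogis(pp_clip01(p))

# Deterministic local RNG scope: runs expr under the given seed and restores
# the caller's RNG state afterwards, so library internals cannot leak state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derive a stream of child seeds from one master seed (keeps everything < 2^31).
pp_child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

is_binary_col <- function(x) {
  u <- unique(x[!is.na(x)])
  length(u) <= 2 && all(u %in% c(0, 1))
}
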