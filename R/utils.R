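# Internal helpers: error classes, quantile convention, seed derivation.

abort_config <- function(msg, ...) {
  rlang::abort(msg, class = c("vaxflow_config_error", "vaxflow_error"), ...)
}

abort_domain <- function(msg, ...) {
  rlang::abort(msg, class = c("vaxflow_domain_error", "vaxflow_error"), ...)
}

abort_contract <- function(msg, ...) {
  rlang::abort(msg, class = c("vaxflow_contract_error", "vaxflow_error"), ...)
}

abort_infeasible <- function(msg, ...) {
  rlang::abort(msg, class = c("vaxflow_infeasible_error", "vaxflow_error"), ...)
}

abort_io <- function(msg, ...) {
  rlang::abort(msg, class = c("vaxflow_io_error", "vaxflow_error"), ...)
}

is_count <- function(x, min = 0) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x >= min && x == round(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x <= 1
}

is_nondecreasing <- function(x) {
  length(x) < 2 || all(diff(x) >= 0)
}

# Sample percentile, median-unbiased convention (Hyndman-Fan type 8).
pct <- function(x, p) {
  unname(stats::quantile(x, probs = p, type = 8, names = FALSE))
}

#' Derive replication seeds from a base seed
#'
#' All randomness in a scenario run flows from one base seed: the base seed
#' initialises R's RNG once and `n` integer sub-seeds are drawn from it, one
#' per replication (or per sweep point). Any single replication can therefore
#' be re-run in isolation from its recorded sub-seed.
#'
#' @param base_seed Integer scalar.
#' @param n Number of sub-seeds to derive.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(base_seed, n) {
  if (!is_count(n)) abort_domain("`n` must be a non-negative integer.")
  if (!is.numeric(base_seed) || length(base_seed) != 1 || is.na(base_seed)) {
    abort_domain("`base_seed` must be a single integer.")
  }
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(base_seed))
  sample.int(2147483646L, n, replace = FALSE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
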