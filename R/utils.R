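# internal helpers shared across modules

# degenerate = zero spread up to floating tolerance (absolute + relative to
# the location), so an index that is 0 only up to rounding still counts
is_degenerate <- function(x) {
  s <- stats::sd(x)
  !is.finite(s) || s <= 1e-12 + 1e-10 * abs(mean(x))
}

# z-score; errors on (effectively) zero variance because every standardized
# model downstream is undefined in that case
zscore <- function(x, what = "variable") {
  if (is_degenerate(x)) {
    abort(
      sprintf("cannot standardize %s: zero or non-finite variance", what),
      class = "aaci_error_degenerate"
    )
  }
  (x - mean(x)) / stats::sd(x)
}

# truncated normal via rejection-free inverse CDF
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  p_lo <- stats::pnorm(lower, mean, sd)
  p_hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, p_lo, p_hi), mean, sd)
}

# deterministic per-stage sub-seed derived from one global seed, kept within
# 32-bit integer range
stage_seed <- function(seed, stage) {
  offsets <- c(
    covariates = 11L, intakes = 23L, serum = 37L, outcome = 53L,
    ffq = 71L, bootstrap = 97L
  )
  k <- offsets[[stage]]
  as.integer((as.numeric(seed) * 1009 + k * 9973) %% 2147483647)
}

check_columns <- function(data, cols, where) {
  miss <- setdiff(cols, names(data))
  if (length(miss) > 0) {
    abort(
      sprintf(
        "%s: missing required column%s: %s",
        where, if (length(miss) > 1) "s" else "", paste(miss, collapse = ", ")
      ),
      class = "aaci_error_schema"
    )
  }
  invisible(data)
}
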