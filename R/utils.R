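# Classed error signals so callers/tests can distinguish failure modes.
abort_invalid <- function(msg) {
  stop(errorCondition(msg, class = c("spikecode_invalid_argument",
                                     "spikecode_error")))
}

abort_range <- function(msg) {
  stop(errorCondition(msg, class = c("spikecode_out_of_range",
                                     "spikecode_error")))
}

abort_estimation <- function(msg) {
  stop(errorCondition(msg, class = c("spikecode_estimation_failure",
                                     "spikecode_error")))
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream. seed = NULL means: use the current stream as-is.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    abort_invalid("`seed` must be a single finite number or NULL")
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    set.seed(NULL)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed derivation, kept inside 32-bit integer range.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  x <- as.double(seed)
  for (k in seq_along(idx)) {
    x <- (x * 48271 + as.double(idx[k]) * 16807 + 11) %% 2147483647
  }
  as.integer(x %% 2147483646) + 1L
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_invalid(sprintf("`%s` must be a single finite number", name))
  if (x < lower || (strict_lower && x <= lower) || x > upper)
    abort_invalid(sprintf("`%s` = %g is outside its admissible range", name, x))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
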