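# Internal numerical and validation helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

# order-canonical sum: pooling outputs must be bit-identical under study
# permutation, so every reduction sums its terms in sorted order
ksum <- function(x) sum(sort(x))

# log(sum(exp(x))) without overflow; -Inf-safe, order-canonical
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(ksum(exp(x - m)))
}

stop_validation <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("harmsynth_validation_error", "error")))
}

stop_numerical <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("harmsynth_numerical_error", "error")))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_validation("'%s' must be a single non-missing number", name)
  if (x < lower || x > upper)
    stop_validation("'%s' = %s outside [%s, %s]", name, format(x),
                    format(lower), format(upper))
  invisible(x)
}

assert_count <- function(x, name, lower = 0) {
  assert_scalar_number(x, name, lower = lower)
  if (x != round(x))
    stop_validation("'%s' must be an integer count, got %s", name, format(x))
  invisible(as.integer(x))
}

# Derive a per-stream seed from a root seed and a counter so that adding
# studies to a simulation never reshuffles the draws of earlier studies.
# Kept strictly below 2^31 - 1.
substream_seed <- function(seed, counter) {
  seed <- as.double(seed %% 2147483647)
  (seed * 48271 + as.double(counter) * 7919 + 1) %% 2147483647
}
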