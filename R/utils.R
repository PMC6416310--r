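# Internal helpers shared across stages.

# Locale-independent row ordering: radix sort over all columns, left to right.
# Keeps every written table byte-stable across platforms.
stable_arrange <- function(df) {
  if (nrow(df) < 2L) {
    return(df)
  }
  ord <- do.call(order, c(unname(as.list(df)), list(method = "radix")))
  df[ord, , drop = FALSE]
}

# Package messages go through one channel so callers can suppress them.
mp_log <- function(...) {
  message("[modulepivot] ", sprintf(...))
}

stop_mp <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)
}

is_prob <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x <= 1
}

# Deterministic sub-seed derivation; keeps every derived seed a valid 32-bit
# integer whatever small integer the user supplies.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + offset * 7919L) %% 2147483629)
}
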