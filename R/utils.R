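# Internal helpers shared across modules.

# Derive `n` reproducible child seeds from a master seed without disturbing
# the caller's RNG state. Children are < 2^31 so they are valid R seeds.
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(2147483646L, n))
}

# Logistic function with no overflow surprises.
sigmoid <- function(z) 1 / (1 + exp(-z))

assert_binary_labels <- function(labels, arg = "labels") {
  if (anyNA(labels) || !all(labels %in% c(0, 1))) {
    abort(sprintf("`%s` must be 0/1 with no missing values.", arg))
  }
  if (length(unique(labels)) < 2) {
    abort(sprintf("`%s` must contain both classes (0 and 1).", arg))
  }
  invisible(as.integer(labels))
}

# Largest-remainder allocation of `n` items to `fractions` (sums to n).
largest_remainder <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    # ties in the fractional part are broken by position (train first)
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  as.integer(base)
}
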