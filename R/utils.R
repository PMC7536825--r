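# Internal helpers: argument checking and seeded evaluation.

stop_invalid <- function(...) {
  stop(..., call. = FALSE)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid(sprintf("`%s` must be a single finite number", name))
  }
  if (integer && x != round(x)) {
    stop_invalid(sprintf("`%s` must be an integer", name))
  }
  if (x < lower || x > upper) {
    stop_invalid(sprintf("`%s` must be in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}

check_binary <- function(x, name) {
  if (!all(x %in% c(0, 1))) {
    stop_invalid(sprintf("`%s` must contain only 0/1 values", name))
  }
  invisible(x)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# global RNG state is untouched. All package randomness goes through this.
with_seed <- function(seed, expr) {
  check_scalar_number(seed, "seed", integer = TRUE)
  withr::with_seed(as.integer(seed), expr)
}

# Deterministic fan-out of one master seed into per-stage seeds, all < 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
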