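# Internal helpers shared across modules.

# Derive a 32-bit stage seed from the master seed so each stochastic stage
# draws from its own substream while staying reproducible.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647L)
}

# Run `expr` under a local RNG seeded from (seed, stage); global RNG untouched.
with_stage_seed <- function(seed, stage, expr) {
  withr::with_seed(derive_seed(seed, stage), expr)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single number in [0, 1].", name),
          class = "estrocycle_invalid_config")
  }
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min),
          class = "estrocycle_invalid_config")
  }
  invisible(as.integer(x))
}

`%g%` <- function(x, y) if (is.null(x)) y else x
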