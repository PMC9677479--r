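# Internal helpers shared across modules.

# Expand one run seed into a deterministic per-stage seed, kept below 2^31
# so it is a valid R integer on every platform.
derive_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  as.integer((as.double(seed) * 48271 + 1013904223 * offset) %% 2147483647)
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

assert_columns <- function(df, cols, arg = deparse(substitute(df))) {
  if (!is.data.frame(df)) {
    abort(sprintf("`%s` must be a data frame.", arg), class = "kge_type_error")
  }
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(
      sprintf(
        "`%s` is missing required column%s: %s.",
        arg, if (length(missing) > 1L) "s" else "", paste(missing, collapse = ", ")
      ),
      class = "kge_type_error"
    )
  }
  invisible(df)
}

assert_finite_scores <- function(x, arg = "score") {
  if (anyNA(x) || any(!is.finite(x))) {
    abort(
      sprintf("`%s` contains NA or non-finite values.", arg),
      class = "kge_score_error"
    )
  }
  invisible(x)
}

# sample() that never falls into the scalar-x trap (sample(5) == sample(1:5)).
sample_vec <- function(x, size = length(x)) {
  x[sample.int(length(x), size)]
}

# Skew-normal deviates via the delta-|Z0| construction:
# X = loc + scale * (delta*|Z0| + sqrt(1-delta^2)*Z1), delta = a/sqrt(1+a^2).
rskewnorm <- function(n, location = 0, scale = 1, alpha = 0) {
  delta <- alpha / sqrt(1 + alpha^2)
  z0 <- abs(rnorm(n))
  z1 <- rnorm(n)
  location + scale * (delta * z0 + sqrt(1 - delta^2) * z1)
}
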