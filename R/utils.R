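# Internal helpers shared across modules.

# round half away from zero; base round() rounds half to even, which would
# silently change binomial test counts such as 10.5
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# log(sum(exp(x))) without overflow; -Inf for empty input
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (length(x) == 0L || all(x == -Inf)) return(-Inf)
  m <- max(x)
  m + log(sum(exp(x - m)))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name, lower, upper, x))
  }
  invisible(x)
}

assert_count_columns <- function(x, cols, where) {
  for (cl in cols) {
    v <- x[[cl]]
    if (any(is.na(v)) || any(v < 0) || any(v != floor(v))) {
      abort(sprintf("Column `%s` in %s must hold non-negative integers.", cl, where))
    }
  }
  invisible(x)
}

# run `expr` under a temporary RNG state when `seed` is given
with_sim_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  assert_scalar_number(seed, "seed")
  withr::with_seed(as.integer(seed), expr)
}

pg_inform <- function(...) {
  if (isTRUE(getOption("phenogeno.quiet", FALSE))) return(invisible(NULL))
  inform(sprintf(...))
}
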