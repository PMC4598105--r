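# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed when `seed` is non-NULL, restoring
# the caller's RNG state afterwards; otherwise use the ambient RNG stream.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

# Derive `n` reproducible child seeds (< 2^31) from one user seed so that
# sub-computations (EM restarts, per-run streams) are independently seeded.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  withr::with_seed(as.integer(seed), as.list(sample.int(.Machine$integer.max, n)))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf(
      "`%s` must be %s %s%s; got %g.", name,
      if (strict_lower) "greater than" else "at least", format(lower),
      if (is.finite(upper)) {
        sprintf(" and %s %s", if (strict_upper) "less than" else "at most",
                format(upper))
      } else "",
      x
    ))
  }
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) ||
      x < lower) {
    abort(sprintf("`%s` must be an integer >= %d.", name, lower))
  }
  invisible(as.integer(x))
}

trapezoid <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
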