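# Internal helpers shared across modules.

# Logistic function used by the participation and engagement read-outs.
sigmoid <- function(x) plogis(x)

# Clamp x into [lo, hi]; attaches a "clamped" attribute when any value moved.
clamp <- function(x, lo, hi) {
  y <- pmin(pmax(x, lo), hi)
  attr(y, "clamped") <- any(y != x)
  y
}

# Derive a per-stream 32-bit seed from a master seed. Arithmetic (not
# sampling-based) so stream k is unchanged when more streams are requested.
derive_seed <- function(master, stream) {
  (as.double(master) * 1000003 + as.double(stream) * 7919) %% 2147483629
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "apeo_invalid_argument")
  }
  if (strict_lower && x <= lower) {
    abort(sprintf("`%s` must be > %s.", name, lower),
          class = "apeo_domain_error")
  }
  if (!strict_lower && x < lower) {
    abort(sprintf("`%s` must be >= %s.", name, lower),
          class = "apeo_invalid_argument")
  }
  if (x > upper) {
    abort(sprintf("`%s` must be <= %s.", name, upper),
          class = "apeo_invalid_argument")
  }
  invisible(x)
}

check_same_length <- function(x, y, xname, yname) {
  if (length(x) != length(y)) {
    abort(sprintf("`%s` (length %d) and `%s` (length %d) must have equal length.",
                  xname, length(x), yname, length(y)),
          class = "apeo_shape_error")
  }
  invisible(TRUE)
}

# Evaluate an expression with a local RNG seed, restoring the caller's state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483629))
  expr
}
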