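# internal helpers shared across modules

#' @keywords internal
#' @noRd
abort_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

check_scalar_num <- function(x, field, lower = -Inf, upper = Inf,
                             strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_field(field, "must be a single finite number")
  }
  if (strict_lower && x <= lower) {
    abort_field(field, sprintf("must be > %g", lower))
  }
  if (!strict_lower && x < lower) {
    abort_field(field, sprintf("must be >= %g", lower))
  }
  if (x > upper) abort_field(field, sprintf("must be <= %g", upper))
  invisible(x)
}

check_count <- function(x, field, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != round(x)) {
    abort_field(field, "must be a single integer")
  }
  if (x < min) abort_field(field, sprintf("must be >= %d", min))
  invisible(as.integer(x))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. All stochastic phantom operations go
# through this so one study seed governs every draw reproducibly.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible child seed from a base seed and a stream index,
# keeping the result inside 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 7919 + as.double(index) * 104729) %%
               2147483647)
}
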