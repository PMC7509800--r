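# internal helpers shared across modules

# Evaluate `code` under a fixed RNG state without disturbing the caller's
# stream. All user-facing generators route through this, so they are pure
# functions of (config, seed).
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
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
    set.seed(as.integer(seed))
  }
  force(code)
}

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

assert_scalar_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_config("`%s` must be a single finite number", name)
  }
  if (positive && x <= 0) stop_config("`%s` must be > 0 (got %g)", name, x)
  if (nonneg && x < 0) stop_config("`%s` must be >= 0 (got %g)", name, x)
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min) {
    stop_config("`%s` must be an integer >= %d", name, min)
  }
  invisible(as.integer(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
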