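# Internal helpers shared across modules.

# Raise a classed condition so callers can distinguish failure modes.
abort <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "eegtrp_error")))
}

warn_classed <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "eegtrp_warning")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
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
  force(expr)
}

# Root-mean-square of a numeric vector.
rms <- function(x) sqrt(mean(x^2))

# Derive a child seed from (seed, k), kept inside the 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(k)) %% 2147483629)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
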