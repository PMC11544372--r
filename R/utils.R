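# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
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
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# Checked accessor for named effect vectors: absent names mean "no effect".
lookup_effect <- function(x, name, default = 0) {
  if (is.null(x) || is.null(names(x)) || !name %in% names(x)) {
    return(default)
  }
  unname(x[[name]])
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == round(x)
}

is_prob <- function(x) {
  is.numeric(x) && all(!is.na(x)) && all(x >= 0) && all(x <= 1)
}
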