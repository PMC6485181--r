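# internal helpers shared across modules

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL means "use the current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop(sprintf("'%s' must be a probability in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

check_pos <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) >= 1L && !anyNA(x) && all(is.finite(x)) &&
    (if (strict) all(x > 0) else all(x >= 0))
  if (!ok) {
    stop(sprintf("'%s' must be %s", name, if (strict) "> 0" else ">= 0"),
         call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
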