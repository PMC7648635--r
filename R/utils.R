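# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
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
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Coerce a 0/1/logical vector to logical, erroring on anything else.
as_presence <- function(x, what = "pattern") {
  if (length(x) == 0L) stop(what, " must be non-empty", call. = FALSE)
  if (is.logical(x)) {
    if (anyNA(x)) stop(what, " must not contain NA", call. = FALSE)
    return(x)
  }
  if (is.numeric(x) && all(x %in% c(0, 1))) return(x == 1)
  stop(what, " must be logical or 0/1", call. = FALSE)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
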