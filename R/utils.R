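## internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
## seed = NULL leaves the RNG stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = genv)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = genv)), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

stopifnot_scalar <- function(x, name = deparse(substitute(x))) {
  if (length(x) != 1L || is.na(x)) stop(name, " must be a non-missing scalar", call. = FALSE)
  invisible(x)
}

## lower median: for even n take the smaller of the two central order statistics
median_lower <- function(x) {
  x <- sort(x)
  x[[(length(x) + 1L) %/% 2L]]
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
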