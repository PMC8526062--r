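#' @keywords internal
"_PACKAGE"

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. seed = NULL runs in the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stopf(fmt, ...)
  invisible(TRUE)
}

is_count <- function(x) length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
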