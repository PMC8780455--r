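#' @keywords internal
"_PACKAGE"

## Single-base alphabet used throughout; everything else is dropped at import.
DNA_BASES <- c("A", "C", "G", "T")

#' Derive a child seed from a master seed and a key
#'
#' Deterministic string hash of the master seed and any number of
#' string/numeric components. Used so that, e.g., replicate 7 of sample "S01"
#' always receives the same seed regardless of how many other samples exist.
#'
#' @param seed master integer seed.
#' @param ... components (coerced to character) identifying the child stream.
#' @return a non-negative integer scalar below 2^31.
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(c(format(seed, scientific = FALSE), vapply(list(...), function(x)
    paste(format(x, scientific = FALSE), collapse = "\r"), character(1))),
    collapse = "\x1f")
  bytes <- utf8ToInt(key)
  # polynomial rolling hash mod the Mersenne prime 2^31-1, exact in doubles
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

## Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
## RNG state is untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Locale-independent ordering used wherever reproducibility matters.
radix_order <- function(...) order(..., method = "radix")

stop_mo <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warn_mo <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
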