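# Internal helpers: seed splitting and local RNG scope.

#' Derive a reproducible substream seed
#'
#' All randomness in the package flows from a single integer seed; per-read
#' (or per-run) substreams are derived deterministically from the master seed
#' and an index, so that simulating read `i` does not depend on how many
#' reads were simulated before it. Derived seeds stay below 2^31.
#'
#' @param seed Master integer seed.
#' @param index Non-negative integer stream index.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, index = 0L) {
  s <- abs(as.double(seed)) %% 2147483647
  v <- (s * 48271 + as.double(index) * 104729 + 1) %% 2147483629
  as.integer(v)
}

# Evaluate `code` with a temporary RNG state; the caller's state is restored.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
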