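# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded operations inside the package
#' never disturb the caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Derive a stream-specific child seed from a parent seed; stays below 2^31.
derive_seed <- function(seed, i) {
  (as.double(seed) * 48271 + as.double(i) * 9973 + 1) %% 2147483587
}

#' Round-trip numeric values through IEEE single precision
#'
#' Embedding vectors are stored on disk as little-endian 32-bit floats;
#' quantizing at computation time makes the save/load round trip bit-exact.
#' @noRd
as_float32 <- function(x) {
  d <- dim(x)
  y <- readBin(writeBin(as.numeric(x), raw(), size = 4, endian = "little"),
               "numeric", n = length(x), size = 4, endian = "little")
  dim(y) <- d
  y
}

# Clamp to [lo, hi].
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a
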