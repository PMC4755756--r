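# Small shared helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Conventional "half-up" rounding used for display of percentages, where
#' `round()`'s round-half-even rule would disagree with tabulated values
#' (e.g. 6.25 -> 6.3 at one decimal).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's .Random.seed afterwards so library calls never perturb user RNG.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Derive a child seed from a top-level seed and a stage tag
#'
#' A single top-level seed fans out deterministically to per-stage seeds so
#' that one integer reproduces an entire pipeline run. The derivation is a
#' fixed integer hash kept below 2^31.
#'
#' @param seed integer top-level seed.
#' @param tag character stage tag (e.g. `"noise"`, `"tp341"`).
#' @return an integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, tag) {
  h <- as.double(seed) %% 2147483647
  for (k in utf8ToInt(as.character(tag))) {
    h <- (h * 131 + k) %% 2147483647
  }
  as.integer(h)
}

# Quantize doubles to the nearest IEEE single-precision value. Rendered maps
# are quantized once so that CCP4 mode-2 (float32) round trips are bit-exact.
quantize_float32 <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4, endian = "little"),
          what = "numeric", n = length(x), size = 4, endian = "little")
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
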