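# Internal helpers: seeded evaluation, clamping, content hashing.

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' previous RNG state so package functions never leak global state.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
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
  code
}

# clamps in place so dim/class attributes survive (pmin/pmax drop them)
clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Content hash of numeric data
#'
#' Order-sensitive fold hash used for provenance records in run manifests.
#' Numeric data are quantised to 16-bit integers (exact integer input is
#' used as-is) and folded pairwise with two fixed primes modulo 2^31 - 1.
#' Not cryptographic; intended to detect accidental input changes between
#' runs of the same pipeline.
#'
#' @param x numeric vector, matrix or array.
#' @return an 8-character lowercase hexadecimal string.
#' @examples
#' content_hash(matrix(1:6, 2))
#' @export
content_hash <- function(x) {
  v <- as.numeric(x)
  if (length(v) == 0L) return("00000000")
  q <- if (all(v == round(v)) && all(abs(v) < 2^30)) {
    as.numeric(v %% 65536)
  } else {
    round(clamp01(v) * 65535)
  }
  p <- 2147483647  # 2^31 - 1
  h <- (q + 1) %% p
  # log-depth order-sensitive reduction; odd/even positions get distinct primes
  while (length(h) > 1L) {
    if (length(h) %% 2L == 1L) h <- c(h, 12345)
    odd <- h[seq(1L, length(h), by = 2L)]
    even <- h[seq(2L, length(h), by = 2L)]
    h <- (odd * 31 + even * 131 + 7) %% p
  }
  sprintf("%08x", as.integer(h))
}

fmt_num <- function(x) format(x, digits = 6, trim = TRUE)
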