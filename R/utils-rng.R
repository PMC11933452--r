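#' Evaluate an expression under a local RNG seed
#'
#' Saves the global RNG state, seeds it, evaluates `expr`, and restores the
#' previous state, so seeded draws inside the package never perturb the
#' caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
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
  expr
}

#' Deterministic 31-bit hash of a string
#'
#' Polynomial rolling hash over UTF-8 bytes, used to derive named RNG
#' substreams and the stub embedding backend. Stable across platforms and
#' sessions (no dependence on R's internal string hashing).
#'
#' @param x character scalar.
#' @return integer in [0, 2^31 - 1].
#' @keywords internal
hash_string <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- as.integer(utf8ToInt(enc2utf8(x)))
  h <- 0
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  for (b in bytes) {
    h <- (h * 131 + b) %% m
  }
  as.integer(h)
}

#' Derive a substream seed from a global seed and a label
#'
#' All randomness in the package flows from one global seed through named
#' substreams, so independent stages draw from decorrelated streams while a
#' run remains bit-reproducible.
#'
#' @param seed integer global seed.
#' @param label character substream name.
#' @return integer seed below 2^31.
#' @keywords internal
substream_seed <- function(seed, label) {
  as.integer((as.numeric(seed) + hash_string(label)) %% 2147483647)
}
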