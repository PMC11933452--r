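log_base_value <- function(log_base) {
  if (is.character(log_base)) {
    log_base <- match.arg(log_base, c("e", "2"))
    if (log_base == "e") return(exp(1)) else return(2)
  }
  stopifnot(is.numeric(log_base), length(log_base) == 1L, log_base > 1)
  log_base
}

as_tokens <- function(stimulus) {
  if (inherits(stimulus, "text_stimulus")) stimulus$tokens
  else as.character(stimulus)
}

#' Prefix entropies of a token sequence
#'
#' For each position i, the Shannon entropy of the empirical word-frequency
#' distribution of the prefix ending at (and including) position i:
#' H_i = -sum_w f_w log(f_w), where f_w is the relative frequency of word w
#' among the first i tokens. H_1 is always 0 (a single word is a degenerate
#' distribution), and H_i <= log(n_i) where n_i is the number of unique
#' words in the prefix.
#'
#' @param stimulus a [text_stimulus][tokenize_text] or character token vector.
#' @param log_base `"e"` (nats, default), `"2"` (bits), or a numeric base.
#' @return Numeric vector of length equal to the token count.
#' @export
#' @examples
#' prefix_entropy(c("a", "a", "b"))  # 0, 0, 0.6365...
prefix_entropy <- function(stimulus, log_base = "e") {
  tokens <- as_tokens(stimulus)
  stopifnot(length(tokens) >= 1L)
  base <- log_base_value(log_base)
  n <- length(tokens)
  counts <- new.env(hash = TRUE, parent = emptyenv())
  h <- numeric(n)
  # incremental update: track sum of c*log(c) over word counts c
  clogc <- 0
  n_unique <- 0L
  for (i in seq_len(n)) {
    w <- tokens[[i]]
    old <- if (is.null(counts[[w]])) 0 else counts[[w]]
    if (old == 0) n_unique <- n_unique + 1L
    if (old > 0) clogc <- clogc - old * log(old)
    cnt <- old + 1
    counts[[w]] <- cnt
    if (cnt > 1) clogc <- clogc + cnt * log(cnt)
    # H = log(i) - (1/i) * sum c*log(c), in nats; rescale to requested base.
    # A single-type prefix is exactly 0 (avoids accumulating round-off).
    h[i] <- if (n_unique == 1L) 0 else (log(i) - clogc / i) / log(base)
  }
  # guard tiny negative round-off
  pmax(h, 0)
}

#' Cumulated empirical entropy of a text
#'
#' The sum of [prefix_entropy()] over all token positions. This is the
#' text-level proxy for objective information content: it is 0 for a
#' constant text and log(n!) for a text of n all-distinct words.
#'
#' @inheritParams prefix_entropy
#' @return Scalar cumulated entropy in the units of `log_base`.
#' @export
#' @examples
#' cumulated_entropy(letters[1:4])  # log(24)
cumulated_entropy <- function(stimulus, log_base = "e") {
  sum(prefix_entropy(stimulus, log_base = log_base))
}

#' Basic lexical counts of a stimulus
#'
#' @inheritParams prefix_entropy
#' @return Named list: `token_count`, `unique_count`, and `repetition_rate`
#'   (1 - unique/token, the fraction of tokens that repeat an earlier type).
#' @export
lexical_counts <- function(stimulus) {
  tokens <- as_tokens(stimulus)
  stopifnot(length(tokens) >= 1L)
  tc <- length(tokens)
  uc <- length(unique(tokens))
  list(token_count = tc, unique_count = uc,
       repetition_rate = 1 - uc / tc)
}

#' Vocabulary trajectory of a stimulus
#'
#' n_i: the number of unique word types among the first i tokens;
#' nondecreasing in i.
#'
#' @inheritParams prefix_entropy
#' @return Integer vector of length equal to the token count.
#' @export
vocabulary_trajectory <- function(stimulus) {
  tokens <- as_tokens(stimulus)
  cumsum(!duplicated(tokens))
}
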