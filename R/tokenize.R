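#' Tokenizer configuration
#'
#' Controls the deterministic normalization applied before a text is split
#' into word tokens. The defaults (case folding on, punctuation stripped,
#' whitespace splitting) make token identity purely lexical; compounds are
#' never split and no stemming or lemmatization is applied.
#'
#' @param case_folding lowercase the text before splitting.
#' @param punctuation_stripping remove punctuation characters.
#' @return A `tokenizer_config` list, serializable with [jsonlite::toJSON()].
#' @export
#' @examples
#' tokenize_text("Der Winter. Der Winter!", tokenizer_config())
tokenizer_config <- function(case_folding = TRUE, punctuation_stripping = TRUE) {
  structure(
    list(
      case_folding = isTRUE(case_folding),
      punctuation_stripping = isTRUE(punctuation_stripping),
      token_delimiter = "whitespace"
    ),
    class = "tokenizer_config"
  )
}

#' Tokenize a raw text into a stimulus object
#'
#' Applies the configured normalization and splits on whitespace, returning a
#' `text_stimulus`: the ordered token sequence over which prefix entropies
#' are computed (positions are 1-based).
#'
#' @param raw_text character scalar, nonempty after stripping.
#' @param config a [tokenizer_config()].
#' @param stimulus_id short label used in outputs and error messages.
#' @return A `text_stimulus` list with `stimulus_id`, `raw_text`, `tokens`.
#' @export
#' @examples
#' s <- tokenize_text("A b A b c", stimulus_id = "demo")
#' length(s$tokens)  # 5
tokenize_text <- function(raw_text, config = tokenizer_config(),
                          stimulus_id = "stimulus") {
  stopifnot(is.character(raw_text), length(raw_text) == 1L)
  txt <- raw_text
  if (config$case_folding) txt <- tolower(txt)
  if (config$punctuation_stripping) {
    # keep letters (incl. umlauts), digits, whitespace; drop the rest
    txt <- gsub("[^[:alnum:][:space:]]", " ", txt)
  }
  tokens <- strsplit(trimws(txt), "[[:space:]]+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) {
    stop("stimulus '", stimulus_id, "': no tokens remain after normalization",
         call. = FALSE)
  }
  new_text_stimulus(stimulus_id, raw_text, tokens)
}

new_text_stimulus <- function(stimulus_id, raw_text, tokens) {
  stopifnot(length(tokens) >= 1L, is.character(tokens))
  structure(
    list(stimulus_id = as.character(stimulus_id),
         raw_text = as.character(raw_text),
         tokens = as.character(tokens)),
    class = "text_stimulus"
  )
}

#' @export
print.text_stimulus <- function(x, ...) {
  cat("<text_stimulus> ", x$stimulus_id, ": ", length(x$tokens), " tokens, ",
      length(unique(x$tokens)), " unique\n", sep = "")
  invisible(x)
}
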