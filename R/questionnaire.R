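#' Load a questionnaire scoring key from JSON
#'
#' A key file declares the scale name, the admissible per-item response
#' range, the item ids grouped by subscale, and the reverse-coded item set.
#' Keys for the study's instruments (BFI-10, BPS, MSBS, STAI-Y, BRS) ship
#' under `inst/extdata/keys/` and are editable — item-level scoring is
#' configuration, not code.
#'
#' @param path JSON key file.
#' @return A `questionnaire_key` list.
#' @export
load_questionnaire_key <- function(path) {
  key <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  stopifnot(all(c("scale", "response_range", "subscales") %in% names(key)))
  key$subscales <- as.list(key$subscales)
  if (is.null(key$reverse_items)) key$reverse_items <- character(0)
  items <- unlist(key$subscales, use.names = FALSE)
  if (!all(key$reverse_items %in% items)) {
    stop("reverse-coded items not in item set: ",
         paste(setdiff(key$reverse_items, items), collapse = ", "),
         call. = FALSE)
  }
  structure(key, class = "questionnaire_key")
}

#' Score a questionnaire from item responses
#'
#' Reverse-coded items are mapped as `range_max + range_min - response`,
#' then each subscale is summed. A missing (absent or NA) item excludes only
#' the affected subscale for that participant, flagged — the participant's
#' other scales remain scored. Out-of-range responses are a hard error
#' naming the item.
#'
#' @param responses named numeric vector/list keyed by item id.
#' @param key a [load_questionnaire_key()] result (or equivalent list).
#' @return List: `scores` (named numeric per subscale, plus `total` when the
#'   key has > 1 subscale and all are scored), `excluded` (named logical per
#'   subscale).
#' @export
score_questionnaire <- function(responses, key) {
  responses <- unlist(responses)
  rng <- as.numeric(key$response_range)
  items <- unlist(key$subscales, use.names = FALSE)
  present <- intersect(names(responses), items)
  bad <- present[!is.na(responses[present]) &
                 (responses[present] < rng[1] | responses[present] > rng[2])]
  if (length(bad) > 0L) {
    stop("response out of range [", rng[1], ", ", rng[2], "] for item(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  scored <- responses
  rev_items <- intersect(key$reverse_items, present)
  scored[rev_items] <- rng[2] + rng[1] - scored[rev_items]
  scores <- c(); excluded <- c()
  for (sub in names(key$subscales)) {
    ids <- key$subscales[[sub]]
    vals <- scored[ids]
    if (length(ids) == 0L || any(is.na(vals)) ||
        !all(ids %in% names(responses))) {
      scores[sub] <- NA_real_
      excluded[sub] <- TRUE
    } else {
      scores[sub] <- sum(vals)
      excluded[sub] <- FALSE
    }
  }
  if (length(key$subscales) > 1L && !any(excluded)) {
    scores["total"] <- sum(scores[names(key$subscales)])
  }
  list(scores = scores, excluded = excluded)
}
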