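#' Validate a participants-plus-profiles dataset
#'
#' Structural problems (missing required columns) are a hard error; value
#' problems are collected into a violation report with row references:
#' ratings outside [1, 7], participants missing texts, duplicated
#' (participant, stimulus, sentiment) cells, unknown stimulus ids, and
#' unknown cohort labels when a label set is supplied.
#'
#' @param participants participant tibble (or CSV path) with
#'   `participant_id`, `cohort` and Big Five columns.
#' @param ratings long ratings tibble (or CSV path).
#' @param profiles `complexity_profile` list or a profiles table with
#'   `stimulus_id`.
#' @param known_cohorts optional character vector of admissible labels.
#' @return A `validation_report` list: `violations` tibble (row, check,
#'   message), `n_violations`, `valid`.
#' @export
validate_dataset <- function(participants, ratings, profiles,
                             known_cohorts = NULL) {
  if (is.character(participants)) participants <- read.csv(participants)
  if (is.character(ratings)) ratings <- read.csv(ratings)
  stim_ids <- if (is.data.frame(profiles)) profiles$stimulus_id
              else names(profiles)
  req_p <- c("participant_id", "cohort", big_five)
  req_r <- c("participant_id", "stimulus_id", "sentiment", "rating")
  if (!all(req_p %in% names(participants))) {
    stop("participants table missing column(s): ",
         paste(setdiff(req_p, names(participants)), collapse = ", "),
         call. = FALSE)
  }
  if (!all(req_r %in% names(ratings))) {
    stop("ratings table missing column(s): ",
         paste(setdiff(req_r, names(ratings)), collapse = ", "),
         call. = FALSE)
  }
  v <- list()
  add <- function(row, check, message) {
    v[[length(v) + 1L]] <<- tibble::tibble(row = row, check = check,
                                           message = message)
  }
  out_of_bounds <- which(ratings$rating < 1 | ratings$rating > 7)
  for (i in out_of_bounds) {
    add(i, "rating_bounds",
        sprintf("rating %.3g outside the 1-7 scale (participant %s)",
                ratings$rating[i], ratings$participant_id[i]))
  }
  unknown_stim <- which(!ratings$stimulus_id %in% stim_ids)
  for (i in unknown_stim) {
    add(i, "stimulus_id",
        sprintf("unknown stimulus '%s'", ratings$stimulus_id[i]))
  }
  dup <- which(duplicated(ratings[, c("participant_id", "stimulus_id",
                                      "sentiment")]))
  for (i in dup) {
    add(i, "duplicate_cell",
        sprintf("duplicated rating cell (participant %s, %s, %s)",
                ratings$participant_id[i], ratings$stimulus_id[i],
                ratings$sentiment[i]))
  }
  dup_p <- which(duplicated(participants$participant_id))
  for (i in dup_p) {
    add(i, "duplicate_participant",
        sprintf("duplicated participant id '%s'",
                participants$participant_id[i]))
  }
  if (!is.null(known_cohorts)) {
    bad <- which(!participants$cohort %in% known_cohorts)
    for (i in bad) {
      add(i, "cohort_label",
          sprintf("unknown cohort '%s' (participant %s)",
                  participants$cohort[i], participants$participant_id[i]))
    }
  }
  info <- ratings[ratings$sentiment == "information", ]
  counts <- table(factor(info$participant_id,
                         levels = participants$participant_id))
  incomplete <- names(counts)[counts != length(stim_ids)]
  for (pid in incomplete) {
    add(NA_integer_, "completeness",
        sprintf("participant %s has %d of %d information ratings",
                pid, counts[[pid]], length(stim_ids)))
  }
  violations <- if (length(v)) do.call(rbind, v)
                else tibble::tibble(row = integer(0), check = character(0),
                                    message = character(0))
  structure(list(violations = violations, n_violations = nrow(violations),
                 valid = nrow(violations) == 0L),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (x$valid) {
    cat("<validation_report> clean (0 violations)\n")
  } else {
    cat("<validation_report>", x$n_violations, "violation(s)\n")
    print(head(x$violations, 10))
  }
  invisible(x)
}
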