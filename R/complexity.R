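#' Complexity profile of a single stimulus
#'
#' Bundles the objective information-content measures for one text: prefix
#' entropies H_i, cumulated entropy H_cum = sum(H_i), the vocabulary
#' trajectory n_i, lexical counts, semantic diversity, and any external
#' annotations (e.g. conjunction/adjective counts from a part-of-speech
#' annotation file — never computed in-package).
#'
#' @inheritParams prefix_entropy
#' @param provider embedding provider for semantic diversity; `NULL` skips it.
#' @param annotations optional named numeric vector of external counts.
#' @return A `complexity_profile` list.
#' @export
complexity_profile <- function(stimulus, log_base = "e",
                               provider = stub_embedding(),
                               annotations = NULL) {
  stopifnot(inherits(stimulus, "text_stimulus"))
  h <- prefix_entropy(stimulus, log_base = log_base)
  lc <- lexical_counts(stimulus)
  structure(
    list(
      stimulus_id = stimulus$stimulus_id,
      prefix_entropy = h,
      cumulated_entropy = sum(h),
      vocabulary_trajectory = vocabulary_trajectory(stimulus),
      token_count = lc$token_count,
      unique_count = lc$unique_count,
      semantic_diversity = if (is.null(provider)) NA_real_
                           else semantic_diversity(stimulus, provider),
      annotations = annotations,
      log_base = if (is.character(log_base)) log_base else as.character(log_base)
    ),
    class = "complexity_profile"
  )
}

#' @export
print.complexity_profile <- function(x, ...) {
  cat("<complexity_profile> ", x$stimulus_id,
      ": H_cum = ", format(x$cumulated_entropy, digits = 6),
      " (base ", x$log_base, "), ",
      x$token_count, " tokens / ", x$unique_count, " types\n", sep = "")
  invisible(x)
}

#' Profile a whole stimulus set
#'
#' @param stimuli list of [text_stimulus][tokenize_text] objects.
#' @inheritParams complexity_profile
#' @return List of `complexity_profile`s, names = stimulus ids.
#' @export
complexity_profiles <- function(stimuli, log_base = "e",
                                provider = stub_embedding(),
                                annotations = NULL) {
  out <- lapply(stimuli, function(s) {
    ann <- if (is.null(annotations)) NULL else annotations[[s$stimulus_id]]
    complexity_profile(s, log_base = log_base, provider = provider,
                       annotations = ann)
  })
  names(out) <- vapply(out, `[[`, character(1), "stimulus_id")
  out
}

#' Tabulate profiles as a tibble
#'
#' One row per stimulus: id, token/type counts, H_cum, semantic diversity
#' and one column per annotation. This is the CSV-ready summary schema.
#'
#' @param profiles list of `complexity_profile`s.
#' @return A tibble.
#' @export
profiles_table <- function(profiles) {
  rows <- lapply(profiles, function(p) {
    base <- tibble::tibble(
      stimulus_id = p$stimulus_id,
      token_count = p$token_count,
      unique_count = p$unique_count,
      H_cum = p$cumulated_entropy,
      semantic_diversity = p$semantic_diversity
    )
    if (!is.null(p$annotations)) {
      for (nm in names(p$annotations)) base[[nm]] <- p$annotations[[nm]]
    }
    base
  })
  do.call(rbind, rows)
}

#' Read a stimulus set from a directory or JSON manifest
#'
#' A manifest is a JSON array of objects with fields `stimulus_id` and
#' `raw_text`; a directory is read as one UTF-8 plain-text stimulus per
#' `.txt` file (file stem = stimulus id, lexicographic order).
#'
#' @param path directory or `.json` manifest file.
#' @param config a [tokenizer_config()].
#' @return List of `text_stimulus` objects.
#' @export
read_stimulus_set <- function(path, config = tokenizer_config()) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
    if (length(files) == 0L) stop("no .txt stimuli in ", path, call. = FALSE)
    return(lapply(files, function(f) {
      tokenize_text(paste(readLines(f, encoding = "UTF-8", warn = FALSE),
                          collapse = " "),
                    config = config,
                    stimulus_id = sub("\\.txt$", "", basename(f)))
    }))
  }
  manifest <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  stopifnot(all(c("stimulus_id", "raw_text") %in% names(manifest)))
  lapply(seq_len(nrow(manifest)), function(i) {
    tokenize_text(manifest$raw_text[[i]], config = config,
                  stimulus_id = manifest$stimulus_id[[i]])
  })
}

#' Pairwise correlations among complexity measures
#'
#' Computes the Pearson correlation between every pair of complexity
#' measures across the stimulus set, and summarizes the C(m, 2) pairwise
#' coefficients by their mean, SD, and a one-sample t-test against zero.
#' (Study reports label this summary a "two-sample" t-test although it
#' compares one sample of correlations against a constant; it is computed
#' here as the one-sample test.)
#'
#' @param profiles list of `complexity_profile`s (>= 3 stimuli).
#' @param measures character vector of column names from [profiles_table()]
#'   (default: every numeric measure present with nonzero variance required).
#' @return List with `matrix` (m x m correlation matrix), `pairs` (tibble of
#'   pairwise coefficients) and `summary` (n_pairs, mean, sd, t, df, p).
#' @export
complexity_correlations <- function(profiles,
                                    measures = c("H_cum", "semantic_diversity")) {
  tab <- profiles_table(profiles)
  if (nrow(tab) < 3L) stop("need at least 3 stimuli", call. = FALSE)
  stopifnot(length(measures) >= 2L, all(measures %in% names(tab)))
  x <- as.matrix(tab[, measures, drop = FALSE])
  vs <- apply(x, 2, stats::var)
  if (any(vs == 0)) {
    stop("zero-variance measure(s): ",
         paste(measures[vs == 0], collapse = ", "), call. = FALSE)
  }
  cm <- stats::cor(x)
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  pairs <- tibble::tibble(
    measure_1 = measures[idx[, 1]],
    measure_2 = measures[idx[, 2]],
    r = cm[upper.tri(cm)]
  )
  tt <- one_sample_t(pairs$r, mu0 = 0)
  list(
    matrix = cm,
    pairs = pairs,
    summary = list(n_pairs = nrow(pairs), mean = mean(pairs$r),
                   sd = stats::sd(pairs$r), t = tt$statistic, df = tt$df,
                   p = tt$p)
  )
}
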