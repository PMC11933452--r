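#' Summarize ratings per text and sentiment
#'
#' Mean, SD, SEM, median and quartiles for every text-by-sentiment cell of a
#' cohort, with a Kruskal-Wallis test across texts attached per sentiment.
#' SEM is flagged undefined for single-participant cells.
#'
#' @param ratings long ratings tibble.
#' @param cohort_label label stored with the summary.
#' @return A `rating_summary` list: `table` tibble (sentiment, stimulus_id,
#'   n, mean, sd, sem, median, q1, q3), `kruskal` tibble (sentiment, H, df,
#'   p), `cohort`.
#' @export
summarize_ratings <- function(ratings, cohort_label = "cohort") {
  if (nrow(ratings) == 0L) stop("empty cohort", call. = FALSE)
  cells <- split(ratings, list(ratings$sentiment, ratings$stimulus_id),
                 drop = TRUE)
  tab <- do.call(rbind, lapply(cells, function(g) {
    q <- stats::quantile(g$rating, c(0.25, 0.5, 0.75), names = FALSE)
    n <- nrow(g)
    tibble::tibble(sentiment = g$sentiment[1], stimulus_id = g$stimulus_id[1],
                   n = n, mean = mean(g$rating),
                   sd = if (n > 1) stats::sd(g$rating) else NA_real_,
                   sem = if (n > 1) stats::sd(g$rating) / sqrt(n) else NA_real_,
                   median = q[2], q1 = q[1], q3 = q[3])
  }))
  tab <- tab[order(tab$sentiment, tab$stimulus_id), ]
  kw <- do.call(rbind, lapply(split(ratings, ratings$sentiment), function(g) {
    groups <- split(g$rating, g$stimulus_id)
    if (length(groups) < 2L || all(vapply(groups, function(v)
        length(unique(v)), integer(1)) == 1L) &&
        length(unique(g$rating)) == 1L) {
      # constant ratings: H = 0 by definition
      return(tibble::tibble(sentiment = g$sentiment[1], H = 0,
                            df = length(groups) - 1, p = 1))
    }
    k <- kruskal_wallis(groups)
    tibble::tibble(sentiment = g$sentiment[1], H = k$statistic, df = k$df,
                   p = k$p)
  }))
  structure(list(table = tibble::as_tibble(tab),
                 kruskal = tibble::as_tibble(kw), cohort = cohort_label),
            class = "rating_summary")
}

#' @export
print.rating_summary <- function(x, ...) {
  cat("<rating_summary>", x$cohort, "\n")
  print(x$table, n = 12)
  invisible(x)
}

per_participant_means <- function(ratings) {
  agg <- stats::aggregate(rating ~ participant_id + sentiment, data = ratings,
                          FUN = mean)
  ids <- unique(ratings$participant_id)
  out <- tibble::tibble(participant_id = ids)
  for (s in unique(agg$sentiment)) {
    sel <- agg[agg$sentiment == s, ]
    out[[s]] <- sel$rating[match(ids, sel$participant_id)]
  }
  out
}

#' Cross-sentiment association structure
#'
#' Computes each participant's mean rating over texts per sentiment, then
#' all pairwise Pearson correlations between sentiments with Fisher-z CIs
#' and a Bonferroni-corrected significance threshold (alpha / n_pairs; 10
#' pairs for the five sentiments, threshold 0.005 at alpha 0.05).
#'
#' @param ratings long ratings tibble (>= 4 participants).
#' @param alpha family-wise error level.
#' @return List from [correlation_matrix()] plus `means` (the per-participant
#'   mean table).
#' @export
sentiment_associations <- function(ratings, alpha = 0.05) {
  means <- per_participant_means(ratings)
  if (nrow(means) < 4L) stop("need at least 4 participants", call. = FALSE)
  cm <- correlation_matrix(means[, setdiff(names(means), "participant_id")],
                           alpha = alpha)
  cm$means <- means
  cm
}

#' Correlation between information sensitivity and mean boredom
#'
#' Pearson correlation (with Fisher-z CI) between the per-participant
#' information-sensitivity index and the mean boredom rating over texts.
#' Degenerate fits are excluded.
#'
#' @param cohort_fit a [fit_cohort()] result.
#' @param ratings long ratings tibble for the same participants.
#' @return A `correlation_result`.
#' @export
sensitivity_boredom_link <- function(cohort_fit, ratings) {
  fits <- cohort_fit$fits
  usable <- fits[!fits$degenerate & is.finite(fits$information_sensitivity), ]
  if (nrow(usable) < 4L) stop("fewer than 4 usable fits", call. = FALSE)
  means <- per_participant_means(ratings)
  bored <- means$boredom[match(usable$participant_id, means$participant_id)]
  pearson_ci(usable$information_sensitivity, bored)
}

#' Full control-versus-clinical cohort comparison
#'
#' Composes the between-cohort result set: (i) psychometric scale contrasts
#' via rank-sum; (ii) per text-by-sentiment rank-sum tests with Cohen's d
#' (sign convention clinical - control, so a positive d on boredom means
#' more boredom in the clinical cohort); (iii) the per-sentiment profile of
#' 5 d values (one per text) with pairwise rank-sum comparisons between the
#' information profile and every other sentiment's profile; (iv) the per-text
#' mean entropy contribution of each cohort, compared across the texts with
#' a Wilcoxon signed-rank test (sided-ness configurable and recorded).
#'
#' @param control,clinical lists with elements `participants`, `ratings` and
#'   `fit` (a [fit_cohort()] result) for each cohort.
#' @param scales psychometric scale columns to contrast.
#' @param sensitivity_sides sided-ness of the signed-rank sensitivity
#'   contrast (`"two.sided"` default; `"greater"` tests control > clinical).
#' @return A `cohort_comparison` list.
#' @export
compare_cohorts <- function(control, clinical,
                            scales = c("BPS", "MSBS", "STAI_Y", "BRS",
                                       "neuroticism"),
                            sensitivity_sides = "two.sided") {
  stim_c <- sort(unique(control$ratings$stimulus_id))
  stim_a <- sort(unique(clinical$ratings$stimulus_id))
  if (!identical(stim_c, stim_a)) {
    stop("cohorts were rated on different stimulus sets", call. = FALSE)
  }
  # (i) psychometric contrasts
  scale_tests <- do.call(rbind, lapply(scales, function(sc) {
    a <- clinical$participants[[sc]]; b <- control$participants[[sc]]
    rs <- rank_sum(a, b)
    tibble::tibble(scale = sc, statistic = rs$statistic, p = rs$p, d = rs$d,
                   n_clinical = length(a), n_control = length(b))
  }))
  # (ii) per text x sentiment rating contrasts
  cells <- expand.grid(sentiment = unique(control$ratings$sentiment),
                       stimulus_id = stim_c, stringsAsFactors = FALSE)
  rating_tests <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    s <- cells$sentiment[i]; t <- cells$stimulus_id[i]
    a <- clinical$ratings$rating[clinical$ratings$sentiment == s &
                                 clinical$ratings$stimulus_id == t]
    b <- control$ratings$rating[control$ratings$sentiment == s &
                                control$ratings$stimulus_id == t]
    rs <- rank_sum(a, b)
    tibble::tibble(sentiment = s, stimulus_id = t, statistic = rs$statistic,
                   p = rs$p, d = rs$d)
  }))
  # (iii) per-sentiment |d| profiles, information vs others
  d_profiles <- split(abs(rating_tests$d), rating_tests$sentiment)
  others <- setdiff(names(d_profiles), "information")
  profile_tests <- do.call(rbind, lapply(others, function(s) {
    rs <- rank_sum(d_profiles[["information"]], d_profiles[[s]])
    tibble::tibble(comparison = paste0("information_vs_", s),
                   statistic = rs$statistic, p = rs$p)
  }))
  # (iv) per-text mean entropy contribution, signed-rank over texts
  mc <- control$fit$by_text$mean_external
  ma <- clinical$fit$by_text$mean_external[
    match(control$fit$by_text$stimulus_id, clinical$fit$by_text$stimulus_id)]
  sens_test <- signed_rank_exact(mc - ma, sides = sensitivity_sides)
  structure(
    list(scale_tests = scale_tests,
         rating_tests = tibble::as_tibble(rating_tests),
         d_profiles = d_profiles,
         profile_tests = tibble::as_tibble(profile_tests),
         sensitivity_contrast = list(
           by_text = tibble::tibble(
             stimulus_id = control$fit$by_text$stimulus_id,
             control_mean_entropy_contribution = mc,
             clinical_mean_entropy_contribution = ma),
           test = sens_test,
           mean_control = mean(mc), mean_clinical = mean(ma))),
    class = "cohort_comparison"
  )
}

#' @export
print.cohort_comparison <- function(x, ...) {
  sc <- x$sensitivity_contrast
  cat("<cohort_comparison>\n",
      sprintf("  mean entropy contribution: control %.3f vs clinical %.3f\n",
              sc$mean_control, sc$mean_clinical),
      sprintf("  signed-rank over texts: V = %g, p = %.4g (%s)\n",
              sc$test$statistic, sc$test$p, sc$test$sides))
  invisible(x)
}
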