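big_five <- c("openness", "conscientiousness", "extraversion",
              "agreeableness", "neuroticism")

sentiments <- c("information", "boredom", "creativity", "affect", "arousal")

#' Configuration for a synthetic rating cohort
#'
#' Parameterizes the generative model behind a cohort of raters. Perceived
#' information for participant p and text t follows
#' `mu = s_p * g(H_t) + sum_k w_k * trait_pk + eps`, `eps ~ N(0, sigma^2)`,
#' where `g` is either proportional to entropy rescaled to the rating range
#' (`"linear"`, the default — matching the linear transmission model being
#' fitted, so parameter recovery is well-posed) or a concave inverse-U
#' peaking at `peak_entropy` (`"inverse_U"` — emulating the observed peak of
#' perceived information at intermediate complexity; note the linear fitter
#' then absorbs much of the response into the trait-constant component, so
#' the sensitivity index loses most of its resolution for s_p). Boredom is affine in the latent (pre-noise)
#' perceived information with negative coupling by default; creativity,
#' affect and arousal are affine in the stimulus index. All ratings are
#' clipped to [1, 7] (scale saturation), optionally rounded to integers.
#'
#' Trait scores are BFI-10 sum scores (two 1-5 items per dimension, range
#' 2-10); psychometric scales are sum scores clipped to their instrument
#' ranges.
#'
#' @param n_participants cohort size.
#' @param cohort_label label stored with every participant.
#' @param trait_means,trait_sds named per Big Five dimension (BFI-10 units).
#' @param scale_means,scale_sds named per psychometric scale.
#' @param sensitivity_mean,sensitivity_sd distribution of the per-person
#'   entropy-sensitivity weight s_p (unitless).
#' @param trait_weights named Big Five weights w_k (rating units per trait
#'   unit) on perceived information.
#' @param noise_sd rating noise sigma (rating units).
#' @param response_shape `"linear"` (default) or `"inverse_U"`.
#' @param peak_entropy inverse-U peak H* in entropy units; `NULL` defaults to
#'   midway between the 3rd and 4th stimulus entropies.
#' @param response_scale rating units spanned by g (its value at the peak).
#' @param boredom_intercept,boredom_coupling boredom = intercept + coupling *
#'   latent information + noise; coupling is negative by default.
#' @param index_maps intercept/slope per remaining sentiment as a function of
#'   stimulus index.
#' @param integer_rounding round ratings to whole numbers (the analog scale
#'   is continuous by default).
#' @param seed integer seed.
#' @return A `cohort_gen_config` list.
#' @export
cohort_gen_config <- function(n_participants = 142L,
                              cohort_label = "control",
                              trait_means = c(openness = 7, conscientiousness = 7,
                                              extraversion = 6, agreeableness = 7,
                                              neuroticism = 5),
                              trait_sds = c(openness = 1.5, conscientiousness = 1.5,
                                            extraversion = 1.5, agreeableness = 1.5,
                                            neuroticism = 1.5),
                              scale_means = c(BPS = 90, MSBS = 25,
                                              STAI_Y = 38, BRS = 21),
                              scale_sds = c(BPS = 20, MSBS = 8,
                                            STAI_Y = 9, BRS = 4),
                              sensitivity_mean = 1.0,
                              sensitivity_sd = 0.4,
                              trait_weights = c(openness = 0.060,
                                                conscientiousness = 0.050,
                                                extraversion = 0.045,
                                                agreeableness = 0.040,
                                                neuroticism = 0.035),
                              noise_sd = 0.2,
                              response_shape = c("linear", "inverse_U"),
                              peak_entropy = NULL,
                              response_scale = 3.5,
                              boredom_intercept = 7,
                              boredom_coupling = -0.7,
                              index_maps = list(
                                creativity = c(intercept = 1.2, slope = 0.9),
                                affect = c(intercept = 2.0, slope = 0.7),
                                arousal = c(intercept = 2.6, slope = 0.4)),
                              integer_rounding = FALSE,
                              seed = 1L) {
  response_shape <- match.arg(response_shape)
  stopifnot(noise_sd >= 0, sensitivity_sd >= 0,
            setequal(names(trait_means), big_five),
            setequal(names(trait_weights), big_five))
  structure(
    list(n_participants = as.integer(n_participants),
         cohort_label = cohort_label,
         trait_means = trait_means[big_five], trait_sds = trait_sds[big_five],
         scale_means = scale_means, scale_sds = scale_sds,
         sensitivity_mean = sensitivity_mean, sensitivity_sd = sensitivity_sd,
         trait_weights = trait_weights[big_five],
         noise_sd = noise_sd,
         response_shape = response_shape,
         peak_entropy = peak_entropy,
         response_scale = response_scale,
         boredom_intercept = boredom_intercept,
         boredom_coupling = boredom_coupling,
         index_maps = index_maps,
         integer_rounding = isTRUE(integer_rounding),
         rating_bounds = c(1, 7),
         seed = as.integer(seed)),
    class = "cohort_gen_config"
  )
}

#' Preset for a clinical (ADHD-like) cohort
#'
#' Same generative model as [cohort_gen_config()] with a reduced mean
#' entropy sensitivity and shifted psychometric means (higher boredom
#' proneness, state boredom, anxiety and neuroticism; lower resilience),
#' emulating the clinical contrast of the study design.
#'
#' @param n_participants cohort size (default 19).
#' @param sensitivity_mean reduced mean sensitivity (default 0.6).
#' @param seed integer seed.
#' @param ... further overrides passed to [cohort_gen_config()].
#' @return A `cohort_gen_config`.
#' @export
clinical_cohort_config <- function(n_participants = 19L,
                                   sensitivity_mean = 0.6,
                                   seed = 2L, ...) {
  cohort_gen_config(
    n_participants = n_participants,
    cohort_label = "clinical",
    trait_means = c(openness = 7, conscientiousness = 6, extraversion = 6,
                    agreeableness = 7, neuroticism = 7),
    scale_means = c(BPS = 130, MSBS = 35, STAI_Y = 52, BRS = 16),
    sensitivity_mean = sensitivity_mean,
    seed = seed, ...)
}

scale_ranges <- c(BPS_min = 28, BPS_max = 196, MSBS_min = 8, MSBS_max = 56,
                  STAI_Y_min = 20, STAI_Y_max = 80, BRS_min = 6, BRS_max = 30)

scale_range <- function(scale) {
  c(scale_ranges[[paste0(scale, "_min")]], scale_ranges[[paste0(scale, "_max")]])
}

#' Draw a synthetic participant table and its ground truth
#'
#' Trait and scale scores are normal draws clipped to instrument ranges
#' (BFI-10 sums to [2, 10]); the per-person entropy sensitivity s_p is a
#' normal draw, stored only in the ground-truth table, never among the
#' observables.
#'
#' @param config a [cohort_gen_config()].
#' @return List: `participants` tibble (participant_id, cohort, Big Five and
#'   scale columns), `ground_truth` tibble (participant_id, sensitivity).
#' @export
generate_participants <- function(config) {
  stopifnot(inherits(config, "cohort_gen_config"))
  n <- config$n_participants
  ids <- sprintf("%s_%03d", config$cohort_label, seq_len(n))
  draws <- with_seed(substream_seed(config$seed, "participants"), {
    traits <- sapply(big_five, function(k) {
      pmin(pmax(rnorm(n, config$trait_means[[k]], config$trait_sds[[k]]), 2), 10)
    })
    scales <- sapply(names(config$scale_means), function(k) {
      rng <- scale_range(k)
      pmin(pmax(rnorm(n, config$scale_means[[k]], config$scale_sds[[k]]),
                rng[1]), rng[2])
    })
    s <- rnorm(n, config$sensitivity_mean, config$sensitivity_sd)
    list(traits = traits, scales = scales, s = s)
  })
  participants <- tibble::as_tibble(as.data.frame(draws$traits))
  for (k in colnames(draws$scales)) participants[[k]] <- draws$scales[, k]
  participants <- cbind(
    tibble::tibble(participant_id = ids, cohort = config$cohort_label),
    participants
  )
  list(participants = tibble::as_tibble(participants),
       ground_truth = tibble::tibble(participant_id = ids,
                                     sensitivity = draws$s))
}

# Bounded entropy response g(H): rating units as a function of cumulated
# entropy, either proportional to H or a concave inverse-U peaking at H*.
# The inverse-U uses side-specific widths so g = response_scale at the peak
# and 0 at both ends of the design's entropy range: both the monotonous and
# the maximally random text elicit low perceived information.
entropy_response <- function(h, config) {
  stopifnot(all(is.finite(h)), max(h) > 0)
  if (config$response_shape == "linear") {
    return(config$response_scale * h / max(h))
  }
  hstar <- config$peak_entropy
  if (is.null(hstar)) {
    hstar <- if (length(h) >= 4) mean(sort(h)[3:4]) else mean(range(h))
  }
  w_left <- max(hstar - min(h), .Machine$double.eps)
  w_right <- max(max(h) - hstar, .Machine$double.eps)
  width <- ifelse(h < hstar, w_left, w_right)
  config$response_scale * pmax(1 - ((h - hstar) / width)^2, 0)
}

profile_entropies <- function(profiles) {
  vapply(profiles, `[[`, numeric(1), "cumulated_entropy")
}

#' Simulate sentiment ratings for a participant table
#'
#' Applies the generative model of [cohort_gen_config()] to every
#' (participant, stimulus) cell: perceived information from the entropy
#' response plus trait effects plus noise; boredom affine in the latent
#' perceived information; creativity/affect/arousal affine in stimulus
#' index. All ratings clipped to [1, 7]; the clipped fraction is reported.
#'
#' @param cohort output of [generate_participants()].
#' @param profiles `complexity_profile` list carrying `cumulated_entropy`.
#' @param config the same [cohort_gen_config()].
#' @return List: `ratings` long tibble (participant_id, stimulus_id,
#'   sentiment, rating), `clipped_fraction`.
#' @export
generate_ratings <- function(cohort, profiles, config) {
  h <- profile_entropies(profiles)
  if (any(!is.finite(h))) stop("profiles lack cumulated entropy", call. = FALSE)
  stim_ids <- names(profiles)
  g <- entropy_response(h, config)
  p <- cohort$participants
  s <- cohort$ground_truth$sensitivity[match(p$participant_id,
                                             cohort$ground_truth$participant_id)]
  n <- nrow(p); m <- length(h)
  trait_term <- as.matrix(p[, big_five]) %*% config$trait_weights  # n x 1
  latent_info <- outer(as.numeric(s), g) +
    matrix(trait_term, n, m)                                      # n x m
  idx <- seq_len(m)
  draws <- with_seed(substream_seed(config$seed, "ratings"), {
    list(info = latent_info + matrix(rnorm(n * m, 0, config$noise_sd), n, m),
         bored = config$boredom_intercept +
           config$boredom_coupling * latent_info +
           matrix(rnorm(n * m, 0, config$noise_sd), n, m),
         rest = lapply(config$index_maps, function(ab) {
           matrix(rep(ab[["intercept"]] + ab[["slope"]] * idx, each = n), n, m) +
             matrix(rnorm(n * m, 0, config$noise_sd), n, m)
         }))
  })
  raw <- c(list(information = draws$info, bored = draws$bored), draws$rest)
  names(raw) <- c("information", "boredom", names(config$index_maps))
  lo <- config$rating_bounds[1]; hi <- config$rating_bounds[2]
  total <- 0; clipped <- 0
  long <- lapply(names(raw), function(sent) {
    x <- raw[[sent]]
    total <<- total + length(x)
    clipped <<- clipped + sum(x < lo | x > hi)
    x <- pmin(pmax(x, lo), hi)
    if (config$integer_rounding) x <- round(x)
    tibble::tibble(
      participant_id = rep(p$participant_id, times = m),
      stimulus_id = rep(stim_ids, each = n),
      sentiment = sent,
      rating = as.numeric(x)
    )
  })
  list(ratings = do.call(rbind, long), clipped_fraction = clipped / total)
}

#' Generate a complete two-cohort synthetic dataset
#'
#' Shares one stimulus set between a control and a clinical cohort
#' configuration and records all configs, seeds and the ground-truth
#' sensitivity gap, so every downstream stage (design build, fitting,
#' cohort contrasts) can be exercised end-to-end.
#'
#' @param control_config,clinical_config [cohort_gen_config()]s.
#' @param stimuli output of [generate_stimulus_set()]; built from
#'   `stimulus_config` when `NULL`.
#' @param stimulus_config a [stimulus_gen_config()] used when `stimuli` is
#'   `NULL`.
#' @return A `synthetic_dataset` list: `stimuli`, `profiles`, `participants`
#'   (both cohorts), `ratings` (long), `ground_truth`, `provenance`.
#' @export
generate_two_cohorts <- function(control_config = cohort_gen_config(),
                                 clinical_config = clinical_cohort_config(),
                                 stimuli = NULL,
                                 stimulus_config = stimulus_gen_config()) {
  if (is.null(stimuli)) stimuli <- generate_stimulus_set(stimulus_config)
  profiles <- stimuli$profiles
  cohorts <- lapply(list(control_config, clinical_config), function(cfg) {
    cohort <- generate_participants(cfg)
    r <- generate_ratings(cohort, profiles, cfg)
    list(cohort = cohort, ratings = r)
  })
  structure(
    list(
      stimuli = stimuli$stimuli,
      profiles = profiles,
      participants = rbind(cohorts[[1]]$cohort$participants,
                           cohorts[[2]]$cohort$participants),
      ratings = rbind(cohorts[[1]]$ratings$ratings,
                      cohorts[[2]]$ratings$ratings),
      ground_truth = rbind(
        cbind(cohorts[[1]]$cohort$ground_truth,
              cohort = control_config$cohort_label),
        cbind(cohorts[[2]]$cohort$ground_truth,
              cohort = clinical_config$cohort_label)),
      provenance = list(
        control_config = control_config,
        clinical_config = clinical_config,
        stimulus_config = stimuli$config,
        sensitivity_gap = control_config$sensitivity_mean -
          clinical_config$sensitivity_mean,
        clipped_fraction = c(
          control = cohorts[[1]]$ratings$clipped_fraction,
          clinical = cohorts[[2]]$ratings$clipped_fraction))
    ),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset>", length(x$stimuli), "stimuli;",
      nrow(x$participants), "participants (",
      paste(table(x$participants$cohort), collapse = " + "), ");",
      nrow(x$ratings), "ratings\n")
  invisible(x)
}

#' Convert long ratings to a wide participant-by-column table
#'
#' Columns are named `<sentiment>_<stimulus_id>`.
#'
#' @param ratings long tibble from [generate_ratings()].
#' @return Wide tibble, one row per participant.
#' @export
ratings_wide <- function(ratings) {
  key <- paste(ratings$sentiment, ratings$stimulus_id, sep = "_")
  ids <- unique(ratings$participant_id)
  cols <- unique(key)
  out <- matrix(NA_real_, length(ids), length(cols),
                dimnames = list(ids, cols))
  out[cbind(match(ratings$participant_id, ids), match(key, cols))] <-
    ratings$rating
  tibble::as_tibble(cbind(tibble::tibble(participant_id = ids),
                          as.data.frame(out)))
}
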