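#' Assemble a full pipeline run configuration
#'
#' One object carrying every stage's settings plus the single global seed
#' from which all stage substreams are derived, so a run is fully
#' reproducible from its serialized config. When `simulate = TRUE` the
#' pipeline generates a two-cohort synthetic dataset; otherwise it loads
#' participants/ratings/profiles from the given CSV paths.
#'
#' @param out_dir output directory.
#' @param seed global integer seed; stage seeds are derived substreams.
#' @param lambda ridge strength for the transmission fits.
#' @param shuffle_scheme `"pooled"` or `"within_entropy"`.
#' @param alpha family-wise error level for correlation matrices.
#' @param sensitivity_sides sided-ness of the cohort sensitivity contrast.
#' @param n_shuffle_reps shuffled-null replicates.
#' @param simulate generate synthetic data (default) or load CSVs.
#' @param control_config,clinical_config,stimulus_config generator configs;
#'   defaults are built from the global seed when `NULL`.
#' @param participants_csv,ratings_csv,profiles_manifest input paths when
#'   `simulate = FALSE` (`profiles_manifest` is a stimulus directory or JSON
#'   manifest, scored at load time).
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1L, lambda = 0.2,
                       shuffle_scheme = "pooled", alpha = 0.05,
                       sensitivity_sides = "two.sided",
                       n_shuffle_reps = 1L, simulate = TRUE,
                       control_config = NULL, clinical_config = NULL,
                       stimulus_config = NULL,
                       participants_csv = NULL, ratings_csv = NULL,
                       profiles_manifest = NULL) {
  seed <- as.integer(seed)
  if (is.null(stimulus_config)) {
    stimulus_config <- stimulus_gen_config(seed = substream_seed(seed, "stimuli"))
  }
  if (is.null(control_config)) {
    control_config <- cohort_gen_config(seed = substream_seed(seed, "control"))
  }
  if (is.null(clinical_config)) {
    clinical_config <- clinical_cohort_config(seed = substream_seed(seed, "clinical"))
  }
  structure(
    list(out_dir = out_dir, seed = seed, lambda = lambda,
         shuffle_scheme = shuffle_scheme, alpha = alpha,
         sensitivity_sides = sensitivity_sides,
         n_shuffle_reps = as.integer(n_shuffle_reps),
         simulate = isTRUE(simulate),
         control_config = control_config,
         clinical_config = clinical_config,
         stimulus_config = stimulus_config,
         participants_csv = participants_csv, ratings_csv = ratings_csv,
         profiles_manifest = profiles_manifest),
    class = "run_config"
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("[stage: ", name, "] ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes complexity scoring, (optional) simulation, per-participant
#' transmission fits, the shuffled-data null, and the cohort analyses, and
#' writes all tabular outputs as CSV plus a single JSON report with full
#' method metadata. Deterministic: rerunning with an identical config
#' rewrites byte-identical outputs.
#'
#' @param config a [run_config()].
#' @return Invisibly, the report list (also written to
#'   `<out_dir>/report.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)

  dataset <- stage("data", {
    if (config$simulate) {
      generate_two_cohorts(config$control_config, config$clinical_config,
                           stimulus_config = config$stimulus_config)
    } else {
      stimuli <- read_stimulus_set(config$profiles_manifest)
      list(participants = tibble::as_tibble(read.csv(config$participants_csv)),
           ratings = tibble::as_tibble(read.csv(config$ratings_csv)),
           profiles = complexity_profiles(stimuli),
           ground_truth = NULL, provenance = list(source = "csv"))
    }
  })

  stage("validate", {
    rep <- validate_dataset(dataset$participants, dataset$ratings,
                            dataset$profiles)
    if (!rep$valid) {
      write.csv(rep$violations, out("violations.csv"), row.names = FALSE)
      stop(rep$n_violations, " validation violation(s); see violations.csv")
    }
  })

  cohort_labels <- unique(dataset$participants$cohort)
  per_cohort <- stage("fit", {
    lapply(setNames(cohort_labels, cohort_labels), function(lab) {
      p <- dataset$participants[dataset$participants$cohort == lab, ]
      r <- dataset$ratings[dataset$ratings$participant_id %in%
                             p$participant_id, ]
      design <- build_design(p, r, dataset$profiles)
      list(participants = p, ratings = r, design = design,
           fit = fit_cohort(design, lambda = config$lambda))
    })
  })

  null_cmp <- stage("shuffled_null", {
    shuffled_null(per_cohort[[1]]$design, lambda = config$lambda,
                  scheme = config$shuffle_scheme,
                  seed = substream_seed(config$seed, "null"),
                  n_reps = config$n_shuffle_reps)
  })

  analyses <- stage("analyze", {
    a <- list(
      summaries = lapply(per_cohort, function(co)
        summarize_ratings(co$ratings, co$participants$cohort[1])),
      associations = sentiment_associations(per_cohort[[1]]$ratings,
                                            alpha = config$alpha),
      sensitivity_boredom = lapply(per_cohort, function(co)
        sensitivity_boredom_link(co$fit, co$ratings))
    )
    if (length(per_cohort) == 2L) {
      a$comparison <- compare_cohorts(per_cohort[[1]], per_cohort[[2]],
                                      sensitivity_sides = config$sensitivity_sides)
    }
    a
  })

  stage("write", {
    write.csv(profiles_table(dataset$profiles), out("profiles.csv"),
              row.names = FALSE)
    write.csv(dataset$participants, out("participants.csv"), row.names = FALSE)
    write.csv(dataset$ratings, out("ratings.csv"), row.names = FALSE)
    if (!is.null(dataset$ground_truth)) {
      write.csv(dataset$ground_truth, out("ground_truth.csv"),
                row.names = FALSE)
    }
    for (lab in cohort_labels) {
      write.csv(per_cohort[[lab]]$fit$fits,
                out(paste0("fits_", lab, ".csv")), row.names = FALSE)
      write.csv(per_cohort[[lab]]$fit$contributions,
                out(paste0("contributions_", lab, ".csv")), row.names = FALSE)
    }
    write.csv(null_cmp$per_participant, out("null_comparison.csv"),
              row.names = FALSE)
  })

  report <- list(
    config = list(seed = config$seed, lambda = config$lambda,
                  shuffle_scheme = config$shuffle_scheme,
                  alpha = config$alpha,
                  sensitivity_sides = config$sensitivity_sides,
                  regressor_order = design_columns(),
                  r2_convention = "no-intercept (SST about zero)"),
    stimuli = list(
      n = length(dataset$profiles),
      token_counts = vapply(dataset$profiles, `[[`, numeric(1), "token_count"),
      H_cum = profile_entropies(dataset$profiles)),
    cohorts = lapply(per_cohort, function(co) {
      list(n = nrow(co$participants),
           n_excluded = nrow(co$design$excluded),
           pooled_r2 = co$fit$pooled_r2,
           n_degenerate = co$fit$n_degenerate,
           mean_sensitivity = mean(co$fit$fits$information_sensitivity,
                                   na.rm = TRUE))
    }),
    shuffled_null = list(
      scheme = null_cmp$scheme,
      mean_real_mse = mean(null_cmp$per_participant$real_mse),
      mean_shuffled_mse = mean(null_cmp$per_participant$shuffled_mse),
      p = null_cmp$test$p),
    sensitivity_boredom = lapply(analyses$sensitivity_boredom, function(r)
      list(r = r$r, n = r$n, p = r$p, ci = r$ci)),
    associations = list(threshold = analyses$associations$threshold,
                        n_pairs = analyses$associations$n_pairs),
    provenance = dataset$provenance[setdiff(names(dataset$provenance),
                                            c("control_config",
                                              "clinical_config",
                                              "stimulus_config"))]
  )
  if (!is.null(analyses$comparison)) {
    sc <- analyses$comparison$sensitivity_contrast
    report$cohort_comparison <- list(
      mean_entropy_contribution = list(control = sc$mean_control,
                                       clinical = sc$mean_clinical),
      signed_rank = sc$test[c("statistic", "p", "sides", "n_used")])
  }
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(report = report, per_cohort = per_cohort,
                 null = null_cmp, analyses = analyses, dataset = dataset))
}
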