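design_columns <- function() c("entropy", big_five)

#' Build the transmission-regression design matrix
#'
#' One row per (participant, stimulus): the stimulus cumulated entropy, the
#' participant's five Big Five trait scores (constant across their rows),
#' and the information rating as response. Participants with an incomplete
#' information-rating vector or any missing trait score are excluded and
#' listed, never silently dropped.
#'
#' @param participants tibble with `participant_id` and Big Five columns.
#' @param ratings long ratings tibble (participant_id, stimulus_id,
#'   sentiment, rating).
#' @param profiles `complexity_profile` list.
#' @return List: `design` tibble (participant_id, stimulus_id, entropy,
#'   trait columns, y), `excluded` tibble (participant_id, reason),
#'   `columns` (fixed regressor order).
#' @export
build_design <- function(participants, ratings, profiles) {
  h <- profile_entropies(profiles)
  stim_ids <- names(profiles)
  info <- ratings[ratings$sentiment == "information", , drop = FALSE]
  excluded <- list()
  rows <- list()
  for (i in seq_len(nrow(participants))) {
    pid <- participants$participant_id[i]
    traits <- unlist(participants[i, big_five])
    if (any(!is.finite(traits))) {
      excluded[[pid]] <- "missing trait score"
      next
    }
    ri <- info[info$participant_id == pid, , drop = FALSE]
    y <- ri$rating[match(stim_ids, ri$stimulus_id)]
    if (any(is.na(y))) {
      excluded[[pid]] <- "incomplete information ratings"
      next
    }
    rows[[pid]] <- tibble::tibble(
      participant_id = pid, stimulus_id = stim_ids, entropy = unname(h),
      openness = traits[["openness"]],
      conscientiousness = traits[["conscientiousness"]],
      extraversion = traits[["extraversion"]],
      agreeableness = traits[["agreeableness"]],
      neuroticism = traits[["neuroticism"]],
      y = y)
  }
  if (length(rows) == 0L) stop("no eligible participants", call. = FALSE)
  list(design = do.call(rbind, rows),
       excluded = tibble::tibble(
         participant_id = names(excluded),
         reason = unlist(excluded, use.names = FALSE)),
       columns = design_columns())
}

# Ridge solve of min ||y - Xb||^2 + lambda * n * ||b||^2 without intercept,
# via SVD: b = V diag(d / (d^2 + lambda*n)) U' y. At lambda = 0 with
# rank-deficient X the zero singular directions are dropped, yielding the
# minimum-norm least-squares solution.
ridge_solve <- function(X, y, lambda) {
  stopifnot(lambda >= 0)
  n <- nrow(X)
  sv <- svd(X)
  tol <- max(dim(X)) * .Machine$double.eps * max(sv$d, 0)
  rank_deficient <- any(sv$d <= tol)
  if (lambda == 0) {
    keep <- sv$d > tol
    coef <- ifelse(keep, 1 / sv$d, 0)
  } else {
    coef <- sv$d / (sv$d^2 + lambda * n)
  }
  beta <- sv$v %*% (coef * crossprod(sv$u, y))
  list(beta = as.numeric(beta), rank_deficient = rank_deficient)
}

#' Fit one participant's information-transmission regression
#'
#' No-intercept ridge regression of the participant's information ratings on
#' the six regressors (entropy + Big Five): beta minimizes
#' `sum((y - X beta)^2) + lambda * n_rows * sum(beta^2)`. The per-participant
#' design (5 observations, 6 regressors, 5 constant) is rank-deficient, so a
#' positive ridge strength is the default; at `lambda = 0` the minimum-norm
#' solution is returned and flagged. MSE is the mean squared residual on the
#' fitted rows.
#'
#' @param rows one participant's design rows (from [build_design()]).
#' @param lambda ridge strength >= 0 (default 0.2 = 1/n_rows for 5 texts).
#' @return A `transmission_fit` list: `participant_id`, `beta` (named),
#'   `lambda`, `mse`, `rank_deficient`.
#' @export
fit_participant <- function(rows, lambda = 0.2) {
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  stopifnot(nrow(rows) >= 2L)
  X <- as.matrix(rows[, design_columns()])
  y <- rows$y
  sol <- ridge_solve(X, y, lambda)
  beta <- setNames(sol$beta, design_columns())
  res <- y - as.numeric(X %*% beta)
  structure(
    list(participant_id = rows$participant_id[1], beta = beta,
         lambda = lambda, mse = mean(res^2),
         rank_deficient = sol$rank_deficient),
    class = "transmission_fit"
  )
}

#' @export
print.transmission_fit <- function(x, ...) {
  cat("<transmission_fit>", x$participant_id,
      sprintf("MSE = %.4f, lambda = %g%s\n", x$mse, x$lambda,
              if (x$rank_deficient) " (rank-deficient)" else ""))
  print(round(x$beta, 5))
  invisible(x)
}

#' Per-text contribution decomposition and information sensitivity
#'
#' For each text t and regressor j, the contribution is `|x_jt * beta_j|`,
#' normalized per text to relative contributions r_jt summing to one. The
#' entropy share is the *external* contribution, the summed Big Five shares
#' the *internal* contribution (external + internal = 1 by construction).
#' Information sensitivity is the mean over texts of the entropy share. A
#' text whose contributions are all zero makes the participant degenerate:
#' flagged and excluded from sensitivity summaries, never a silent NaN.
#'
#' @param fit a [fit_participant()] result.
#' @param rows the same participant's design rows.
#' @return List: `relative` tibble (stimulus_id, one column per regressor,
#'   external, internal), `information_sensitivity`, `degenerate`.
#' @export
contributions <- function(fit, rows) {
  X <- as.matrix(rows[, design_columns()])
  raw <- abs(sweep(X, 2, fit$beta, `*`))
  denom <- rowSums(raw)
  degenerate <- any(denom <= 0)
  rel <- raw / ifelse(denom > 0, denom, NA_real_)
  out <- tibble::as_tibble(as.data.frame(rel))
  out <- cbind(tibble::tibble(stimulus_id = rows$stimulus_id), out)
  out$external <- out$entropy
  out$internal <- rowSums(rel[, big_five, drop = FALSE])
  list(relative = tibble::as_tibble(out),
       information_sensitivity = if (degenerate) NA_real_
                                 else mean(rel[, "entropy"]),
       degenerate = degenerate)
}

#' Fit every participant in a design and summarize the cohort
#'
#' Runs [fit_participant()] and [contributions()] per participant and
#' aggregates: per-text mean and SEM of external/internal contributions,
#' per-trait relative-contribution distributions, and the pooled no-intercept
#' R^2 = 1 - SSE/SST with SST = sum(y^2) over all rows (convention recorded
#' in the result).
#'
#' @param design output of [build_design()] (or its `design` tibble).
#' @param lambda ridge strength passed to every participant fit.
#' @return A `cohort_fit` list: `fits` tibble (participant_id, beta columns,
#'   mse, information_sensitivity, rank_deficient, degenerate),
#'   `contributions` long tibble, `by_text` summary tibble, `pooled_r2`,
#'   `r2_convention`, `lambda`, `n_degenerate`.
#' @export
fit_cohort <- function(design, lambda = 0.2) {
  d <- if (is.list(design) && !is.data.frame(design)) design$design else design
  ids <- unique(d$participant_id)
  fit_rows <- list(); contrib_rows <- list()
  sse <- 0; sst <- 0
  for (pid in ids) {
    rows <- d[d$participant_id == pid, , drop = FALSE]
    f <- fit_participant(rows, lambda = lambda)
    co <- contributions(f, rows)
    X <- as.matrix(rows[, design_columns()])
    res <- rows$y - as.numeric(X %*% f$beta)
    sse <- sse + sum(res^2); sst <- sst + sum(rows$y^2)
    fit_rows[[pid]] <- tibble::tibble(
      participant_id = pid,
      beta_entropy = f$beta[["entropy"]],
      beta_openness = f$beta[["openness"]],
      beta_conscientiousness = f$beta[["conscientiousness"]],
      beta_extraversion = f$beta[["extraversion"]],
      beta_agreeableness = f$beta[["agreeableness"]],
      beta_neuroticism = f$beta[["neuroticism"]],
      mse = f$mse,
      information_sensitivity = co$information_sensitivity,
      rank_deficient = f$rank_deficient,
      degenerate = co$degenerate)
    cr <- co$relative
    cr$participant_id <- pid
    contrib_rows[[pid]] <- cr
  }
  fits <- do.call(rbind, fit_rows)
  contrib <- do.call(rbind, contrib_rows)
  ok <- contrib[!is.na(contrib$external), , drop = FALSE]
  by_text <- do.call(rbind, lapply(split(ok, ok$stimulus_id), function(g) {
    tibble::tibble(
      stimulus_id = g$stimulus_id[1], n = nrow(g),
      mean_external = mean(g$external),
      sem_external = stats::sd(g$external) / sqrt(nrow(g)),
      mean_internal = mean(g$internal),
      sem_internal = stats::sd(g$internal) / sqrt(nrow(g)))
  }))
  by_text <- by_text[match(unique(d$stimulus_id), by_text$stimulus_id), ]
  structure(
    list(fits = fits, contributions = tibble::as_tibble(contrib),
         by_text = tibble::as_tibble(by_text),
         pooled_r2 = 1 - sse / sst,
         r2_convention = "no-intercept (SST about zero)",
         lambda = lambda,
         n_degenerate = sum(fits$degenerate)),
    class = "cohort_fit"
  )
}

#' @export
print.cohort_fit <- function(x, ...) {
  cat("<cohort_fit>", nrow(x$fits), "participants, lambda =", x$lambda,
      sprintf("\n  pooled R^2 = %.3f (%s); %d degenerate\n",
              x$pooled_r2, x$r2_convention, x$n_degenerate),
      sprintf(" mean sensitivity = %.3f\n",
              mean(x$fits$information_sensitivity, na.rm = TRUE)))
  invisible(x)
}

#' Shuffled-data null comparison for the transmission fit
#'
#' Refits every participant after permuting the regressor columns and
#' compares real versus shuffled MSE distributions with a rank-sum test.
#' The default `"pooled"` scheme permutes the entropy column across ALL rows
#' (participants and texts pooled) and each trait column across participant
#' blocks, so the x-y pairing is destroyed for every regressor while the
#' shuffled design remains a valid design matrix (trait columns stay
#' constant within a participant — permuting them row-wise would manufacture
#' within-participant trait variation, inflating the per-participant design
#' rank and letting the shuffled refit interpolate rather than act as a
#' null). `"within_entropy"` permutes only the entropy column within each
#' participant's rows (sensitivity analysis — trait columns are left
#' untouched since permuting a constant across a participant's own rows is
#' the identity).
#'
#' @param design output of [build_design()] (or its tibble).
#' @param lambda ridge strength (same in both arms).
#' @param scheme `"pooled"` (default) or `"within_entropy"`.
#' @param seed integer seed for the permutations.
#' @param n_reps shuffled replicates; the per-participant shuffled MSE is
#'   the mean over replicates (default 1, one shuffle per seed).
#' @return A `null_comparison` list: `per_participant` tibble (real_mse,
#'   shuffled_mse), `test` rank-sum result (shuffled vs real), `scheme`,
#'   `seed`, `n_reps`, `lambda`.
#' @export
shuffled_null <- function(design, lambda = 0.2, scheme = c("pooled", "within_entropy"),
                          seed = 1L, n_reps = 1L) {
  scheme <- match.arg(scheme)
  d <- if (is.list(design) && !is.data.frame(design)) design$design else design
  ids <- unique(d$participant_id)
  real <- vapply(ids, function(pid) {
    fit_participant(d[d$participant_id == pid, , drop = FALSE], lambda)$mse
  }, numeric(1))
  cols <- design_columns()
  shuffled_mat <- with_seed(substream_seed(seed, "shuffled_null"), {
    sapply(seq_len(n_reps), function(rep) {
      ds <- d
      if (scheme == "pooled") {
        ds$entropy <- sample(ds$entropy)
        # trait columns: permute the participant -> value assignment so the
        # shuffled design keeps trait columns constant within participant
        for (cl in setdiff(cols, "entropy")) {
          vals <- vapply(ids, function(pid) d[[cl]][d$participant_id == pid][1],
                         numeric(1))
          perm <- setNames(sample(vals), ids)
          ds[[cl]] <- perm[ds$participant_id]
        }
      } else {
        for (pid in ids) {
          sel <- ds$participant_id == pid
          ds$entropy[sel] <- sample(ds$entropy[sel])
        }
      }
      vapply(ids, function(pid) {
        fit_participant(ds[ds$participant_id == pid, , drop = FALSE],
                        lambda)$mse
      }, numeric(1))
    })
  })
  shuffled <- rowMeans(matrix(shuffled_mat, nrow = length(ids)))
  structure(
    list(per_participant = tibble::tibble(participant_id = ids,
                                          real_mse = unname(real),
                                          shuffled_mse = unname(shuffled)),
         test = rank_sum(shuffled, real),
         scheme = scheme, seed = seed, n_reps = n_reps, lambda = lambda),
    class = "null_comparison"
  )
}

#' @export
print.null_comparison <- function(x, ...) {
  cat(sprintf(
    "<null_comparison> scheme = %s: real MSE %.3f vs shuffled %.3f (means), p = %.3g\n",
    x$scheme, mean(x$per_participant$real_mse),
    mean(x$per_participant$shuffled_mse), x$test$p))
  invisible(x)
}
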