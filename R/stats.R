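#' Fisher-z confidence interval for a correlation coefficient
#'
#' CI = tanh(atanh(r) +/- z * / sqrt(n - 3)) with multiplier 1.96 for the
#' 95% level. This is the convention consistent with printed intervals such
#' as r = -0.203, n = 142 -> [-0.356, -0.040].
#'
#' @param r Pearson coefficient, |r| < 1.
#' @param n sample size, >= 4.
#' @param conf confidence level (multiplier 1.96 at the default 0.95).
#' @return Numeric `c(lower, upper)`.
#' @export
fisher_z_ci <- function(r, n, conf = 0.95) {
  stopifnot(n >= 4, abs(r) < 1)
  z <- if (identical(conf, 0.95)) 1.96 else stats::qnorm(1 - (1 - conf) / 2)
  se <- 1 / sqrt(n - 3)
  tanh(atanh(r) + c(-1, 1) * z * se)
}

#' Pearson correlation with Fisher-z CI and t-based p value
#'
#' @param x,y numeric vectors of equal length >= 4 with nonzero variance.
#' @param conf confidence level for the Fisher-z interval.
#' @return A `correlation_result` list: `r`, `n`, `p` (two-sided, t transform
#'   with n - 2 df), `ci` (or `NULL` with `ci_flag` when degenerate: |r| = 1
#'   or n < 4).
#' @export
pearson_ci <- function(x, y, conf = 0.95) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  stopifnot(n >= 3)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance input to correlation", call. = FALSE)
  }
  r <- stats::cor(x, y)
  near_perfect <- abs(r) >= 1 - 1e-12
  if (!near_perfect) {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  } else {
    p <- 0
  }
  degenerate <- near_perfect || n < 4
  structure(
    list(r = r, n = n, p = p,
         ci = if (degenerate) NULL else fisher_z_ci(r, n, conf),
         ci_flag = if (degenerate) "degenerate" else "ok"),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("R_P = %.3f, n = %d, p = %.4g", x$r, x$n, x$p))
  if (!is.null(x$ci)) cat(sprintf(", 95%%-CI = [%.3f %.3f]", x$ci[1], x$ci[2]))
  cat("\n")
  invisible(x)
}

#' Bonferroni-controlled correlation matrix
#'
#' Tests all unordered column pairs with [pearson_ci()] and reports the
#' Bonferroni-adjusted significance threshold alpha / n_pairs alongside the
#' raw p values (raw p values are never adjusted, matching the convention of
#' reporting raw p against a corrected threshold).
#'
#' @param table data.frame/matrix of numeric columns (>= 2).
#' @param alpha family-wise error level.
#' @return List: `results` tibble (var_1, var_2, r, n, p, ci_lower, ci_upper,
#'   significant), `threshold`, `n_pairs`, `matrix`.
#' @export
correlation_matrix <- function(table, alpha = 0.05) {
  x <- as.data.frame(table)
  stopifnot(ncol(x) >= 2L)
  nms <- names(x)
  combs <- utils::combn(nms, 2)
  n_pairs <- ncol(combs)
  threshold <- alpha / n_pairs
  rows <- lapply(seq_len(n_pairs), function(k) {
    a <- combs[1, k]; b <- combs[2, k]
    res <- pearson_ci(x[[a]], x[[b]])
    tibble::tibble(var_1 = a, var_2 = b, r = res$r, n = res$n, p = res$p,
                   ci_lower = if (is.null(res$ci)) NA_real_ else res$ci[1],
                   ci_upper = if (is.null(res$ci)) NA_real_ else res$ci[2],
                   significant = res$p < threshold)
  })
  results <- do.call(rbind, rows)
  cm <- stats::cor(as.matrix(x))
  list(results = results, threshold = threshold, n_pairs = n_pairs,
       matrix = cm)
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic with chi-square p on k - 1 df (wraps
#' [stats::kruskal.test()]).
#'
#' @param groups list of numeric vectors (>= 2 groups, each nonempty).
#' @return List: `statistic`, `df`, `p`, `n`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(vapply(groups, length, integer(1)) == 0L)) {
    stop("empty group in Kruskal-Wallis input", call. = FALSE)
  }
  kt <- stats::kruskal.test(groups)
  list(statistic = unname(kt$statistic), df = as.integer(kt$parameter),
       p = kt$p.value, n = sum(lengths(groups)))
}

#' Wilcoxon rank-sum (Mann-Whitney) test with Cohen's d
#'
#' Exact enumeration when n_a + n_b <= `exact_limit` and there are no ties;
#' otherwise the normal approximation with tie and continuity correction
#' (wraps [stats::wilcox.test()]). Effect size is pooled-SD Cohen's d with
#' sign convention group a - group b.
#'
#' @param a,b numeric vectors, both nonempty.
#' @param sides `"two.sided"` (default), `"less"`, `"greater"`.
#' @param exact_limit combined-size bound for exact enumeration.
#' @return A `two_sample_result` list: `statistic` (U for group a), `p`, `d`,
#'   `n` (c(n_a, n_b)), `method`, `sides`.
#' @export
rank_sum <- function(a, b, sides = c("two.sided", "less", "greater"),
                     exact_limit = 20L) {
  sides <- match.arg(sides)
  stopifnot(length(a) >= 1L, length(b) >= 1L)
  ties <- any(duplicated(c(a, b)))
  use_exact <- (length(a) + length(b)) <= exact_limit && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = sides, exact = use_exact,
                       correct = TRUE)
  )
  d <- if (length(a) >= 2L && length(b) >= 2L &&
           (stats::var(a) > 0 || stats::var(b) > 0)) cohens_d(a, b)
       else NA_real_
  structure(
    list(statistic = unname(wt$statistic), p = wt$p.value, d = d,
         n = c(n_a = length(a), n_b = length(b)),
         method = if (use_exact) "exact" else "normal_approx",
         sides = sides),
    class = "two_sample_result"
  )
}

#' @export
print.two_sample_result <- function(x, ...) {
  cat(sprintf("U = %g, p = %.4g (%s, %s), d = %.3f, n = %d/%d\n",
              x$statistic, x$p, x$method, x$sides,
              if (is.na(x$d)) NA else x$d, x$n[1], x$n[2]))
  invisible(x)
}

#' Wilcoxon signed-rank test on a vector of paired differences
#'
#' Zero differences are dropped before ranking (convention recorded in the
#' result). The null distribution is exact — equivalent to enumerating all
#' 2^n sign patterns — for n <= `exact_limit` without tied absolute
#' differences; otherwise the normal approximation with continuity
#' correction is used.
#'
#' @param differences numeric vector of paired differences.
#' @param sides `"two.sided"` (default), `"less"`, `"greater"`.
#' @param exact_limit size bound for the exact null.
#' @return List: `statistic` (V, sum of positive-difference ranks), `p`,
#'   `n_used`, `n_dropped`, `method`, `sides`, `zero_handling`; degenerate
#'   flag when every difference is zero.
#' @export
signed_rank_exact <- function(differences,
                              sides = c("two.sided", "less", "greater"),
                              exact_limit = 12L) {
  sides <- match.arg(sides)
  d <- differences[differences != 0]
  n_dropped <- length(differences) - length(d)
  if (length(d) == 0L) {
    return(list(statistic = NA_real_, p = NA_real_, n_used = 0L,
                n_dropped = n_dropped, method = "degenerate",
                sides = sides, zero_handling = "drop"))
  }
  ties <- any(duplicated(abs(d)))
  use_exact <- length(d) <= exact_limit && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(d, alternative = sides, exact = use_exact,
                       correct = TRUE)
  )
  list(statistic = unname(wt$statistic), p = wt$p.value,
       n_used = length(d), n_dropped = n_dropped,
       method = if (use_exact) "exact" else "normal_approx",
       sides = sides, zero_handling = "drop")
}

#' Cohen's d with pooled SD
#'
#' d = (mean_a - mean_b) / s_pooled, s_pooled^2 = ((n_a - 1) s_a^2 +
#' (n_b - 1) s_b^2) / (n_a + n_b - 2). Sign convention: group a - group b.
#'
#' @param a,b numeric vectors, each with >= 2 observations.
#' @return Scalar d.
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  stopifnot(na >= 2L, nb >= 2L)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 == 0) stop("zero pooled variance in Cohen's d", call. = FALSE)
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' One-sample t-test against a constant
#'
#' @param values numeric vector, n >= 2, nonzero variance.
#' @param mu0 null value.
#' @return List: `statistic`, `df`, `p` (two-sided), `mean`, `n`.
#' @export
one_sample_t <- function(values, mu0 = 0) {
  stopifnot(length(values) >= 2L)
  if (stats::var(values) == 0) stop("zero variance in t-test", call. = FALSE)
  tt <- stats::t.test(values, mu = mu0)
  list(statistic = unname(tt$statistic), df = length(values) - 1L,
       p = tt$p.value, mean = mean(values), n = length(values))
}
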