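make_small_cohort <- function(n = 20, seed = 41, ...) {
  ss <- generate_stimulus_set()
  cfg <- cohort_gen_config(n_participants = n, seed = seed, ...)
  co <- generate_participants(cfg)
  rt <- generate_ratings(co, ss$profiles, cfg)
  list(stimuli = ss, cohort = co, ratings = rt$ratings,
       design = build_design(co$participants, rt$ratings, ss$profiles))
}

test_that("design matrix has one row per participant-text with exclusions", {
  sc <- make_small_cohort(20)
  d <- sc$design
  expect_identical(nrow(d$design), 100L)  # 20 participants x 5 texts
  expect_identical(nrow(d$excluded), 0L)
  # trait columns constant within participant
  for (pid in unique(d$design$participant_id)[1:3]) {
    rows <- d$design[d$design$participant_id == pid, ]
    expect_identical(length(unique(rows$openness)), 1L)
    expect_identical(nrow(rows), 5L)
  }
  # missing trait -> excluded and listed
  p2 <- sc$cohort$participants
  p2$openness[3] <- NA
  d2 <- build_design(p2, sc$ratings, sc$stimuli$profiles)
  expect_identical(nrow(d2$design), 95L)
  expect_identical(d2$excluded$participant_id, p2$participant_id[3])
  expect_match(d2$excluded$reason, "trait")
  # missing a text's information rating -> excluded
  r3 <- sc$ratings
  drop_row <- which(r3$sentiment == "information" &
                    r3$participant_id == p2$participant_id[1])[1]
  d3 <- build_design(sc$cohort$participants, r3[-drop_row, ],
                     sc$stimuli$profiles)
  expect_identical(nrow(d3$excluded), 1L)
  expect_match(d3$excluded$reason, "incomplete")
  expect_error(build_design(p2[3, ], sc$ratings, sc$stimuli$profiles),
               "eligible")
})

test_that("single-regressor exact fit and shrinkage limit behave", {
  rows <- random_design_rows(5)
  # exact linear relation on the entropy column alone: zero out the rest
  rows$openness <- rows$conscientiousness <- rows$extraversion <- 0
  rows$agreeableness <- rows$neuroticism <- 0
  rows$y <- 2 * rows$entropy
  f <- fit_participant(rows, lambda = 0)
  expect_equal(unname(f$beta[["entropy"]]), 2, tolerance = 1e-8)
  expect_equal(f$mse, 0, tolerance = 1e-12)
  # huge ridge drives beta to 0 and MSE to mean(y^2)
  f2 <- fit_participant(rows, lambda = 1e12)
  expect_true(all(abs(f2$beta) < 1e-6))
  expect_equal(f2$mse, mean(rows$y^2), tolerance = 1e-4)
  expect_error(fit_participant(rows, lambda = -1), "lambda")
})

test_that("ridge fit matches the augmented least-squares oracle", {
  withr::with_seed(17, {
    for (rep in 1:100) {
      rows <- random_design_rows(5)
      lambda <- sample(c(0.05, 0.2, 1), 1)
      f <- fit_participant(rows, lambda = lambda)
      X <- as.matrix(rows[, c("entropy", "openness", "conscientiousness",
                              "extraversion", "agreeableness", "neuroticism")])
      expect_equal(unname(f$beta), unname(oracle_ridge(X, rows$y, lambda)),
                   tolerance = 1e-10)
    }
  })
})

test_that("lambda = 0 on the rank-deficient layout returns flagged min-norm", {
  sc <- make_small_cohort(3)
  rows <- sc$design$design[sc$design$design$participant_id ==
                           sc$design$design$participant_id[1], ]
  f <- fit_participant(rows, lambda = 0)
  expect_true(f$rank_deficient)
  # minimum-norm solution reproduces the least-squares fitted values
  X <- as.matrix(rows[, c("entropy", "openness", "conscientiousness",
                          "extraversion", "agreeableness", "neuroticism")])
  fitted_ls <- fitted(lm(rows$y ~ X - 1))
  expect_equal(as.numeric(X %*% f$beta), unname(fitted_ls), tolerance = 1e-8)
  # and has no larger norm than the pivoted QR particular solution
  b_qr <- qr.coef(qr(X), rows$y)
  b_qr[is.na(b_qr)] <- 0
  expect_lte(sum(f$beta^2), sum(b_qr^2) + 1e-10)
})

test_that("contribution rows are normalized and split external/internal", {
  sc <- make_small_cohort(10)
  d <- sc$design$design
  for (pid in unique(d$participant_id)) {
    rows <- d[d$participant_id == pid, ]
    f <- fit_participant(rows, 0.2)
    co <- contributions(f, rows)
    rel <- as.matrix(co$relative[, c("entropy", "openness",
                                     "conscientiousness", "extraversion",
                                     "agreeableness", "neuroticism")])
    expect_equal(unname(rowSums(rel)), rep(1, 5), tolerance = 1e-12)
    expect_equal(co$relative$external + co$relative$internal, rep(1, 5),
                 tolerance = 1e-12)
    expect_true(co$information_sensitivity >= 0 &&
                co$information_sensitivity <= 1)
  }
})

test_that("pure entropy weights give sensitivity one; symmetry gives 1/6", {
  rows <- random_design_rows(5)
  f <- fit_participant(rows, 0.2)
  f$beta[] <- c(1, 0, 0, 0, 0, 0)
  co <- contributions(f, rows)
  expect_equal(co$relative$external, rep(1, 5))
  expect_equal(co$information_sensitivity, 1)
  # equalized |x_j beta_j| on one text -> each share 1/6
  rows1 <- rows[1, ]
  rows1[, c("entropy", "openness", "conscientiousness", "extraversion",
            "agreeableness", "neuroticism")] <- as.list(rep(2, 6))
  f$beta[] <- rep(0.5, 6)
  co1 <- contributions(f, rows1)
  expect_equal(unlist(co1$relative[1, c("entropy", "openness")],
                      use.names = FALSE), c(1 / 6, 1 / 6), tolerance = 1e-12)
  expect_equal(co1$relative$internal, 5 / 6, tolerance = 1e-12)
  # all-zero denominator flags degeneracy rather than returning NaN silently
  f$beta[] <- rep(0, 6)
  co0 <- contributions(f, rows)
  expect_true(co0$degenerate)
  expect_true(is.na(co0$information_sensitivity))
})

test_that("cohort fit recovers a noise-free linear cohort almost exactly", {
  sc <- make_small_cohort(15, noise_sd = 0, response_shape = "linear")
  cf <- fit_cohort(sc$design, lambda = 0.2)
  expect_gt(cf$pooled_r2, 0.99)
  expect_identical(cf$n_degenerate, 0L)
  # contributions long table rows each sum to one
  rel <- as.matrix(cf$contributions[, c("entropy", "openness",
                                        "conscientiousness", "extraversion",
                                        "agreeableness", "neuroticism")])
  expect_equal(unname(rowSums(rel)), rep(1, nrow(rel)), tolerance = 1e-12)
})

test_that("relative contributions are invariant to entropy rescaling at lambda 0", {
  # full column rank requires >= 6 rows with non-constant trait columns
  rows <- random_design_rows(6)
  f1 <- fit_participant(rows, lambda = 0)
  co1 <- contributions(f1, rows)
  rows2 <- rows
  rows2$entropy <- rows2$entropy * 37
  f2 <- fit_participant(rows2, lambda = 0)
  co2 <- contributions(f2, rows2)
  expect_equal(co1$relative$external, co2$relative$external,
               tolerance = 1e-8)
  # beta itself rescales inversely
  expect_equal(f1$beta[["entropy"]], f2$beta[["entropy"]] * 37,
               tolerance = 1e-8)
})

test_that("shuffled null separates real structure and is deterministic", {
  sc <- make_small_cohort(30, seed = 77)
  nc <- shuffled_null(sc$design, seed = 5)
  expect_gt(mean(nc$per_participant$shuffled_mse >
                 nc$per_participant$real_mse), 0.9)
  nc2 <- shuffled_null(sc$design, seed = 5)
  expect_identical(nc$per_participant$shuffled_mse,
                   nc2$per_participant$shuffled_mse)
  nc3 <- shuffled_null(sc$design, seed = 6)
  expect_false(identical(nc$per_participant$shuffled_mse,
                         nc3$per_participant$shuffled_mse))
  expect_error(shuffled_null(sc$design, scheme = "bogus"))
  # shuffled designs keep trait columns constant within participant:
  # within_entropy scheme must leave trait-only structure untouched, so a
  # cohort with zero entropy effect has shuffled MSE equal to real MSE
  sc0 <- make_small_cohort(10, seed = 3, sensitivity_mean = 0,
                           sensitivity_sd = 0)
  nc0 <- shuffled_null(sc0$design, scheme = "within_entropy", seed = 1)
  # entropy permutation changes nothing about the zero-weight entropy fit
  # only through the column values; MSEs stay close but need not be equal,
  # while the trait contribution to the fit is identical by construction
  expect_equal(dim(nc0$per_participant), c(10L, 3L))
})

test_that("zero-noise strong-entropy cohort: every shuffled fit is worse", {
  sc <- make_small_cohort(25, seed = 13, noise_sd = 0,
                          response_shape = "linear")
  nc <- shuffled_null(sc$design, seed = 2)
  expect_true(all(nc$per_participant$shuffled_mse >
                  nc$per_participant$real_mse))
  expect_lt(nc$test$p, 0.001)
})
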