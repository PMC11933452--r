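# Independent brute-force oracles, deliberately naive: each recomputes its
# quantity from first principles so the tested implementation shares no code
# path with the check.

# Prefix entropies by recounting frequencies from scratch at every prefix.
oracle_prefix_entropy <- function(tokens, base = exp(1)) {
  sapply(seq_along(tokens), function(i) {
    f <- table(tokens[seq_len(i)]) / i
    -sum(f * log(f)) / log(base)
  })
}

# Ridge/min-norm fit via the augmented least-squares system:
# rbind(X, sqrt(lambda * n) * I) \ c(y, 0...) solved densely.
oracle_ridge <- function(X, y, lambda) {
  n <- nrow(X); p <- ncol(X)
  Xa <- rbind(X, sqrt(lambda * n) * diag(p))
  ya <- c(y, rep(0, p))
  qr.coef(qr(Xa), ya)
}

# Exact two-sided rank-sum p by enumerating all assignments of the pooled
# sample to group a (no ties assumed).
oracle_rank_sum_p <- function(a, b, sides = "two.sided") {
  pooled <- c(a, b)
  na <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combs <- utils::combn(length(pooled), na)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  mu <- na * length(b) / 2
  switch(sides,
    two.sided = mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9),
    less = mean(us <= u_obs + 1e-9),
    greater = mean(us >= u_obs - 1e-9))
}

# Exact signed-rank p by enumerating all 2^n sign patterns (no tied |d|).
oracle_signed_rank_p <- function(d, sides = "two.sided") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.numeric(signs %*% r)
  mu <- n * (n + 1) / 4
  switch(sides,
    two.sided = mean(abs(vs - mu) >= abs(v_obs - mu) - 1e-9),
    less = mean(vs <= v_obs + 1e-9),
    greater = mean(vs >= v_obs - 1e-9))
}

# Small deterministic design fixture: one participant's rows with arbitrary
# (non-constant) columns, for exercising the solver outside the 5x6 layout.
random_design_rows <- function(n_rows, id = "p1") {
  tibble::tibble(
    participant_id = id,
    stimulus_id = sprintf("t%d", seq_len(n_rows)),
    entropy = runif(n_rows, 0, 300),
    openness = runif(n_rows, 2, 10),
    conscientiousness = runif(n_rows, 2, 10),
    extraversion = runif(n_rows, 2, 10),
    agreeableness = runif(n_rows, 2, 10),
    neuroticism = runif(n_rows, 2, 10),
    y = runif(n_rows, 1, 7))
}

# Mean information rating per participant, computed naively.
per_participant_means_for_test <- function(ratings) {
  info <- ratings[ratings$sentiment == "information", ]
  tapply(info$rating, info$participant_id, mean)
}

# Pearson coefficient for an unordered variable pair from a
# correlation_matrix()/sentiment_associations() result table.
pair_r <- function(res, a, b) {
  tab <- res$results
  hit <- (tab$var_1 == a & tab$var_2 == b) | (tab$var_1 == b & tab$var_2 == a)
  tab$r[hit]
}
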