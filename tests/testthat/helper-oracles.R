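# Independent oracles and small fixture builders used across the suite.

# Brute-force pairwise concordance AUC: probability that a randomly chosen
# hypolactasic (case, low totals) scores below a randomly chosen
# normolactasic (control), ties counted 1/2.
brute_force_auc <- function(scores, labels,
                            positive = "hypolactasic") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  grid <- outer(pos, neg, function(p, q) (p < q) + 0.5 * (p == q))
  mean(grid)
}

# Weighted Deming loss for fixed weights: sum of weighted squared
# generalized distances to the line y = a + b x with error ratio lambda.
deming_loss <- function(a, b, x, y, w, lambda = 1) {
  r <- y - a - b * x
  sum(w * r^2) / (1 + lambda * b^2)
}

# Closed-form OLS via the normal equations (independent of stats::lm).
ols_normal_equations <- function(x, y) {
  X <- cbind(1, x)
  unname(solve(t(X) %*% X, t(X) %*% y)[, 1])
}

# Small well-formed replicate table.
make_replicate_table <- function(values, nominal = 1.5,
                                 analyzer = "cobas_c502",
                                 level_id = "L01", run_id = "run01",
                                 matrix = "urine") {
  tibble::tibble(
    analyzer = analyzer, matrix = matrix, level_id = level_id,
    nominal_conc = nominal, run_id = run_id,
    replicate_index = seq_along(values), value = values,
    raw_response = NA_real_
  )
}

# Day-grouped duplicate table for variance-component tests.
make_day_duplicates <- function(day_means, within_sd, seed = 1) {
  withr::with_seed(seed, {
    rows <- lapply(seq_along(day_means), function(d) {
      make_replicate_table(
        stats::rnorm(2, day_means[d], within_sd),
        run_id = sprintf("day%02d", d)
      )
    })
    tbl <- do.call(rbind, rows)
    tbl$replicate_index <- stats::ave(tbl$value, tbl$run_id,
                                      FUN = seq_along)
    tbl
  })
}

# Mean of a Gaussian truncated to [lower, upper].
truncnorm_mean <- function(mean, sd, lower, upper) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  z <- pnorm(b) - pnorm(a)
  mean + sd * (dnorm(a) - dnorm(b)) / z
}
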