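test_that("within-run stats agree with a direct mean/SD oracle", {
  withr::with_seed(31, {
    for (i in 1:20) {
      values <- rnorm(15, 3.75, 0.1)
      nominal <- runif(1, 0.5, 8)
      s <- within_run_stats(values, nominal)
      expect_equal(s$mean, mean(values), tolerance = 1e-12)
      expect_equal(s$sd, sd(values), tolerance = 1e-12)
      expect_equal(s$cv_pct, 100 * sd(values) / mean(values),
                   tolerance = 1e-12)
      expect_equal(s$inaccuracy_pct,
                   100 * abs(mean(values) - nominal) / nominal,
                   tolerance = 1e-12)
    }
  })
  exact <- within_run_stats(rep(1.5, 5), 1.5)
  expect_equal(exact$cv_pct, 0)
  expect_equal(exact$inaccuracy_pct, 0)
})

test_that("cross-validation inaccuracy reproduces the printed summary rows", {
  # printed (mean, nominal) pairs; inaccuracy is absolute relative deviation
  expect_equal(within_run_stats(rep(0.730, 2), 0.55)$inaccuracy_pct,
               32.7, tolerance = 0.05)
  expect_equal(within_run_stats(rep(1.680, 2), 1.50)$inaccuracy_pct,
               12.0, tolerance = 0.05)
  # candidate reading below nominal still reports positive inaccuracy
  expect_equal(within_run_stats(rep(0.522, 2), 0.55)$inaccuracy_pct,
               5.1, tolerance = 0.05)
})

test_that("variance components match the sums-of-squares oracle", {
  withr::with_seed(32, {
    day_means <- rnorm(20, 1.0, 0.04)
  })
  tbl <- make_day_duplicates(day_means, within_sd = 0.02, seed = 33)
  vc <- between_run_stats(tbl)

  # direct one-way decomposition, balanced design with 2 replicates/day
  groups <- split(tbl$value, tbl$run_id)
  k <- length(groups)
  n_per <- lengths(groups)
  N <- sum(n_per)
  gm <- mean(tbl$value)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  ssb <- sum(n_per * (vapply(groups, mean, numeric(1)) - gm)^2)
  msw <- ssw / (N - k)
  msb <- ssb / (k - 1)
  var_b <- max(0, (msb - msw) / 2)
  expect_equal(vc$var_within, msw, tolerance = 1e-10)
  expect_equal(vc$var_between, var_b, tolerance = 1e-10)
  expect_equal(vc$within_run_cv_pct, 100 * sqrt(msw) / gm,
               tolerance = 1e-10)
  expect_equal(vc$total_cv_pct,
               100 * sqrt(msw + var_b) / gm, tolerance = 1e-10)
})

test_that("between-run component is clipped at zero and total >= within", {
  withr::with_seed(34, {
    for (i in 1:15) {
      tbl <- make_day_duplicates(rep(1.0, 8), within_sd = 0.05,
                                 seed = 100 + i)
      vc <- between_run_stats(tbl)
      expect_gte(vc$var_between, 0)
      expect_gte(vc$total_cv_pct, vc$within_run_cv_pct)
      expect_equal(vc$total_cv_pct^2,
                   vc$within_run_cv_pct^2 + vc$between_run_cv_pct^2,
                   tolerance = 1e-9)
    }
  })
})

test_that("identical values over all days give all-zero components", {
  tbl <- make_day_duplicates(rep(2.5, 10), within_sd = 0, seed = 1)
  vc <- between_run_stats(tbl)
  expect_equal(vc$within_run_cv_pct, 0)
  expect_equal(vc$between_run_cv_pct, 0)
  expect_equal(vc$total_cv_pct, 0)
})

test_that("a single run is rejected for between-run imprecision", {
  tbl <- make_replicate_table(c(1.5, 1.52, 1.49))
  expect_error(between_run_stats(tbl), "single run")
})

test_that("simulated CV components are recovered over many cohorts", {
  res <- vapply(1:300, function(i) {
    cfg <- precision_sim_config(nominal_levels = 1.0, within_cv_pct = 2,
                                between_cv_pct = 4, n_runs = 20,
                                replicates_per_run = 2, seed = 5000 + i)
    vc <- between_run_stats(simulate_replicates(cfg))
    c(vc$within_run_cv_pct, vc$between_run_cv_pct)
  }, numeric(2))
  expect_equal(mean(res[1, ]), 2, tolerance = 0.1)
  expect_equal(mean(res[2, ]), 4, tolerance = 0.15)
})

test_that("carry-over follows the high-to-low contamination formula", {
  # baseline L run then alternating H/L, noiseless
  seqc <- simulate_carryover_sequence(9.0, 1.5, carryover_pct = 4,
                                      n_pairs = 5, within_cv_pct = 0)
  res <- carryover(seqc$values, seqc$tags)
  expect_equal(res$carryover_pct, 4, tolerance = 1e-10)

  # direct formula oracle: H 9.0, L baseline 1.5, L-after-H 1.8 -> 4.0%
  values <- c(1.5, 1.5, 9.0, 1.8, 9.0, 1.8)
  tags <- c("L", "L", "H", "L", "H", "L")
  expect_equal(carryover(values, tags)$carryover_pct,
               100 * (1.8 - 1.5) / (9.0 - 1.5))

  # no contamination -> 0%; full contamination -> 100%
  expect_equal(carryover(c(1.5, 1.5, 9, 1.5), c("L", "L", "H", "L"))$carryover_pct, 0)
  expect_equal(carryover(c(1.5, 1.5, 9, 9), c("L", "L", "H", "L"))$carryover_pct, 100)
})

test_that("carry-over rejects degenerate or incomplete sequences", {
  expect_error(carryover(c(1.5, 1.5, 9.0), c("L", "L", "H")),
               "no low measurement follows a high")
  expect_error(carryover(c(9.0, 1.8), c("H", "L")), "low-after-low")
  expect_error(carryover(c(1.5, 1.5, 1.5, 1.5), c("L", "L", "H", "L")),
               "degenerate")
  expect_error(carryover(c(1, 2), c("H", "X")), "tags")
})
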