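# End-to-end orchestration: the validation and comparison reports must be
# complete, internally consistent, and reproducible apart from the
# timestamp header.

make_validation_inputs <- function(seed = 1) {
  list(
    linearity = simulate_linearity(
      levels = c(0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4, 5, 6, 7, 8, 10, 12.5, 15),
      slope = 0.0610, intercept = 0.0006, noise_sd = 0.0038,
      replicates = 3, seed = seed
    ),
    blanks = list(
      water = simulate_blanks(60, 0.01, 0.02, seed = seed + 1),
      buffer = simulate_blanks(60, 0.015, 0.02, seed = seed + 2)
    ),
    precision = simulate_replicates(precision_sim_config(
      nominal_levels = c(0.5, 0.75, 0.85, 0.95, 1.5, 3.75, 7.5),
      within_cv_pct = 2, n_runs = 1, replicates_per_run = 20,
      seed = seed + 3
    )),
    between = simulate_replicates(precision_sim_config(
      nominal_levels = 0.84, within_cv_pct = 2, between_cv_pct = 3,
      n_runs = 20, replicates_per_run = 2, seed = seed + 4
    )),
    carry = simulate_carryover_sequence(9.0, 1.5, carryover_pct = 3.3,
                                        n_pairs = 10, within_cv_pct = 1,
                                        seed = seed + 5)
  )
}

test_that("run_validation populates every report block consistently", {
  inp <- make_validation_inputs()
  rep <- run_validation(
    linearity = inp$linearity, blanks = inp$blanks,
    precision_replicates = inp$precision,
    between_run_replicates = inp$between,
    carryover_values = inp$carry$values, carryover_tags = inp$carry$tags,
    basal_means = c(0.05, 0.03, 0.02), analyzer = "cobas_c502"
  )
  expect_s3_class(rep, "validation_report")
  expect_equal(rep$linearity$slope_a, 0.0610, tolerance = 0.02)
  expect_equal(rep$limits$loq / rep$limits$lod, 10 / 3)
  expect_equal(rep$limits$lob,
               max(unlist(rep$limits$lob_per_group)))
  expect_true(rep$limits$lloq_determined)
  # nominal levels well above the LoQ with 2% noise all pass the 20% rules
  expect_lte(rep$limits$lloq, 0.95)
  expect_equal(nrow(rep$within_run), 7)
  vc <- rep$between_run[[1]]
  expect_equal(vc$total_cv_pct^2,
               vc$within_run_cv_pct^2 + vc$between_run_cv_pct^2,
               tolerance = 1e-9)
  expect_equal(rep$carryover$carryover_pct, 3.3, tolerance = 1.5)
  expect_true(rep$selectivity$overall)
})

test_that("validation report files are written and reruns match modulo timestamp", {
  inp <- make_validation_inputs()
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  args <- list(linearity = inp$linearity, blanks = inp$blanks,
               precision_replicates = inp$precision,
               analyzer = "cobas_c502")
  do.call(run_validation, c(args, list(output_dir = dir1)))
  do.call(run_validation, c(args, list(output_dir = dir2)))
  j1 <- jsonlite::read_json(file.path(dir1, "validation_report.json"))
  j2 <- jsonlite::read_json(file.path(dir2, "validation_report.json"))
  j1$timestamp <- j2$timestamp <- NULL
  expect_identical(j1, j2)
  csv <- read.csv(file.path(dir1, "cross_validation.csv"))
  expect_true(all(c("analyzer", "nominal_conc", "mean", "sd", "cv_pct",
                    "inaccuracy_pct") %in% names(csv)))
})

test_that("run_comparison reports all statistics, pre and post adjudication", {
  pairs <- simulate_paired_cohort(cohort_sim_config(seed = 71))
  dir <- withr::local_tempdir()
  rep <- run_comparison(pairs, output_dir = dir)
  rep <- jsonlite::read_json(file.path(dir, "comparison_report.json"))
  for (block in c("deming", "bland_altman_absolute",
                  "bland_altman_percent", "pearson", "roc_before",
                  "kappa_before")) {
    expect_false(is.null(rep[[block]]), label = block)
  }
  expect_gte(rep$kappa_before$kappa, -1)
  expect_lte(rep$kappa_before$kappa, 1)
  expect_equal(rep$candidate_cutoff, rep$roc_before$selected_cutoff)
  expect_lt(rep$bland_altman_absolute$bias, 0)

  # adjudicating a discordant patient reports both before and after
  res <- run_comparison(pairs, candidate_cutoff = 19.18)
  adj <- adjudicate(pairs, 37.87, 19.18)
  if (length(adj$report$discordant_ids) > 0) {
    ov <- tibble::tibble(patient_id = adj$report$discordant_ids[1],
                         adjudicated_label = "normolactasic",
                         reason = "synthetic follow-up")
    rep2 <- run_comparison(pairs, candidate_cutoff = 19.18, overrides = ov)
    expect_false(is.null(rep2$roc_after))
    expect_false(is.null(rep2$kappa_after))
    expect_length(rep2$adjudication$overrides_applied, 1)
  }
})

test_that("identical method columns give kappa 1 and zero bias", {
  pairs <- tibble::tibble(patient_id = sprintf("P%02d", 1:30),
                          method_a_total = seq(5, 75, length.out = 30))
  pairs$method_b_total <- pairs$method_a_total
  rep <- run_comparison(pairs, reference_cutoff = 37.87,
                        candidate_cutoff = 37.87)
  expect_equal(rep$bland_altman_absolute$bias, 0)
  expect_equal(rep$kappa_before$kappa, 1)
})

test_that("undersized cohorts are rejected before any computation", {
  pairs <- tibble::tibble(patient_id = c("a", "b"),
                          method_a_total = c(10, 50),
                          method_b_total = c(5, 40))
  expect_error(run_comparison(pairs), "at least 3 patients")
})
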