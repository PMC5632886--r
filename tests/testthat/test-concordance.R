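test_that("classification is strictly below the cut-off", {
  expect_equal(classify(37.87, 37.87), "normolactasic")
  expect_equal(classify(19.17, 19.18), "hypolactasic")
  expect_equal(classify(0, 37.87), "hypolactasic")
  expect_equal(classify(c(10, 40), 37.87),
               c("hypolactasic", "normolactasic"))
  expect_error(classify(10, 0))
})

test_that("ROC AUC equals brute-force pairwise concordance on random cohorts", {
  withr::with_seed(51, {
    for (i in 1:15) {
      n <- sample(10:50, 1)
      pairs <- tibble::tibble(
        patient_id = sprintf("P%02d", 1:n),
        method_a_total = runif(n, 5, 80),
        method_b_total = round(runif(n, 5, 60), 1) # rounding forces ties
      )
      labels <- classify(pairs$method_a_total, 37.87)
      if (length(unique(labels)) < 2) next
      roc <- roc_transfer(pairs, 37.87)
      expect_equal(roc$auc,
                   brute_force_auc(pairs$method_b_total, labels),
                   tolerance = 1e-12)
    }
  })
})

test_that("perfectly separated scores give AUC 1 and Youden J = 1", {
  pairs <- tibble::tibble(
    patient_id = sprintf("P%02d", 1:12),
    method_a_total = c(rep(20, 6), rep(60, 6)),
    method_b_total = c(runif(6, 2, 10), runif(6, 30, 50))
  )
  roc <- roc_transfer(pairs, 37.87)
  expect_equal(roc$auc, 1)
  expect_equal(roc$youden, 1)
  expect_gt(roc$selected_cutoff, 10)
  expect_lt(roc$selected_cutoff, 30)
})

test_that("identical candidate scores give AUC 0.5", {
  pairs <- tibble::tibble(
    patient_id = sprintf("P%02d", 1:10),
    method_a_total = c(rep(20, 5), rep(60, 5)),
    method_b_total = rep(25, 10)
  )
  expect_equal(roc_transfer(pairs, 37.87)$auc, 0.5)
})

test_that("selected cut-off reproduces the Youden-maximal operating point", {
  withr::with_seed(52, {
    pairs <- simulate_paired_cohort(cohort_sim_config(seed = 53))
  })
  roc <- roc_transfer(pairs, 37.87)
  labels <- classify(pairs$method_a_total, 37.87)
  pred <- classify(pairs$method_b_total, roc$selected_cutoff)
  sens <- mean(pred[labels == "hypolactasic"] == "hypolactasic")
  spec <- mean(pred[labels == "normolactasic"] == "normolactasic")
  expect_equal(sens, roc$sens_at_cutoff, tolerance = 1e-12)
  expect_equal(spec, roc$spec_at_cutoff, tolerance = 1e-12)
  expect_equal(sens + spec - 1, roc$youden, tolerance = 1e-12)
})

test_that("single-class reference labels are rejected", {
  pairs <- tibble::tibble(patient_id = c("a", "b", "c"),
                          method_a_total = c(50, 60, 70),
                          method_b_total = c(30, 40, 50))
  expect_error(roc_transfer(pairs, 37.87), "single class")
})

test_that("kappa matches the hand-computed 2x2 oracle", {
  # both-hypo 50, a-only 10, b-only 10, both-normo 30:
  # p_o = 0.80, p_e = 0.6*0.6 + 0.4*0.4 = 0.52, kappa = 0.28/0.48
  a <- c(rep("hypolactasic", 60), rep("normolactasic", 40))
  b <- c(rep("hypolactasic", 50), rep("normolactasic", 10),
         rep("hypolactasic", 10), rep("normolactasic", 30))
  k <- cohens_kappa(a, b)
  expect_equal(k$kappa, 0.28 / 0.48, tolerance = 1e-12)
  expect_equal(k$p_observed, 0.80)
  expect_equal(k$p_expected, 0.52)
  expect_equal(sum(k$contingency), 100)
  expect_true(k$ci95[1] < k$kappa && k$kappa < k$ci95[2])
})

test_that("kappa is symmetric and label-name invariant", {
  withr::with_seed(54, {
    a <- sample(c("hypolactasic", "normolactasic"), 80, replace = TRUE)
    b <- sample(c("hypolactasic", "normolactasic"), 80, replace = TRUE)
  })
  k1 <- cohens_kappa(a, b)
  k2 <- cohens_kappa(b, a)
  expect_equal(k1$kappa, k2$kappa, tolerance = 1e-12)
  expect_equal(k1$se, k2$se, tolerance = 1e-12)
  swap <- function(x) ifelse(x == "hypolactasic", "normolactasic",
                             "hypolactasic")
  k3 <- cohens_kappa(swap(a), swap(b))
  expect_equal(k3$kappa, k1$kappa, tolerance = 1e-12)
})

test_that("kappa edge cases behave", {
  a <- c("hypolactasic", "normolactasic", "hypolactasic")
  expect_equal(cohens_kappa(a, a)$kappa, 1)
  und <- cohens_kappa(rep("normolactasic", 5), rep("normolactasic", 5))
  expect_equal(und$status, "undefined")
  expect_true(is.na(und$kappa))
})

test_that("independent labels give kappa near zero in expectation", {
  ks <- vapply(1:200, function(i) {
    withr::with_seed(6000 + i, {
      a <- sample(c("hypolactasic", "normolactasic"), 60, replace = TRUE,
                  prob = c(0.3, 0.7))
      b <- sample(c("hypolactasic", "normolactasic"), 60, replace = TRUE,
                  prob = c(0.3, 0.7))
    })
    cohens_kappa(a, b)$kappa
  }, numeric(1))
  expect_lt(abs(mean(ks)), 0.03)
})

test_that("adjudication lists discordant ids and applies overrides only to them", {
  pairs <- tibble::tibble(
    patient_id = c("1", "6", "8", "20"),
    method_a_total = c(50, 35.74, 24.14, 10),  # ref: normo,hypo,hypo,hypo
    method_b_total = c(40, 23.28, 20.65, 5)    # cand: normo,normo,normo,hypo
  )
  res <- adjudicate(pairs, reference_cutoff = 37.87,
                    candidate_cutoff = 19.18)
  expect_setequal(res$report$discordant_ids, c("6", "8"))
  expect_length(res$report$overrides_applied, 0)
  expect_true(all(is.na(res$pairs$adjudicated_label)))

  overrides <- tibble::tibble(
    patient_id = c("6", "8"),
    adjudicated_label = "normolactasic",
    reason = "clinician follow-up: asymptomatic, hospital value above cut-off"
  )
  res2 <- adjudicate(pairs, 37.87, 19.18, overrides)
  expect_length(res2$report$overrides_applied, 2)
  expect_equal(res2$pairs$adjudicated_label,
               c(NA, "normolactasic", "normolactasic", NA))

  # corrected table is concordant everywhere
  lab_a <- ifelse(is.na(res2$pairs$adjudicated_label),
                  classify(res2$pairs$method_a_total, 37.87),
                  res2$pairs$adjudicated_label)
  lab_b <- classify(res2$pairs$method_b_total, 19.18)
  expect_equal(cohens_kappa(lab_a, lab_b)$kappa, 1)

  expect_error(adjudicate(pairs, 37.87, 19.18,
                          tibble::tibble(patient_id = "999",
                                         adjudicated_label = "normolactasic")),
               "unknown patient id.*999")
})
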