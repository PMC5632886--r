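# Seeded generators for every input table the pipeline consumes: replicate
# precision series, linearity series, blank series, carry-over sequences,
# and the paired patient cohort with the constant-positive interfering
# background that separates the reference (phloroglucinol) readings from
# the candidate (enzymatic) ones. All generators are pure functions of
# (config, seed): identical inputs give identical tables.

#' Configuration for replicate precision simulations
#'
#' @param nominal_levels nominal concentrations (mg/dL), one per level.
#' @param within_cv_pct within-run CV in percent.
#' @param between_cv_pct between-run (day-to-day) CV in percent.
#' @param n_runs number of runs (days).
#' @param replicates_per_run replicates per run and level.
#' @param seed integer RNG seed.
#' @param analyzer,matrix labels written into the table.
#' @return a `precision_sim_config` list.
#' @export
precision_sim_config <- function(nominal_levels, within_cv_pct,
                                 between_cv_pct = 0, n_runs = 1L,
                                 replicates_per_run = 20L, seed = 1L,
                                 analyzer = "cobas_c502", matrix = "urine") {
  stopifnot(all(nominal_levels > 0), within_cv_pct >= 0,
            between_cv_pct >= 0, n_runs >= 1L, replicates_per_run >= 1L)
  structure(list(nominal_levels = nominal_levels,
                 within_cv_pct = within_cv_pct,
                 between_cv_pct = between_cv_pct,
                 n_runs = as.integer(n_runs),
                 replicates_per_run = as.integer(replicates_per_run),
                 seed = as.integer(seed), analyzer = analyzer,
                 matrix = matrix),
            class = "precision_sim_config")
}

#' Simulate a replicate measurement table
#'
#' Each measurement is `nominal * (1 + run_effect + within_noise)`: one
#' Gaussian run effect per (level, run) drawn from the between-run CV, and
#' an independent Gaussian within-run deviate per replicate. Multiplicative
#' noise matches how the validation expresses imprecision (CVs).
#'
#' @param cfg a [precision_sim_config()].
#' @return a validated replicate table.
#' @export
simulate_replicates <- function(cfg) {
  stopifnot(inherits(cfg, "precision_sim_config"))
  withr::with_seed(cfg$seed, {
    rows <- list()
    for (li in seq_along(cfg$nominal_levels)) {
      nominal <- cfg$nominal_levels[li]
      for (run in seq_len(cfg$n_runs)) {
        run_effect <- stats::rnorm(1, 0, cfg$between_cv_pct / 100)
        within <- stats::rnorm(cfg$replicates_per_run, 0,
                               cfg$within_cv_pct / 100)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          analyzer = cfg$analyzer, matrix = cfg$matrix,
          level_id = sprintf("L%02d", li), nominal_conc = nominal,
          run_id = sprintf("run%02d", run),
          replicate_index = seq_len(cfg$replicates_per_run),
          value = pmax(0, nominal * (1 + run_effect + within)),
          raw_response = NA_real_
        )
      }
    }
    validate_replicates(do.call(rbind, rows))
  })
}

#' Simulate a linearity series
#'
#' `response = slope * level + intercept + N(0, noise_sd)`, each level
#' measured `replicates` times.
#'
#' @param levels nominal concentrations (mg/dL).
#' @param slope response slope (AU.dL/mg).
#' @param intercept response intercept (AU).
#' @param noise_sd Gaussian response noise SD (AU, >= 0).
#' @param replicates replicates per level.
#' @param seed integer RNG seed.
#' @return tibble with columns `conc` and `response`.
#' @export
simulate_linearity <- function(levels, slope, intercept = 0, noise_sd = 0,
                               replicates = 3L, seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  stopifnot(replicates >= 1L, length(levels) >= 1L)
  conc <- rep(levels, each = replicates)
  withr::with_seed(as.integer(seed), {
    tibble::tibble(
      conc = conc,
      response = slope * conc + intercept +
        stats::rnorm(length(conc), 0, noise_sd)
    )
  })
}

#' Simulate a blank measurement series
#'
#' Additive Gaussian noise around a small blank mean (negative draws kept:
#' instrument blanks can read below zero in response-derived units).
#'
#' @param n number of blank measurements.
#' @param mean,sd blank distribution parameters (mg/dL).
#' @param seed integer RNG seed.
#' @return numeric vector of blank measurements.
#' @export
simulate_blanks <- function(n, mean = 0.02, sd = 0.015, seed = 1L) {
  stopifnot(n >= 2L, sd >= 0)
  withr::with_seed(as.integer(seed), stats::rnorm(n, mean, sd))
}

#' Simulate a carry-over measurement sequence
#'
#' Builds an ordered H/L sequence (a baseline block of low replicates
#' followed by alternating high/low pairs) in which each low measurement
#' directly after a high one is contaminated by `carryover_pct` percent of
#' the high-low difference.
#'
#' @param high_conc,low_conc true concentrations (mg/dL).
#' @param carryover_pct injected carry-over in percent.
#' @param n_pairs number of H-then-L pairs after the baseline block.
#' @param n_baseline number of leading low (uncontaminated) replicates.
#' @param within_cv_pct measurement CV in percent.
#' @param seed integer RNG seed.
#' @return list with `values` and `tags` suitable for [carryover()].
#' @export
simulate_carryover_sequence <- function(high_conc, low_conc, carryover_pct,
                                        n_pairs = 10L, n_baseline = 3L,
                                        within_cv_pct = 0, seed = 1L) {
  stopifnot(high_conc > low_conc, n_pairs >= 1L, n_baseline >= 1L,
            within_cv_pct >= 0)
  tags <- c(rep("L", n_baseline), rep(c("H", "L"), n_pairs))
  truth <- ifelse(tags == "H", high_conc, low_conc)
  prev <- c(NA, tags[-length(tags)])
  contaminated <- tags == "L" & !is.na(prev) & prev == "H"
  truth[contaminated] <- low_conc +
    carryover_pct / 100 * (high_conc - low_conc)
  withr::with_seed(as.integer(seed), {
    values <- truth * (1 + stats::rnorm(length(truth), 0,
                                        within_cv_pct / 100))
  })
  list(values = values, tags = tags)
}

# Truncated-normal sampler via inverse-CDF; deterministic under the caller's
# seed. sd = 0 degenerates to the (in-range) mean.
.rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) {
    if (mean < lower || mean > upper) {
      stop("impossible truncation: degenerate mean outside the range",
           call. = FALSE)
    }
    return(rep(mean, n))
  }
  plo <- stats::pnorm((lower - mean) / sd)
  phi <- stats::pnorm((upper - mean) / sd)
  if (phi - plo < 1e-12) {
    stop("impossible truncation: range carries no probability mass",
         call. = FALSE)
  }
  mean + sd * stats::qnorm(stats::runif(n, plo, phi))
}

#' Configuration for the synthetic paired patient cohort
#'
#' Defaults encode the study conditions of the comparison cohort: 224
#' patients; the phloroglucinol reading carries an interfering positive
#' background with mean 12.92 mg, SD 5.26 mg, truncated to 1.93-22.64 mg
#' (the range observed after placebo administration). Class-conditional
#' true-xylose distributions are log-normal (totals stay positive); their
#' parameters are testing configuration, not epidemiological claims.
#'
#' @param n_patients cohort size.
#' @param prevalence_hypo fraction of truly hypolactasic patients.
#' @param hypo_true_mean,hypo_true_sd true-total distribution (mg) for
#'   hypolactasic patients.
#' @param normo_true_mean,normo_true_sd true-total distribution (mg) for
#'   normolactasic patients.
#' @param background_mean,background_sd,background_range truncated-Gaussian
#'   parameters (mg) of the phloroglucinol-only background.
#' @param measurement_cv_pct length-2 numeric: per-method multiplicative
#'   measurement CV in percent, order (method A = phloroglucinol,
#'   method B = enzymatic).
#' @param seed integer RNG seed.
#' @return a `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(n_patients = 224L, prevalence_hypo = 0.5,
                              hypo_true_mean = 10, hypo_true_sd = 5,
                              normo_true_mean = 50, normo_true_sd = 25,
                              background_mean = 12.92, background_sd = 5.26,
                              background_range = c(1.93, 22.64),
                              measurement_cv_pct = c(5, 5), seed = 1L) {
  stopifnot(n_patients >= 1L, prevalence_hypo >= 0, prevalence_hypo <= 1,
            hypo_true_sd >= 0, normo_true_sd >= 0, background_sd >= 0,
            length(background_range) == 2L,
            background_range[1] <= background_range[2],
            length(measurement_cv_pct) == 2L, all(measurement_cv_pct >= 0))
  structure(list(n_patients = as.integer(n_patients),
                 prevalence_hypo = prevalence_hypo,
                 hypo_true_mean = hypo_true_mean, hypo_true_sd = hypo_true_sd,
                 normo_true_mean = normo_true_mean,
                 normo_true_sd = normo_true_sd,
                 background_mean = background_mean,
                 background_sd = background_sd,
                 background_range = background_range,
                 measurement_cv_pct = measurement_cv_pct,
                 seed = as.integer(seed)),
            class = "cohort_sim_config")
}

# log-normal parameters by moment matching
.lnorm_pars <- function(mean, sd) {
  cv2 <- (sd / mean)^2
  sdlog <- sqrt(log(1 + cv2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a paired patient cohort
#'
#' Per patient: draw the hypolactasic/normolactasic class, then the true
#' excreted xylose `T` from the class-conditional log-normal. The enzymatic
#' reading is `T * (1 + eps_b)`; the phloroglucinol reading is
#' `(T + B) * (1 + eps_a)` with `B` the truncated-Gaussian interfering
#' background — so the reference method reads systematically *high* and
#' Bland-Altman bias (enzymatic - phloroglucinol) is negative, about
#' `-mean(B)`. Both readings are floored at 0.
#'
#' @param cfg a [cohort_sim_config()].
#' @return a validated paired-comparison table; the true class, true totals
#'   and drawn backgrounds are attached as the `"truth"` attribute (a
#'   tibble) for recovery experiments.
#' @export
simulate_paired_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_sim_config"))
  withr::with_seed(cfg$seed, {
    n <- cfg$n_patients
    hypo <- stats::runif(n) < cfg$prevalence_hypo
    t_true <- numeric(n)
    if (any(hypo)) {
      p <- .lnorm_pars(cfg$hypo_true_mean, cfg$hypo_true_sd)
      t_true[hypo] <- stats::rlnorm(sum(hypo), p$meanlog, p$sdlog)
    }
    if (any(!hypo)) {
      p <- .lnorm_pars(cfg$normo_true_mean, cfg$normo_true_sd)
      t_true[!hypo] <- stats::rlnorm(sum(!hypo), p$meanlog, p$sdlog)
    }
    bg <- .rtruncnorm(n, cfg$background_mean, cfg$background_sd,
                      cfg$background_range[1], cfg$background_range[2])
    eps_a <- stats::rnorm(n, 0, cfg$measurement_cv_pct[1] / 100)
    eps_b <- stats::rnorm(n, 0, cfg$measurement_cv_pct[2] / 100)
    pairs <- tibble::tibble(
      patient_id = sprintf("P%03d", seq_len(n)),
      method_a_total = pmax(0, (t_true + bg) * (1 + eps_a)),
      method_b_total = pmax(0, t_true * (1 + eps_b))
    )
    pairs <- validate_comparison(pairs)
    attr(pairs, "truth") <- tibble::tibble(
      patient_id = sprintf("P%03d", seq_len(n)),
      hypolactasic = hypo, true_total = t_true, background = bg
    )
    pairs
  })
}
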