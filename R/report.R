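# Consolidated reports: one orchestrator per study half. run_validation()
# mirrors the validation-parameter table (linearity, limits, CVs,
# inaccuracy, carry-over, selectivity); run_comparison() bundles Deming,
# Bland-Altman, Pearson, ROC transfer (before/after adjudication) and
# kappa. Both write machine-readable JSON; the timestamp is isolated in one
# header field so reruns are otherwise byte-identical.

.report_header <- function(kind) {
  list(report = kind, package = "xylassay",
       version = as.character(utils::packageVersion("xylassay")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

.write_json_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Run the full analytical validation and emit a report
#'
#' Orchestrates linearity fitting, LoB/LoD/LoQ estimation, LLoQ
#' determination from per-level within-run summaries, selectivity,
#' within-run / between-run / total imprecision, and carry-over, for one
#' analyzer. Writes `validation_report.json` (structured like the
#' validation-parameter table) and `cross_validation.csv` (the per-level
#' within-run summary) into `output_dir` when given.
#'
#' @param linearity data frame with `conc` / `response` columns.
#' @param blanks named list of numeric blank-measurement vectors (one per
#'   blank population; the method LoB is the maximum of the group LoBs).
#' @param precision_replicates replicate table for within-run precision and
#'   for LLoQ determination (`nominal_conc` required).
#' @param between_run_replicates replicate table of day-duplicate control
#'   measurements (`value`, `run_id`), or a named list of such tables (one
#'   per control); `NULL` to skip.
#' @param carryover_values,carryover_tags ordered carry-over sequence; both
#'   `NULL` to skip.
#' @param basal_means mean signals of drug-free urine samples for the
#'   selectivity check; `NULL` to skip.
#' @param analyzer analyzer label for the report.
#' @param output_dir directory for the report files, or `NULL` to only
#'   return the report object.
#' @param cv_max,inaccuracy_max LLoQ acceptance thresholds (percent).
#' @param selectivity_fraction fraction of the LLoQ the basal signal must
#'   stay below.
#' @return the report as a nested list (class `validation_report`),
#'   invisibly when written to disk.
#' @export
run_validation <- function(linearity, blanks, precision_replicates,
                           between_run_replicates = NULL,
                           carryover_values = NULL, carryover_tags = NULL,
                           basal_means = NULL, analyzer = "analyzer",
                           output_dir = NULL, cv_max = 20,
                           inaccuracy_max = 20,
                           selectivity_fraction = 0.20) {
  fit <- fit_linearity(linearity)
  lims <- estimate_lod_loq(fit)
  lob <- estimate_lob(blanks)
  if (!is.list(lob)) lob <- list(per_group = c(all = lob), lob = lob)

  summaries <- within_run_summary(precision_replicates)
  # LLoQ is matrix-specific: determined from urine levels when any are
  # present, since buffer controls understate matrix effects at low levels
  precision_replicates <- validate_replicates(precision_replicates)
  lloq_summaries <- if (any(precision_replicates$matrix == "urine")) {
    within_run_summary(
      precision_replicates[precision_replicates$matrix == "urine", ]
    )
  } else summaries
  lloq <- determine_lloq(lloq_summaries, cv_max = cv_max,
                         inaccuracy_max = inaccuracy_max)

  selectivity <- NULL
  if (!is.null(basal_means)) {
    selectivity <- selectivity_check(basal_means, lloq$lloq,
                                     fraction = selectivity_fraction)
  }

  between <- NULL
  if (!is.null(between_run_replicates)) {
    tabs <- if (is.data.frame(between_run_replicates)) {
      list(control = between_run_replicates)
    } else between_run_replicates
    between <- lapply(tabs, function(tab) {
      vc <- between_run_stats(tab)
      vc[c("within_run_cv_pct", "between_run_cv_pct", "total_cv_pct",
           "grand_mean", "n_runs", "n")]
    })
  }

  co <- NULL
  if (!is.null(carryover_values)) {
    co <- carryover(carryover_values, carryover_tags)
  }

  report <- c(.report_header("validation"), list(
    analyzer = analyzer,
    linearity = list(slope_a = fit$slope_a, intercept_y0 = fit$intercept_y0,
                     r_squared = fit$r_squared,
                     residual_cv = fit$residual_cv,
                     conc_range = fit$conc_range, n = fit$n),
    limits = list(lob = lob$lob, lob_per_group = as.list(lob$per_group),
                  lod = lims$lod, loq = lims$loq,
                  lloq = lloq$lloq, lloq_determined = lloq$determined),
    within_run = summaries,
    between_run = between,
    carryover = co,
    selectivity = selectivity
  ))
  class(report) <- c("validation_report", "list")

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    .write_json_report(report, file.path(output_dir,
                                         "validation_report.json"))
    utils::write.csv(summaries,
                     file.path(output_dir, "cross_validation.csv"),
                     row.names = FALSE)
    return(invisible(report))
  }
  report
}

#' Run the full method comparison and emit a report
#'
#' Bundles the paired-comparison statistics: weighted Deming regression,
#' Bland-Altman in absolute and percent modes, Pearson correlation, ROC
#' cut-off transfer, and Cohen's kappa at the reference / candidate
#' cut-offs. When `overrides` are supplied, discordant patients are
#' adjudicated and the ROC and kappa are reported both before and after the
#' correction. Writes `comparison_report.json` into `output_dir` when given.
#'
#' @param pairs a paired-comparison table (or path handled by the caller).
#' @param reference_cutoff reference-method cut-off in mg.
#' @param candidate_cutoff candidate-method cut-off in mg; `NULL` derives it
#'   from the ROC transfer (Youden-maximal threshold).
#' @param lambda Deming measurement-error variance ratio.
#' @param overrides optional adjudication data frame (see [adjudicate()]).
#' @param output_dir directory for the report file, or `NULL`.
#' @return nested report list (class `comparison_report`), invisibly when
#'   written to disk.
#' @export
run_comparison <- function(pairs, reference_cutoff = 37.87,
                           candidate_cutoff = NULL, lambda = 1,
                           overrides = NULL, output_dir = NULL) {
  pairs <- validate_comparison(pairs)
  if (nrow(pairs) < 3L) {
    stop("at least 3 patients required for the comparison", call. = FALSE)
  }
  deming <- weighted_deming(pairs, lambda = lambda)
  ba_abs <- bland_altman(pairs, mode = "absolute")
  ba_pct <- bland_altman(pairs, mode = "percent")
  pear <- pearson_correlation(pairs)
  roc_before <- roc_transfer(pairs, reference_cutoff)
  if (is.null(candidate_cutoff)) {
    candidate_cutoff <- roc_before$selected_cutoff
  }
  labels_a <- .reference_labels(pairs, reference_cutoff)
  labels_b <- classify(pairs$method_b_total, candidate_cutoff)
  kappa_before <- cohens_kappa(labels_a, labels_b)

  adj <- NULL
  roc_after <- NULL
  kappa_after <- NULL
  if (!is.null(overrides)) {
    adj <- adjudicate(pairs, reference_cutoff, candidate_cutoff, overrides)
    roc_after <- roc_transfer(adj$pairs, reference_cutoff)
    labels_a2 <- .reference_labels(adj$pairs, reference_cutoff)
    kappa_after <- cohens_kappa(labels_a2, labels_b)
  }

  strip <- function(x) {
    if (is.null(x)) return(NULL)
    x[!(names(x) %in% c("averages", "differences", "thresholds",
                        "sensitivities", "specificities"))]
  }
  kap <- function(k) {
    if (is.null(k)) return(NULL)
    list(kappa = k$kappa, se = k$se, ci95 = k$ci95,
         contingency = as.vector(k$contingency),
         p_observed = k$p_observed, p_expected = k$p_expected,
         n = k$n, status = k$status)
  }
  report <- c(.report_header("comparison"), list(
    n = nrow(pairs),
    difference_orientation = "enzymatic_minus_phloroglucinol",
    reference_cutoff = reference_cutoff,
    candidate_cutoff = candidate_cutoff,
    deming = unclass(deming),
    bland_altman_absolute = strip(unclass(ba_abs)),
    bland_altman_percent = strip(unclass(ba_pct)),
    pearson = pear,
    roc_before = strip(unclass(roc_before)),
    kappa_before = kap(kappa_before),
    adjudication = if (is.null(adj)) NULL else adj$report,
    roc_after = strip(unclass(roc_after)),
    kappa_after = kap(kappa_after)
  ))
  class(report) <- c("comparison_report", "list")

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    .write_json_report(report, file.path(output_dir,
                                         "comparison_report.json"))
    return(invisible(report))
  }
  report
}
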