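# Imprecision and inaccuracy: within-run summaries, the one-way (days as
# runs) variance-component decomposition behind between-run and total CVs,
# and the high-low carry-over estimate.

#' Within-run precision and accuracy summary
#'
#' Mean, SD (n-1), CV% = 100*SD/mean and inaccuracy% = 100*|mean - nominal|
#' / nominal for one level on one analyzer. Inaccuracy is the absolute
#' relative deviation, so under- and over-recovery both report positive.
#'
#' @param values replicate measurements (mg/dL).
#' @param nominal nominal concentration of the level (mg/dL, > 0).
#' @param analyzer,level_id optional labels carried into the summary.
#' @return one-row tibble: `analyzer`, `level_id`, `nominal_conc`, `n`,
#'   `mean`, `sd`, `cv_pct`, `inaccuracy_pct`.
#' @export
within_run_stats <- function(values, nominal, analyzer = NA_character_,
                             level_id = NA_character_) {
  stopifnot(is.numeric(values), length(nominal) == 1L)
  if (length(values) < 2L) {
    stop("at least 2 replicates required", call. = FALSE)
  }
  if (!is.finite(nominal) || nominal <= 0) {
    stop("nominal concentration must be positive", call. = FALSE)
  }
  m <- mean(values)
  s <- stats::sd(values)
  tibble::tibble(
    analyzer = analyzer, level_id = level_id, nominal_conc = nominal,
    n = length(values), mean = m, sd = s,
    cv_pct = 100 * s / m,
    inaccuracy_pct = 100 * abs(m - nominal) / nominal
  )
}

#' Within-run summaries for every (analyzer, level) cell of a table
#'
#' Applies [within_run_stats()] to each (analyzer, level_id) group of a
#' replicate table; this is the cross-validation summary shape (one row per
#' analyzer and urine level).
#'
#' @param tbl a validated replicate table with `nominal_conc` set.
#' @return tibble of per-cell summaries, ordered by analyzer then nominal.
#' @export
within_run_summary <- function(tbl) {
  tbl <- validate_replicates(tbl)
  if (any(is.na(tbl$nominal_conc))) {
    stop("nominal_conc required for every row", call. = FALSE)
  }
  groups <- split(tbl, list(tbl$analyzer, tbl$level_id), drop = TRUE)
  out <- lapply(groups, function(g) {
    within_run_stats(g$value, g$nominal_conc[1],
                     analyzer = g$analyzer[1], level_id = g$level_id[1])
  })
  out <- do.call(rbind, out)
  out <- out[order(out$analyzer, out$nominal_conc), ]
  rownames(out) <- NULL
  out
}

#' Between-run and total imprecision by variance-component decomposition
#'
#' One-way random-effects ANOVA with runs (days) as the grouping factor.
#' The within-run variance is the pooled within-day mean square; the
#' between-run variance is `max(0, (MS_between - MS_within) / n0)` with
#' `n0` the (average) replicates per run, so it never goes negative. CVs
#' are expressed relative to the grand mean, and the total CV is the
#' root-sum-of-squares of the two components, so
#' `total^2 = within^2 + between^2` holds by construction.
#'
#' @param tbl a replicate table (or any data frame) with columns `value`
#'   and `run_id`; typically duplicates of one control measured over
#'   consecutive days.
#' @return object of class `variance_components`: `within_run_cv_pct`,
#'   `between_run_cv_pct`, `total_cv_pct`, plus the variance components,
#'   `grand_mean`, `n_runs` and `n`.
#' @export
between_run_stats <- function(tbl) {
  stopifnot(is.data.frame(tbl), all(c("value", "run_id") %in% names(tbl)))
  run <- factor(tbl$run_id)
  value <- tbl$value
  k <- nlevels(run)
  if (k < 2L) {
    stop("between-run imprecision undefined with a single run", call. = FALSE)
  }
  n_per <- table(run)
  if (max(n_per) < 2L) {
    stop("at least one run needs 2 or more replicates", call. = FALSE)
  }
  # all-identical values are legitimate (zero imprecision); drop the
  # perfect-fit notice the F-table emits for them
  aov_tab <- withCallingHandlers(
    stats::anova(stats::lm(value ~ run)),
    warning = function(w) {
      if (grepl("perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  ms_between <- aov_tab$`Mean Sq`[1]
  ms_within <- aov_tab$`Mean Sq`[2]
  n_total <- length(value)
  # unbalanced-design effective replicates per run
  n0 <- (n_total - sum(n_per^2) / n_total) / (k - 1)
  var_within <- ms_within
  var_between <- max(0, (ms_between - ms_within) / n0)
  gm <- mean(value)
  cv <- function(v) 100 * sqrt(v) / gm
  structure(list(
    within_run_cv_pct = cv(var_within),
    between_run_cv_pct = cv(var_between),
    total_cv_pct = cv(var_within + var_between),
    var_within = var_within, var_between = var_between,
    grand_mean = gm, n_runs = k, n = n_total
  ), class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat("Variance components (", x$n, " measurements over ", x$n_runs,
      " runs, grand mean ", sprintf("%.3f", x$grand_mean), " mg/dL)\n",
      sep = "")
  cat(sprintf("  within-run CV  %.2f%%\n", x$within_run_cv_pct))
  cat(sprintf("  between-run CV %.2f%%\n", x$between_run_cv_pct))
  cat(sprintf("  total CV       %.2f%%\n", x$total_cv_pct))
  invisible(x)
}

#' Carry-over from an ordered high/low measurement sequence
#'
#' Contamination of a low sample by a preceding high sample:
#' `100 * (mean(L after H) - mean(L after L)) / (mean(H) - mean(L after L))`.
#' Accepts any ordered sequence of H/L tags — both a block design (a run of
#' L replicates then alternating H, L) and a repeated H-then-L sequence.
#' The first measurement has no predecessor and only contributes to the H
#' mean if tagged H.
#'
#' @param values measured concentrations in assay order (mg/dL).
#' @param tags character vector of `"H"` / `"L"` tags, same length.
#' @return list with `carryover_pct` (may be negative; reported as-is) and
#'   the three means it derives from.
#' @export
carryover <- function(values, tags) {
  stopifnot(length(values) == length(tags), is.numeric(values))
  if (!all(tags %in% c("H", "L"))) {
    stop("tags must be 'H' or 'L'", call. = FALSE)
  }
  n <- length(values)
  if (n < 2L) stop("sequence too short", call. = FALSE)
  prev <- c(NA, tags[-n])
  l_after_h <- values[tags == "L" & !is.na(prev) & prev == "H"]
  l_after_l <- values[tags == "L" & !is.na(prev) & prev == "L"]
  h_vals <- values[tags == "H"]
  if (length(l_after_h) == 0L) {
    stop("no low measurement follows a high one: carry-over pattern missing",
         call. = FALSE)
  }
  if (length(l_after_l) == 0L) {
    stop("no low-after-low baseline measurements in the sequence",
         call. = FALSE)
  }
  if (length(h_vals) == 0L) stop("no high measurements", call. = FALSE)
  denom <- mean(h_vals) - mean(l_after_l)
  if (denom == 0) {
    stop("degenerate sequence: high mean equals low baseline", call. = FALSE)
  }
  list(
    carryover_pct = 100 * (mean(l_after_h) - mean(l_after_l)) / denom,
    mean_l_after_h = mean(l_after_h),
    mean_l_after_l = mean(l_after_l),
    mean_h = mean(h_vals)
  )
}
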