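# Detection capability: LoB from blank replicates, LoD/LoQ from the
# linearity regression, LLoQ from per-level precision/accuracy, and the
# selectivity rule for basal (drug-free) urine.

#' Limit of blank from blank replicate measurements
#'
#' `LoB = mean + 1.645 * SD` of the blank measurements (sample SD, n-1
#' denominator). When several blank populations are supplied (e.g. distilled
#' water and assay buffer analyzed separately), each gets its own LoB and
#' the method LoB is the maximum of the group values — the conservative
#' combination.
#'
#' @param blanks numeric vector of blank measurements (mg/dL), or a named
#'   list of such vectors, one per blank population.
#' @return for a vector, the LoB (mg/dL); for a list, a list with
#'   `per_group` (named numeric) and `lob` (the method LoB, their maximum).
#' @export
estimate_lob <- function(blanks) {
  one <- function(x, label = NULL) {
    if (length(x) < 2L) {
      stop("at least 2 blank measurements required",
           if (!is.null(label)) paste0(" (group '", label, "')") else "",
           call. = FALSE)
    }
    mean(x) + 1.645 * stats::sd(x)
  }
  if (is.list(blanks) && !is.data.frame(blanks)) {
    per <- vapply(seq_along(blanks),
                  function(i) one(blanks[[i]], names(blanks)[i]),
                  numeric(1))
    names(per) <- names(blanks)
    return(list(per_group = per, lob = max(per)))
  }
  stopifnot(is.numeric(blanks))
  one(blanks)
}

#' Limits of detection and quantification from a linearity fit
#'
#' Regression-based estimators: `LoD = 3 * CV / a` and `LoQ = 10 * CV / a`,
#' where `a` is the linearity slope (AU.dL/mg) and `CV` the residual
#' dispersion of the linearity fit in response units (see
#' [fit_linearity()]). The multipliers force `LoQ / LoD = 10 / 3` exactly.
#'
#' @param fit a `linearity_fit`, or any list with elements `slope_a` and
#'   `residual_cv` (so printed fit parameters can be used directly).
#' @return list with `lod` and `loq` in mg/dL.
#' @export
estimate_lod_loq <- function(fit) {
  stopifnot(is.list(fit), !is.null(fit$slope_a), !is.null(fit$residual_cv))
  if (!is.finite(fit$slope_a) || fit$slope_a <= 0) {
    stop("invalid fit: slope must be positive", call. = FALSE)
  }
  if (fit$residual_cv < 0) {
    stop("invalid fit: residual dispersion must be non-negative",
         call. = FALSE)
  }
  list(lod = 3 * fit$residual_cv / fit$slope_a,
       loq = 10 * fit$residual_cv / fit$slope_a)
}

#' Lower limit of quantification from per-level summaries
#'
#' The LLoQ is the lowest nominal concentration whose imprecision (CV%) and
#' absolute inaccuracy (%) both stay within the acceptance threshold
#' (default 20%, inclusive — a level sitting exactly at 20.0% passes, per
#' the bioanalytical-validation guidelines' "should not exceed 20%").
#'
#' @param summaries data frame with columns `nominal_conc`, `cv_pct`,
#'   `inaccuracy_pct` (one row per level).
#' @param cv_max,inaccuracy_max acceptance thresholds in percent.
#' @return list with `lloq` (mg/dL, `NA` if undetermined), `determined`
#'   (logical), and `table` (the input with a `pass` flag).
#' @export
determine_lloq <- function(summaries, cv_max = 20, inaccuracy_max = 20) {
  stopifnot(is.data.frame(summaries))
  if (nrow(summaries) == 0L) {
    stop("no level summaries supplied", call. = FALSE)
  }
  need <- c("nominal_conc", "cv_pct", "inaccuracy_pct")
  missing_cols <- setdiff(need, names(summaries))
  if (length(missing_cols) > 0L) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  tbl <- tibble::as_tibble(summaries)
  tbl$pass <- tbl$cv_pct <= cv_max & abs(tbl$inaccuracy_pct) <= inaccuracy_max
  passing <- tbl$nominal_conc[tbl$pass]
  if (length(passing) == 0L) {
    return(list(lloq = NA_real_, determined = FALSE, table = tbl))
  }
  list(lloq = min(passing), determined = TRUE, table = tbl)
}

#' Selectivity check on basal urine samples
#'
#' Interference is absent when the mean signal of each drug-free (basal)
#' urine sample stays strictly below a fraction (default 20%) of the LLoQ.
#'
#' @param basal_means mean measured signals (mg/dL) of the basal samples.
#' @param lloq the LLoQ in mg/dL (must be determined).
#' @param fraction acceptance fraction of the LLoQ.
#' @return list with `threshold`, per-sample `pass` flags, and `overall`.
#' @export
selectivity_check <- function(basal_means, lloq, fraction = 0.20) {
  if (is.na(lloq)) {
    stop("LLoQ is undetermined: selectivity check not possible",
         call. = FALSE)
  }
  stopifnot(lloq > 0, fraction > 0, is.numeric(basal_means))
  threshold <- fraction * lloq
  pass <- basal_means < threshold
  list(threshold = threshold, pass = pass, overall = all(pass))
}
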