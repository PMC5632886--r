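# Photometric response model of the two-reagent enzymatic assay: the NADH
# absorbance increase at 340 nm is proportional to sample xylose, so
# concentration follows from a single-point calibration, and assay quality
# from an ordinary least-squares linearity fit.

#' Single-point calibration record
#'
#' The analyzers are calibrated with one xylose standard (default
#' 3.75 mg/dL) and water as the sample blank.
#'
#' @param calibrator_response absorbance response of the calibrator (AU).
#' @param blank_response absorbance response of the water blank (AU).
#' @param calibrator_conc calibrator concentration in mg/dL.
#' @return an object of class `calibration_record`.
#' @export
calibration_record <- function(calibrator_response, blank_response,
                               calibrator_conc = 3.75) {
  stopifnot(length(calibrator_response) == 1L, length(blank_response) == 1L,
            length(calibrator_conc) == 1L)
  if (!is.finite(calibrator_conc) || calibrator_conc <= 0) {
    stop("calibrator_conc must be positive", call. = FALSE)
  }
  if (calibrator_response == blank_response) {
    stop("degenerate calibration: calibrator response equals blank response",
         call. = FALSE)
  }
  if (calibrator_response < blank_response) {
    stop("calibrator response must exceed the blank response", call. = FALSE)
  }
  structure(list(calibrator_conc = calibrator_conc,
                 calibrator_response = calibrator_response,
                 blank_response = blank_response),
            class = "calibration_record")
}

#' Concentration from a sample response by single-point calibration
#'
#' Linear interpolation through the blank and the single calibrator:
#' `conc = calibrator_conc * (r - r_blank) / (r_cal - r_blank)`.
#' Sub-blank responses give negative concentrations; they are returned
#' as-is with a warning so downstream QC can flag them.
#'
#' @param sample_response absorbance response(s) of the sample(s) (AU).
#' @param cal a [calibration_record()].
#' @return concentration(s) in mg/dL.
#' @export
single_point_calibrate <- function(sample_response, cal) {
  stopifnot(inherits(cal, "calibration_record"))
  span <- cal$calibrator_response - cal$blank_response
  if (span == 0) {
    stop("degenerate calibration: zero response span", call. = FALSE)
  }
  conc <- cal$calibrator_conc * (sample_response - cal$blank_response) / span
  if (any(conc < 0)) {
    warning(sum(conc < 0), " sample(s) below blank: negative concentration",
            call. = FALSE)
  }
  conc
}

#' Linearity fit of response against nominal concentration
#'
#' Ordinary least squares of the absorbance response on the nominal
#' concentration; replicate points enter individually (no pre-averaging), so
#' residual degrees of freedom are preserved. The residual dispersion
#' `residual_cv` is the standard deviation (n-1 denominator) of the fit
#' residuals, in response units; it feeds the regression-based LoD/LoQ
#' estimators ([estimate_lod_loq()]).
#'
#' @param conc nominal concentrations (mg/dL), or a data frame with columns
#'   `conc` and `response`.
#' @param response absorbance responses (AU); ignored when `conc` is a data
#'   frame.
#' @return an object of class `linearity_fit` with `slope_a`,
#'   `intercept_y0`, `r_squared`, `residual_cv`, `conc_range` and `n`.
#' @export
fit_linearity <- function(conc, response = NULL) {
  if (is.data.frame(conc)) {
    stopifnot(all(c("conc", "response") %in% names(conc)))
    response <- conc$response
    conc <- conc$conc
  }
  stopifnot(length(conc) == length(response), is.numeric(conc),
            is.numeric(response))
  if (length(unique(conc)) < 2L) {
    stop("rank-deficient design: all concentration levels identical",
         call. = FALSE)
  }
  if (length(unique(conc)) < 3L) {
    stop("at least 3 distinct concentration levels required", call. = FALSE)
  }
  fit <- stats::lm(response ~ conc)
  res <- stats::residuals(fit)
  # noiseless series are a supported case; drop the perfect-fit notice
  r2 <- withCallingHandlers(
    summary(fit)$r.squared,
    warning = function(w) {
      if (grepl("perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  structure(list(
    slope_a = unname(stats::coef(fit)["conc"]),
    intercept_y0 = unname(stats::coef(fit)["(Intercept)"]),
    r_squared = r2,
    residual_cv = stats::sd(res),
    conc_range = range(conc),
    n = length(conc)
  ), class = "linearity_fit")
}

#' @export
print.linearity_fit <- function(x, ...) {
  cat("Linearity fit (OLS, n =", x$n, "points)\n")
  cat(sprintf("  slope a      %.4f AU.dL/mg\n", x$slope_a))
  cat(sprintf("  intercept y0 %.4f\n", x$intercept_y0))
  cat(sprintf("  R^2          %.4f\n", x$r_squared))
  cat(sprintf("  residual CV  %.4f AU\n", x$residual_cv))
  cat(sprintf("  range        %.2f-%.2f mg/dL\n",
              x$conc_range[1], x$conc_range[2]))
  invisible(x)
}

#' Reagent on-board stability as recovery traces
#'
#' For each control series measured over storage days, reports recovery per
#' day under two definitions: percent of the day-1 value, and (when an
#' assigned control value is supplied) percent of the assigned value. Each
#' day is flagged pass/fail against a recovery band (default 85-115%).
#' Both definitions are reported because neither is universally the one a
#' kit insert quotes.
#'
#' @param series data frame with columns `day` (integer, strictly increasing
#'   per control), `control_id`, `measured_conc` (mg/dL).
#' @param assigned optional named numeric vector of assigned control
#'   concentrations, names matching `control_id`.
#' @param band numeric length-2 acceptance band in percent.
#' @return a tibble with one row per (control, day): recovery percentages
#'   and pass flags.
#' @export
stability_recovery <- function(series, assigned = NULL, band = c(85, 115)) {
  stopifnot(is.data.frame(series),
            all(c("day", "control_id", "measured_conc") %in% names(series)),
            length(band) == 2L, band[1] < band[2])
  if (nrow(series) == 0L) stop("empty stability series", call. = FALSE)
  out <- lapply(split(series, series$control_id), function(s) {
    s <- s[order(s$day), , drop = FALSE]
    if (any(diff(s$day) <= 0)) {
      stop("days must be strictly increasing within control '",
           s$control_id[1], "'", call. = FALSE)
    }
    day1 <- s$measured_conc[1]
    if (day1 == 0) {
      stop("day-1 value is 0 for control '", s$control_id[1],
           "': recovery undefined", call. = FALSE)
    }
    rec1 <- 100 * s$measured_conc / day1
    reca <- rep(NA_real_, nrow(s))
    if (!is.null(assigned) && s$control_id[1] %in% names(assigned)) {
      reca <- 100 * s$measured_conc / assigned[[s$control_id[1]]]
    }
    tibble::tibble(
      control_id = s$control_id, day = s$day,
      measured_conc = s$measured_conc,
      recovery_vs_day1_pct = rec1,
      recovery_vs_assigned_pct = reca,
      pass_day1 = rec1 >= band[1] & rec1 <= band[2],
      pass_assigned = ifelse(is.na(reca), NA,
                             reca >= band[1] & reca <= band[2])
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
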