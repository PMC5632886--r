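# Paired method comparison: errors-in-both-variables (Deming) regression
# with the Linnet-style iteratively reweighted variant, Bland-Altman
# agreement in absolute and percent-of-average modes, and Pearson
# correlation. Orientation throughout: x = method A (reference,
# phloroglucinol), y = method B (candidate, enzymatic); differences are
# y - x, so a candidate reading low gives a negative bias.

.resolve_pairs <- function(x, y) {
  if (is.data.frame(x)) {
    x <- validate_comparison(x)
    list(x = x$method_a_total, y = x$method_b_total)
  } else {
    stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
    list(x = x, y = y)
  }
}

# Closed-form (weighted) Deming estimate. lambda is the ratio of the x
# measurement-error variance to the y measurement-error variance.
.deming_estimate <- function(x, y, w, lambda) {
  sw <- sum(w)
  mx <- sum(w * x) / sw
  my <- sum(w * y) / sw
  u <- sum(w * (x - mx)^2)
  q <- sum(w * (y - my)^2)
  p <- sum(w * (x - mx) * (y - my))
  if (p == 0) stop("degenerate pairs: zero covariance", call. = FALSE)
  slope <- ((lambda * q - u) +
              sqrt((u - lambda * q)^2 + 4 * lambda * p^2)) / (2 * lambda * p)
  c(slope = slope, intercept = my - slope * mx)
}

# One full (optionally reweighted) fit; returns slope/intercept/weights and
# iteration diagnostics.
.deming_fit_once <- function(x, y, lambda, weighted, max_iter, tol) {
  w <- rep(1, length(x))
  est <- .deming_estimate(x, y, w, lambda)
  iterations <- 0L
  converged <- TRUE
  if (weighted) {
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      b <- est["slope"]; a <- est["intercept"]
      d <- y - (a + b * x)
      xhat <- x + lambda * b * d / (1 + lambda * b^2)
      yhat <- y - d / (1 + lambda * b^2)
      level <- (xhat + yhat) / 2
      if (any(level <= 0)) {
        stop("weighted Deming requires positive fitted levels; ",
             "check for zero/negative totals", call. = FALSE)
      }
      w <- 1 / level^2
      new_est <- .deming_estimate(x, y, w, lambda)
      rel <- max(abs(new_est - est) / pmax(abs(est), 1e-12))
      est <- new_est
      iterations <- it
      if (rel < tol) {
        converged <- TRUE
        break
      }
    }
  }
  list(slope = unname(est["slope"]), intercept = unname(est["intercept"]),
       weights = w, iterations = iterations, converged = converged)
}

#' Deming regression for paired method-comparison data
#'
#' Errors-in-both-variables straight-line fit of the candidate method (y,
#' enzymatic totals) on the reference method (x, phloroglucinol totals).
#' With `weighted = TRUE` (the default) the fit is iteratively reweighted
#' with weights `1 / level^2`, where `level` is the average of the fitted x
#' and y for each pair — the standard weighted-Deming convention for assays
#' whose error scales with concentration. Iteration stops when the relative
#' parameter change drops below `tol` (default 1e-10) or after `max_iter`
#' rounds; non-convergence is flagged in the result, not raised.
#'
#' Confidence intervals come from a leave-one-out jackknife with a
#' t-quantile on n - 2 degrees of freedom — deterministic, no resampling.
#'
#' @param x reference-method totals (mg), or a paired-comparison table
#'   (then `y` is ignored).
#' @param y candidate-method totals (mg).
#' @param lambda ratio of the x to the y measurement-error variance;
#'   defaults to 1 (equal error).
#' @param weighted logical; `FALSE` gives the unweighted Deming fit.
#' @param conf_level confidence level for the jackknife intervals.
#' @param max_iter,tol reweighting iteration controls.
#' @param ci logical; set `FALSE` to skip the jackknife (point estimate only).
#' @return object of class `deming_fit`: `slope`, `intercept`,
#'   `slope_ci95`, `intercept_ci95`, `slope_se`, `intercept_se`, `lambda`,
#'   `weighted`, `n`, `converged`, `iterations`.
#' @export
weighted_deming <- function(x, y = NULL, lambda = 1, weighted = TRUE,
                            conf_level = 0.95, max_iter = 100L,
                            tol = 1e-10, ci = TRUE) {
  p <- .resolve_pairs(x, y)
  x <- p$x; y <- p$y
  n <- length(x)
  if (n < 3L) stop("at least 3 pairs required", call. = FALSE)
  stopifnot(lambda > 0)
  if (weighted && any(x <= 0 | y <= 0)) {
    stop("weighted Deming requires strictly positive totals (pairs ",
         paste(which(x <= 0 | y <= 0), collapse = ", "), ")", call. = FALSE)
  }
  fit <- .deming_fit_once(x, y, lambda, weighted, max_iter, tol)
  slope_ci <- intercept_ci <- c(NA_real_, NA_real_)
  slope_se <- intercept_se <- NA_real_
  if (ci) {
    jack <- vapply(seq_len(n), function(i) {
      f <- .deming_fit_once(x[-i], y[-i], lambda, weighted, max_iter, tol)
      c(f$slope, f$intercept)
    }, numeric(2))
    theta_bar <- rowMeans(jack)
    se <- sqrt((n - 1) / n *
                 rowSums((jack - theta_bar)^2))
    tq <- stats::qt(1 - (1 - conf_level) / 2, df = n - 2)
    slope_se <- se[1]; intercept_se <- se[2]
    slope_ci <- fit$slope + c(-1, 1) * tq * slope_se
    intercept_ci <- fit$intercept + c(-1, 1) * tq * intercept_se
  }
  structure(list(
    slope = fit$slope, intercept = fit$intercept,
    slope_ci95 = slope_ci, intercept_ci95 = intercept_ci,
    slope_se = slope_se, intercept_se = intercept_se,
    lambda = lambda, weighted = weighted, n = n,
    converged = fit$converged, iterations = fit$iterations,
    conf_level = conf_level
  ), class = "deming_fit")
}

#' @export
print.deming_fit <- function(x, ...) {
  kind <- if (x$weighted) "Weighted Deming" else "Deming"
  cat(kind, " regression (n = ", x$n, ", lambda = ", x$lambda, ")\n",
      sep = "")
  cat(sprintf("  slope     %.4f  [%.4f, %.4f]\n",
              x$slope, x$slope_ci95[1], x$slope_ci95[2]))
  cat(sprintf("  intercept %.4f  [%.4f, %.4f]\n",
              x$intercept, x$intercept_ci95[1], x$intercept_ci95[2]))
  if (!x$converged) cat("  WARNING: reweighting did not converge\n")
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Differences are candidate minus reference (`method_b - method_a`). In
#' `"absolute"` mode differences are in mg; in `"percent"` mode each
#' difference is expressed as a percentage of the average of the two
#' measurements (which must be positive). The limits of agreement are
#' `bias +/- 1.96 * SD` of the differences.
#'
#' @inheritParams weighted_deming
#' @param mode `"absolute"` or `"percent"`.
#' @return object of class `bland_altman`: `mode`, `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `n`, plus the per-pair `averages` and
#'   `differences` for plotting.
#' @export
bland_altman <- function(x, y = NULL, mode = c("absolute", "percent")) {
  mode <- match.arg(mode)
  p <- .resolve_pairs(x, y)
  x <- p$x; y <- p$y
  if (length(x) < 2L) stop("at least 2 pairs required", call. = FALSE)
  avg <- (x + y) / 2
  d <- y - x
  if (mode == "percent") {
    bad <- avg <= 0
    if (any(bad)) {
      stop("percent mode requires positive pair averages (pairs ",
           paste(which(bad), collapse = ", "), ")", call. = FALSE)
    }
    d <- 100 * d / avg
  }
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(
    mode = mode, bias = bias, sd_diff = s,
    loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
    n = length(x), averages = avg, differences = d
  ), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  unit <- if (x$mode == "percent") "%" else " mg"
  cat("Bland-Altman (", x$mode, " mode, n = ", x$n, ")\n", sep = "")
  cat(sprintf("  bias %.2f%s, limits of agreement [%.2f, %.2f]%s\n",
              x$bias, unit, x$loa_low, x$loa_high, unit))
  invisible(x)
}

#' Pearson correlation between the two methods
#'
#' Product-moment correlation with the two-sided t-test p-value, via
#' [stats::cor.test()].
#'
#' @inheritParams weighted_deming
#' @return list with `r`, `p_value`, `ci95`, `n`.
#' @export
pearson_correlation <- function(x, y = NULL) {
  p <- .resolve_pairs(x, y)
  x <- p$x; y <- p$y
  if (length(x) < 3L) stop("at least 3 pairs required", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance in one method", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value,
       ci95 = as.numeric(ct$conf.int), n = length(x))
}
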