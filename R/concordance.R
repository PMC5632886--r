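# Diagnostic concordance: classification at a cut-off (strictly below =
# hypolactasic), transfer of the decision threshold to the candidate method
# via an ROC curve against reference-method labels, chance-corrected
# agreement (Cohen's kappa), and adjudication of discordant patients.

.XYL_LABELS <- c("hypolactasic", "normolactasic")

#' Classify total urinary xylose at a cut-off
#'
#' A total strictly below the cut-off is classified hypolactasic; at or
#' above, normolactasic (low xylose excretion indicates low lactase
#' activity).
#'
#' @param totals total urinary xylose in mg.
#' @param cutoff decision threshold in mg (> 0).
#' @return character vector of `"hypolactasic"` / `"normolactasic"`.
#' @export
classify <- function(totals, cutoff) {
  stopifnot(is.numeric(totals), length(cutoff) == 1L, cutoff > 0)
  ifelse(totals < cutoff, .XYL_LABELS[1], .XYL_LABELS[2])
}

# Reference labels for a paired table: adjudicated label wins, then an
# explicit reference label, then classification of method A at the cut-off.
.reference_labels <- function(pairs, reference_cutoff) {
  lab <- classify(pairs$method_a_total, reference_cutoff)
  if ("reference_label" %in% names(pairs)) {
    keep <- !is.na(pairs$reference_label)
    lab[keep] <- pairs$reference_label[keep]
  }
  if ("adjudicated_label" %in% names(pairs)) {
    keep <- !is.na(pairs$adjudicated_label)
    lab[keep] <- pairs$adjudicated_label[keep]
  }
  lab
}

#' Transfer the diagnostic cut-off to the candidate method via ROC
#'
#' Treats the reference-method classification at `reference_cutoff` as
#' truth and builds the empirical ROC of the candidate totals
#' (`method_b_total`) against it. Hypolactasic patients have *low* totals,
#' so the curve is oriented with controls (normolactasic) above cases. The
#' AUC is the empirical (trapezoidal) area, equal to the pairwise rank
#' statistic with ties counted 1/2, with a DeLong 95% CI. The transferred
#' cut-off maximizes Youden's J = sensitivity + specificity - 1; ties break
#' toward the lower threshold. Thresholds sit at midpoints between adjacent
#' sorted unique totals (with infinite sentinels).
#'
#' @param pairs a validated paired-comparison table; adjudicated labels,
#'   when present, override the cut-off classification.
#' @param reference_cutoff reference-method cut-off in mg (default 37.87).
#' @return object of class `roc_transfer`: `thresholds`, `sensitivities`,
#'   `specificities`, `auc`, `auc_ci95`, `selected_cutoff`,
#'   `selection_rule`, `youden`, `sens_at_cutoff`, `spec_at_cutoff`, `n`.
#' @export
roc_transfer <- function(pairs, reference_cutoff = 37.87) {
  pairs <- validate_comparison(pairs)
  labels <- .reference_labels(pairs, reference_cutoff)
  if (length(unique(labels)) < 2L) {
    stop("degenerate ROC: reference labels contain a single class",
         call. = FALSE)
  }
  roc <- pROC::roc(response = labels, predictor = pairs$method_b_total,
                   levels = c("normolactasic", "hypolactasic"),
                   direction = ">", quiet = TRUE)
  # pROC warns that a degenerate (width-zero) CI accompanies AUC == 1;
  # expected for separable synthetic cohorts, so not re-raised
  auc_ci <- withCallingHandlers(
    as.numeric(pROC::ci.auc(roc, method = "delong")),
    warning = function(w) {
      if (grepl("always 1-1", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  co <- pROC::coords(roc, "all", ret = c("threshold", "sensitivity",
                                         "specificity"),
                     transpose = FALSE)
  youden <- co$sensitivity + co$specificity - 1
  best <- which(youden == max(youden))
  # ties toward the lower threshold
  sel <- best[which.min(co$threshold[best])]
  structure(list(
    thresholds = co$threshold,
    sensitivities = co$sensitivity,
    specificities = co$specificity,
    auc = as.numeric(pROC::auc(roc)),
    auc_ci95 = auc_ci[c(1, 3)],
    selected_cutoff = co$threshold[sel],
    selection_rule = "youden_max_lower_threshold_tiebreak",
    youden = max(youden),
    sens_at_cutoff = co$sensitivity[sel],
    spec_at_cutoff = co$specificity[sel],
    n = nrow(pairs)
  ), class = "roc_transfer")
}

#' @export
print.roc_transfer <- function(x, ...) {
  cat("ROC cut-off transfer (n = ", x$n, ")\n", sep = "")
  cat(sprintf("  AUC %.3f [%.3f, %.3f] (DeLong)\n",
              x$auc, x$auc_ci95[1], x$auc_ci95[2]))
  cat(sprintf("  selected cut-off %.2f mg (J = %.3f; sens %.3f, spec %.3f)\n",
              x$selected_cutoff, x$youden, x$sens_at_cutoff,
              x$spec_at_cutoff))
  invisible(x)
}

#' Cohen's kappa for two binary classifications
#'
#' Chance-corrected agreement from the 2x2 contingency table:
#' `kappa = (p_o - p_e) / (1 - p_e)`. The standard error is the
#' Fleiss-Cohen-Everitt large-sample estimate and the 95% CI is
#' `kappa +/- 1.96 * SE`.
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @return object of class `kappa_result`: `kappa`, `se`, `ci95`,
#'   `contingency`, `p_observed`, `p_expected`, `n`; `kappa` is `NA` with
#'   `status = "undefined"` when both raters are constant and identical
#'   (expected agreement 1).
#' @export
cohens_kappa <- function(labels_a, labels_b) {
  stopifnot(length(labels_a) == length(labels_b), length(labels_a) >= 1L)
  lev <- sort(unique(c(labels_a, labels_b)))
  a <- factor(labels_a, levels = lev)
  b <- factor(labels_b, levels = lev)
  tab <- table(a, b)
  n <- length(labels_a)
  p <- tab / n
  po <- sum(diag(p))
  marg_a <- rowSums(p)
  marg_b <- colSums(p)
  pe <- sum(marg_a * marg_b)
  if (abs(1 - pe) < .Machine$double.eps^0.5) {
    return(structure(list(kappa = NA_real_, se = NA_real_,
                          ci95 = c(NA_real_, NA_real_), contingency = tab,
                          p_observed = po, p_expected = pe, n = n,
                          status = "undefined"),
                     class = "kappa_result"))
  }
  kappa <- (po - pe) / (1 - pe)
  # Fleiss, Cohen & Everitt large-sample variance
  k_lev <- length(lev)
  sum1 <- 0
  for (i in seq_len(k_lev)) {
    sum1 <- sum1 + p[i, i] *
      ((1 - pe) - (marg_a[i] + marg_b[i]) * (1 - po))^2
  }
  sum2 <- 0
  for (i in seq_len(k_lev)) {
    for (j in seq_len(k_lev)) {
      if (i != j) {
        sum2 <- sum2 + p[i, j] * (marg_b[i] + marg_a[j])^2
      }
    }
  }
  sum2 <- sum2 * (1 - po)^2
  term3 <- (po * pe - 2 * pe + po)^2
  var_k <- (sum1 + sum2 - term3) / (n * (1 - pe)^4)
  se <- sqrt(max(0, var_k))
  structure(list(kappa = unname(kappa), se = unname(se),
                 ci95 = unname(kappa + c(-1, 1) * 1.96 * se),
                 contingency = tab, p_observed = unname(po),
                 p_expected = unname(pe), n = n, status = "ok"),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  if (identical(x$status, "undefined")) {
    cat("Cohen's kappa: undefined (expected agreement = 1)\n")
    return(invisible(x))
  }
  cat(sprintf("Cohen's kappa %.4f (SE %.4f, 95%% CI %.4f-%.4f, n = %d)\n",
              x$kappa, x$se, x$ci95[1], x$ci95[2], x$n))
  invisible(x)
}

#' Adjudicate discordant classifications between the two methods
#'
#' Classifies every patient by both methods at their respective cut-offs,
#' lists the discordant patient ids, and applies clinician overrides (each
#' an id, a corrected label, and a reason) by setting `adjudicated_label`
#' for those ids only. The corrected table can then be re-run through
#' [roc_transfer()] and [cohens_kappa()].
#'
#' @param pairs a validated paired-comparison table.
#' @param reference_cutoff reference-method cut-off in mg.
#' @param candidate_cutoff candidate-method cut-off in mg.
#' @param overrides optional data frame with columns `patient_id`,
#'   `adjudicated_label`, and optionally `reason`.
#' @return list with `pairs` (corrected table) and `report` (list:
#'   `discordant_ids`, `overrides_applied`).
#' @export
adjudicate <- function(pairs, reference_cutoff = 37.87,
                       candidate_cutoff, overrides = NULL) {
  pairs <- validate_comparison(pairs)
  stopifnot(length(candidate_cutoff) == 1L, candidate_cutoff > 0)
  lab_a <- .reference_labels(pairs, reference_cutoff)
  lab_b <- classify(pairs$method_b_total, candidate_cutoff)
  discordant <- pairs$patient_id[lab_a != lab_b]
  applied <- list()
  if (!is.null(overrides) && nrow(overrides) > 0L) {
    stopifnot(all(c("patient_id", "adjudicated_label") %in% names(overrides)))
    unknown <- setdiff(as.character(overrides$patient_id), pairs$patient_id)
    if (length(unknown) > 0L) {
      stop("override(s) for unknown patient id(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    bad <- !(overrides$adjudicated_label %in% .XYL_LABELS)
    if (any(bad)) {
      stop("invalid override label(s): ",
           paste(overrides$adjudicated_label[bad], collapse = ", "),
           call. = FALSE)
    }
    for (i in seq_len(nrow(overrides))) {
      id <- as.character(overrides$patient_id[i])
      row <- match(id, pairs$patient_id)
      pairs$adjudicated_label[row] <- overrides$adjudicated_label[i]
      applied[[length(applied) + 1L]] <- list(
        patient_id = id,
        new_label = overrides$adjudicated_label[i],
        reason = if ("reason" %in% names(overrides))
          overrides$reason[i] else NA_character_
      )
    }
  }
  list(pairs = pairs,
       report = list(discordant_ids = discordant,
                     overrides_applied = applied))
}
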