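## Baseline-toxicity QSAR and sensitivity-ratio classification.
##
## Baseline (narcosis) toxicity is the minimal nonspecific toxicity
## expected from membrane partitioning alone; it is predicted from the
## liposome-water distribution ratio at pH 7.4 (log D_lipw) with a fish
## embryo QSAR of the form log10(1/LC50[mol/L]) = a * logDlipw + b.
## A compound acts specifically on angiogenesis when its ISV IC50 lies
## far below both the predicted baseline LC50 (SR_baseline > 10) and the
## observed mortality LC50 (SR_mortality > 4).

#' QSAR coefficients for baseline toxicity
#'
#' Slope and intercept of the fish-embryo baseline-toxicity QSAR applied
#' as log10(1/LC50\[mol/L\]) = slope * logDlipw + intercept.  The defaults
#' are kept in configuration rather than hard-coded in the formula so
#' that updated QSARs can be supplied.
#'
#' @param slope per log-unit of D_lipw.
#' @param intercept on the log10 mol/L scale.
#' @return an object of class `qsar_coefficients`.
#' @export
qsar_coefficients <- function(slope = 0.99, intercept = 0.78) {
  structure(list(slope = slope, intercept = intercept),
            class = "qsar_coefficients")
}

#' Predict baseline-toxicity LC50 from hydrophobicity
#'
#' @param log_dlipw log10 liposome-water distribution ratio at pH 7.4
#'   (vectorized).
#' @param coef a [qsar_coefficients()] object.
#' @return predicted baseline LC50 in µM.
#' @export
predict_baseline_lc50 <- function(log_dlipw, coef = qsar_coefficients()) {
  if (any(!is.finite(log_dlipw))) stopf("`log_dlipw` must be finite")
  10^(-(coef$slope * log_dlipw + coef$intercept)) * 1e6
}

#' Sensitivity ratios of anti-angiogenic specificity
#'
#' SR_baseline = predicted baseline LC50 / IC50 and SR_mortality =
#' observed LC50 / IC50.  When no mortality was observed (`lc50_uM` is
#' NA), the maximum tested concentration is substituted, yielding a
#' minimal (lower-bound) ratio flagged `sr_mortality_is_minimal`.
#'
#' @param ic50_uM ISV-inhibition IC50 in µM (> 0, required).
#' @param lc50_uM observed mortality LC50 in µM, or NA if none observed.
#' @param baseline_lc50_uM predicted baseline LC50 in µM.
#' @param max_conc_uM maximum tested concentration in µM.
#' @param thresholds named vector `c(baseline =, mortality =)`.
#' @return an object of class `specificity_result`.
#' @export
compute_sensitivity_ratios <- function(ic50_uM, lc50_uM = NA,
                                       baseline_lc50_uM, max_conc_uM,
                                       thresholds = c(baseline = 10,
                                                      mortality = 4)) {
  if (is.na(ic50_uM) || ic50_uM <= 0)
    stopf("`ic50_uM` is required and must be > 0: no ratio defined")
  if (max_conc_uM <= 0) stopf("`max_conc_uM` must be > 0")
  minimal <- is.na(lc50_uM)
  sr_mort <- if (minimal) max_conc_uM / ic50_uM else lc50_uM / ic50_uM
  res <- structure(list(
    sr_baseline = baseline_lc50_uM / ic50_uM,
    sr_mortality = sr_mort,
    sr_mortality_is_minimal = minimal,
    thresholds = thresholds,
    specific = NA
  ), class = "specificity_result")
  res$specific <- classify_specificity(res)
  res
}

#' Classify specific anti-angiogenic activity
#'
#' Strict threshold comparison: specific when SR_baseline > 10 AND
#' SR_mortality > 4 (boundary values are not specific).
#'
#' @param result a [compute_sensitivity_ratios()] result.
#' @return logical.
#' @export
classify_specificity <- function(result) {
  stopifnot(inherits(result, "specificity_result"))
  th <- result$thresholds
  isTRUE(result$sr_baseline > th[["baseline"]] &&
           result$sr_mortality > th[["mortality"]])
}

#' @export
print.specificity_result <- function(x, ...) {
  cat(sprintf(
    "<specificity_result> SR_baseline = %.4g, SR_mortality = %.4g%s -> %s\n",
    x$sr_baseline, x$sr_mortality,
    if (x$sr_mortality_is_minimal) " (minimal)" else "",
    if (x$specific) "specific" else "not specific"))
  invisible(x)
}

#' Specificity assessment for a compound table
#'
#' Vectorized convenience over [predict_baseline_lc50()] and
#' [compute_sensitivity_ratios()].
#'
#' @param compounds data.frame with columns `name`, `log_dlipw`,
#'   `ic50_uM`, `lc50_uM` (NA when no mortality), `max_conc_uM` and
#'   optionally `window`.
#' @param coef a [qsar_coefficients()] object.
#' @param thresholds named thresholds, see [compute_sensitivity_ratios()].
#' @return the input with columns baseline_lc50_uM, sr_baseline,
#'   sr_mortality, sr_mortality_is_minimal, specific appended.
#' @export
assess_specificity <- function(compounds, coef = qsar_coefficients(),
                               thresholds = c(baseline = 10, mortality = 4)) {
  need <- c("name", "log_dlipw", "ic50_uM", "max_conc_uM")
  if (!all(need %in% names(compounds)))
    stopf("compounds table needs columns: %s", paste(need, collapse = ", "))
  if (is.null(compounds$lc50_uM)) compounds$lc50_uM <- NA_real_
  base <- predict_baseline_lc50(compounds$log_dlipw, coef)
  out <- compounds
  out$baseline_lc50_uM <- base
  res <- lapply(seq_len(nrow(compounds)), function(i)
    compute_sensitivity_ratios(compounds$ic50_uM[i], compounds$lc50_uM[i],
                               base[i], compounds$max_conc_uM[i],
                               thresholds))
  out$sr_baseline <- vapply(res, `[[`, numeric(1), "sr_baseline")
  out$sr_mortality <- vapply(res, `[[`, numeric(1), "sr_mortality")
  out$sr_mortality_is_minimal <-
    vapply(res, `[[`, logical(1), "sr_mortality_is_minimal")
  out$specific <- vapply(res, `[[`, logical(1), "specific")
  out
}
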