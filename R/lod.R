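#' Limit of blank
#'
#' The highest apparent analyte value expected from blank replicates:
#' `LoB = mean_blank + 1.645 * SD_blank`, with the sample (n-1) standard
#' deviation. 1.645 is the one-sided 95% normal quantile, so LoB is the
#' 95th percentile of the blank distribution under normality.
#'
#' @param blank_values Replicate blank measurements or predictions
#'   (mg/mL), n >= 2.
#' @return List with `mean_blank`, `sd_blank`, `lob` and `n_blank`.
#' @examples
#' limit_of_blank(c(-1, 0, 1) / sd(c(-1, 0, 1)))$lob  # 1.645
#' @export
limit_of_blank <- function(blank_values) {
  blank_values <- as.numeric(blank_values)
  if (length(blank_values) < 2L)
    stop_invalid("at least 2 blank replicates are required")
  m <- mean(blank_values)
  s <- stats::sd(blank_values)
  list(mean_blank = m, sd_blank = s, lob = m + 1.645 * s,
       n_blank = length(blank_values))
}

#' Limit of detection
#'
#' `LoD = LoB + 1.645 * SD_low`, where `SD_low` is the sample standard
#' deviation of replicate measurements of a sample known to contain a low
#' analyte concentration.
#'
#' @param lob Limit of blank (mg/mL), e.g. from [limit_of_blank()].
#' @param low_conc_values Replicate low-concentration measurements or
#'   predictions (mg/mL), n >= 2.
#' @return List with `sd_low`, `lod` and `n_low`.
#' @export
limit_of_detection <- function(lob, low_conc_values) {
  low_conc_values <- as.numeric(low_conc_values)
  if (length(low_conc_values) < 2L)
    stop_invalid("at least 2 low-concentration replicates are required")
  s <- stats::sd(low_conc_values)
  list(sd_low = s, lod = lob + 1.645 * s, n_low = length(low_conc_values))
}

#' LoB / LoD from a calibration model
#'
#' Predicts every blank and low-concentration replicate spectrum in the
#' dataset with the model and applies [limit_of_blank()] and
#' [limit_of_detection()] to the predicted concentrations. Negative
#' predictions are retained (clipping would bias the SDs downward).
#'
#' @param model A [build_model()] result.
#' @param dataset An `ir_dataset` containing replicate spectra at both
#'   levels, or a `fused_block` matching the model's axis.
#' @param blank_conc Blank level (default 0 mg/mL).
#' @param low_conc Low level; default: smallest non-blank level present.
#' @return An object of class `lod_result` with `mean_blank`, `sd_blank`,
#'   `sd_low`, `lob`, `lod`, `n_blank`, `n_low` and `source = "predicted"`.
#' @export
lod_from_model <- function(model, dataset, blank_conc = 0, low_conc = NULL) {
  meta <- if (inherits(dataset, "ir_dataset")) dataset$MIR$meta
          else dataset$meta
  conc <- meta$concentration
  if (is.null(low_conc)) {
    cand <- sort(unique(conc[conc > blank_conc]))
    if (length(cand) == 0L)
      stop_invalid("no level above blank_conc present")
    low_conc <- cand[1L]
  }
  if (!any(conc == blank_conc) || !any(conc == low_conc))
    stop_invalid("dataset lacks replicate spectra at the blank or low level")
  pred <- predict(model, dataset)
  b <- limit_of_blank(pred[conc == blank_conc])
  d <- limit_of_detection(b$lob, pred[conc == low_conc])
  structure(c(b, d, list(low_conc = low_conc, source = "predicted")),
            class = "lod_result")
}

#' @export
print.lod_result <- function(x, ...) {
  cat(sprintf(
    "<lod_result> LoB = %.4g, LoD = %.4g mg/mL (%s; n_blank = %d, n_low = %d)\n",
    x$lob, x$lod, x$source, x$n_blank, x$n_low))
  invisible(x)
}
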