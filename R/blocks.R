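#' Spectral data block
#'
#' One instrument's spectra: an intensity matrix (one row per spectrum)
#' on a declared axis, carrying per-row sample, replicate and
#' concentration metadata. MIR and NIR measurements of the same samples
#' are stored as two blocks sharing the metadata sequence.
#'
#' @param modality `"MIR"` or `"NIR"`.
#' @param axis Strictly monotone numeric grid.
#' @param unit `"cm-1"` or `"nm"`.
#' @param intensities Numeric matrix `[n_spectra x length(axis)]`, no NAs.
#' @param meta data.frame with columns `sample_id`, `replicate_id`,
#'   `concentration` (mg/mL), one row per spectrum.
#' @return An object of class `spectral_block`.
#' @export
spectral_block <- function(modality = c("MIR", "NIR"), axis,
                           unit = c("cm-1", "nm"), intensities, meta) {
  modality <- match.arg(modality)
  unit <- match.arg(unit)
  intensities <- as.matrix(intensities)
  if (ncol(intensities) != length(axis))
    stop_invalid("intensity columns must match axis length")
  if (anyNA(intensities)) stop_invalid("intensities contain missing values")
  need <- c("sample_id", "replicate_id", "concentration")
  if (!is.data.frame(meta) || !all(need %in% names(meta)))
    stop_invalid("meta needs columns sample_id, replicate_id, concentration")
  if (nrow(meta) != nrow(intensities))
    stop_invalid("meta rows must match spectra rows")
  structure(list(modality = modality, axis = as.numeric(axis), unit = unit,
                 intensities = intensities,
                 meta = meta[, need, drop = FALSE],
                 preprocessed = FALSE),
            class = "spectral_block")
}

#' @export
print.spectral_block <- function(x, ...) {
  cat(sprintf("<spectral_block> %s: %d spectra x %d points (%g-%g %s)%s\n",
              x$modality, nrow(x$intensities), length(x$axis),
              min(x$axis), max(x$axis), x$unit,
              if (isTRUE(x$preprocessed)) " [preprocessed]" else ""))
  invisible(x)
}

#' @export
dim.spectral_block <- function(x) dim(x$intensities)

# subset a block (and paired dataset) by spectrum rows
block_subset <- function(block, rows) {
  block$intensities <- block$intensities[rows, , drop = FALSE]
  block$meta <- block$meta[rows, , drop = FALSE]
  rownames(block$meta) <- NULL
  block
}

#' Write / read spectra as wide CSV
#'
#' The exchange format mirrors the instrument-software CSV export used for
#' combined-spectra analysis: columns `sample_id`, `replicate_id`,
#' `concentration_mg_per_ml`, then one column per axis point labelled
#' `"<value><unit>"` (e.g. `"2110nm"`, `"1330cm-1"`).
#'
#' @param block A [spectral_block()].
#' @param path File path.
#' @return `read_spectra()` returns a [spectral_block()];
#'   `write_spectra()` returns `path` invisibly.
#' @export
write_spectra <- function(block, path) {
  stopifnot(inherits(block, "spectral_block"))
  df <- data.frame(
    sample_id = block$meta$sample_id,
    replicate_id = block$meta$replicate_id,
    concentration_mg_per_ml = block$meta$concentration,
    block$intensities,
    check.names = FALSE
  )
  names(df)[-(1:3)] <- paste0(format(block$axis, trim = TRUE, digits = 15,
                                     scientific = FALSE), block$unit)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra
#' @param modality Modality label for the block read back.
#' @export
read_spectra <- function(path, modality = c("MIR", "NIR")) {
  modality <- match.arg(modality)
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("sample_id", "replicate_id", "concentration_mg_per_ml")
  if (!all(need %in% names(df)))
    stop_invalid("file lacks the sample_id/replicate_id/concentration header")
  labels <- setdiff(names(df), need)
  unit <- if (all(grepl("cm-1$", labels))) "cm-1"
          else if (all(grepl("nm$", labels))) "nm"
          else stop_invalid("axis column labels must all end in 'nm' or 'cm-1'")
  axis <- as.numeric(sub(paste0(unit, "$"), "", labels))
  spectral_block(
    modality = modality, axis = axis, unit = unit,
    intensities = as.matrix(df[, labels, drop = FALSE]),
    meta = data.frame(sample_id = as.character(df$sample_id),
                      replicate_id = as.character(df$replicate_id),
                      concentration = as.numeric(df$concentration_mg_per_ml),
                      stringsAsFactors = FALSE)
  )
}
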