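#' Preprocessing specification
#'
#' The preprocessing chain applied to every block before modeling:
#' Savitzky-Golay derivative, then standard normal variate (SNV) per
#' spectrum, then (after any fusion) mean-centering with statistics taken
#' from the calibration set only. Defaults reproduce a 2nd-derivative
#' filter of polynomial order 2 with a 15-point smoothing window.
#'
#' @param sg_window Odd filter window length, at least `sg_polyorder + 2`.
#' @param sg_polyorder Polynomial order of the local fit.
#' @param sg_deriv Derivative order (<= `sg_polyorder`).
#' @param apply_snv Apply SNV row scaling after the derivative?
#' @param center `"calibration_mean"` or `"none"`.
#' @return An object of class `preprocess_spec`.
#' @export
preprocess_spec <- function(sg_window = 15L, sg_polyorder = 2L,
                            sg_deriv = 2L, apply_snv = TRUE,
                            center = c("calibration_mean", "none")) {
  center <- match.arg(center)
  sg_window <- as.integer(sg_window)
  sg_polyorder <- as.integer(sg_polyorder)
  sg_deriv <- as.integer(sg_deriv)
  if (sg_window %% 2L == 0L) stop_invalid("sg_window must be odd")
  if (sg_deriv > sg_polyorder)
    stop_invalid("sg_deriv must not exceed sg_polyorder")
  if (sg_window < sg_polyorder + 2L)
    stop_invalid("sg_window must be at least sg_polyorder + 2")
  structure(list(sg_window = sg_window, sg_polyorder = sg_polyorder,
                 sg_deriv = sg_deriv, apply_snv = isTRUE(apply_snv),
                 center = center),
            class = "preprocess_spec")
}

# Savitzky-Golay convolution coefficients for the window midpoint:
# least-squares fit of a degree-`polyorder` polynomial on the window,
# evaluated as the `deriv`-th derivative at the centre, scaled by the
# grid spacing. Exact for polynomials up to `polyorder`.
sg_coefficients <- function(window, polyorder, deriv, h = 1) {
  k <- (window - 1L) %/% 2L
  A <- outer(seq(-k, k), 0:polyorder, `^`)
  # row (deriv+1) of the pseudo-inverse gives the fitted polynomial
  # coefficient a_deriv; d^m/dx^m at 0 is m! * a_m
  pinv <- solve(crossprod(A), t(A))
  pinv[deriv + 1L, ] * factorial(deriv) / h^deriv
}

#' Savitzky-Golay derivative filter
#'
#' Applies the local polynomial least-squares derivative filter row-wise.
#' Interior points get the exact convolution value; the `(window-1)/2`
#' edge points on each side replicate the nearest valid interior value so
#' the matrix width is preserved for fusion bookkeeping.
#'
#' @param x Numeric matrix (spectra in rows) or a single spectrum vector.
#' @param spec A [preprocess_spec()] supplying window/order/derivative.
#' @param h Grid spacing of the axis the rows are sampled on; derivative
#'   output is per `h`-unit (e.g. AU per nm^2 for a 2nd derivative).
#' @return Matrix (or vector) of the same shape.
#' @export
savitzky_golay <- function(x, spec = preprocess_spec(), h = 1) {
  vec <- is.null(dim(x))
  x <- rbind(x)
  n <- ncol(x)
  w <- spec$sg_window
  if (n < w) stop_invalid("spectrum shorter than the filter window")
  k <- (w - 1L) %/% 2L
  coef <- sg_coefficients(w, spec$sg_polyorder, spec$sg_deriv, h)
  # n x n filter matrix: column j holds the window weights for output j
  D <- matrix(0, n, n)
  for (j in (k + 1L):(n - k)) D[(j - k):(j + k), j] <- coef
  for (j in seq_len(k)) D[, j] <- D[, k + 1L]
  for (j in (n - k + 1L):n) D[, j] <- D[, n - k]
  out <- x %*% D
  if (vec) drop(out) else out
}

#' Standard normal variate
#'
#' Centers and scales each spectrum (row) to mean 0 and sample standard
#' deviation 1, removing additive offsets and multiplicative scatter.
#'
#' @param x Numeric matrix (spectra in rows) or vector.
#' @return Same shape; each row has mean 0, sample SD 1.
#' @export
snv <- function(x) {
  vec <- is.null(dim(x))
  x <- rbind(x)
  mu <- rowMeans(x)
  sdv <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1L))
  bad <- which(sdv == 0 | !is.finite(sdv))
  if (length(bad))
    stop_degenerate(sprintf("constant spectrum cannot be SNV-scaled (row %s)",
                            paste(bad, collapse = ", ")))
  out <- (x - mu) / sdv
  if (vec) drop(out) else out
}

#' Mean-center with calibration statistics
#'
#' Computes column means from `train` only and subtracts them from both
#' matrices, so prediction data are always shifted by the calibration
#' means.
#'
#' @param train Calibration matrix.
#' @param apply_to Optional matrix to shift by the same vector.
#' @return List with `train`, `apply_to` (or NULL) and `means`.
#' @export
mean_center <- function(train, apply_to = NULL) {
  train <- as.matrix(train)
  if (!is.null(apply_to)) {
    apply_to <- as.matrix(apply_to)
    if (ncol(apply_to) != ncol(train))
      stop_invalid("column counts of train and apply_to differ")
  }
  mu <- colMeans(train)
  list(train = sweep(train, 2L, mu),
       apply_to = if (!is.null(apply_to)) sweep(apply_to, 2L, mu),
       means = mu)
}

#' Apply the per-block preprocessing chain
#'
#' Savitzky-Golay derivative (on the block's native axis) followed by SNV.
#' The block is flagged as preprocessed and a second application is
#' refused: the chain is not idempotent, and silently derivatizing twice
#' is a classic chemometric bug.
#'
#' @param block A raw [spectral_block()].
#' @param spec A [preprocess_spec()].
#' @return The block with transformed intensities, `preprocessed = TRUE`.
#' @export
preprocess_block <- function(block, spec = preprocess_spec()) {
  stopifnot(inherits(block, "spectral_block"))
  if (isTRUE(block$preprocessed))
    stop_invalid("block is already preprocessed; refusing to re-apply the chain")
  h <- grid_spacing(block$axis)
  x <- savitzky_golay(block$intensities, spec, h)
  if (spec$apply_snv) x <- snv(x)
  block$intensities <- x
  block$preprocessed <- TRUE
  block
}

#' Fuse preprocessed blocks into one feature matrix
#'
#' Low-level data fusion: column-wise concatenation of (optionally
#' masked) blocks in the given order. No resampling onto a common grid is
#' done; a provenance axis records, for every fused column, its modality,
#' native axis value and equivalent wavelength in nm, so fused regression
#' vectors can be reported on a single nanometre axis.
#'
#' @param blocks List of [spectral_block()] objects sharing row metadata
#'   order.
#' @param masks Optional list (same length) of `c(lo, hi)` windows in
#'   each block's native unit; `NULL` entries keep the full axis.
#' @return An object of class `fused_block`: list with the feature matrix
#'   `x`, provenance data.frame `axis` (`modality`, `value`, `unit`,
#'   `nm`), and the shared `meta`.
#' @export
fuse_blocks <- function(blocks, masks = NULL) {
  stopifnot(is.list(blocks), length(blocks) >= 1L,
            all(vapply(blocks, inherits, TRUE, "spectral_block")))
  if (is.null(masks)) masks <- vector("list", length(blocks))
  if (length(masks) != length(blocks))
    stop_invalid("one mask (or NULL) per block required")
  ref <- blocks[[1L]]$meta
  for (b in blocks[-1L]) {
    if (!identical(b$meta$sample_id, ref$sample_id) ||
        !identical(b$meta$replicate_id, ref$replicate_id) ||
        !identical(b$meta$concentration, ref$concentration))
      stop_alignment("blocks do not share row metadata order")
  }
  parts <- vector("list", length(blocks))
  axes <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    keep <- if (is.null(masks[[i]])) rep(TRUE, length(b$axis))
            else b$axis >= min(masks[[i]]) & b$axis <= max(masks[[i]])
    if (!any(keep)) stop_invalid("mask selects no points in a block")
    parts[[i]] <- b$intensities[, keep, drop = FALSE]
    val <- b$axis[keep]
    axes[[i]] <- data.frame(
      modality = b$modality, value = val, unit = b$unit,
      nm = if (b$unit == "cm-1") 1e7 / val else val,
      stringsAsFactors = FALSE)
  }
  structure(list(x = do.call(cbind, parts),
                 axis = do.call(rbind, axes),
                 meta = ref),
            class = "fused_block")
}

#' @export
print.fused_block <- function(x, ...) {
  cat(sprintf("<fused_block> %d spectra x %d features (%s)\n",
              nrow(x$x), ncol(x$x),
              paste(unique(x$axis$modality), collapse = "+")))
  invisible(x)
}
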