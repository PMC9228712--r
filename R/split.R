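#' Kennard-Stone subset selection
#'
#' Deterministic max-min selection: the first two picks are a maximally
#' distant pair (Euclidean distance); each later pick maximizes its
#' minimum distance to everything already selected, so the subset spreads
#' uniformly over the sample space and always includes exterior points.
#' Ties are broken by the lowest row index.
#'
#' @param points Numeric matrix, one candidate per row.
#' @param n_select Number of rows to select (2..nrow).
#' @return Integer vector of selected row indices in selection order.
#' @examples
#' kennard_stone(cbind(0:10), 3)  # picks the extremes, then the middle
#' @export
kennard_stone <- function(points, n_select) {
  points <- as.matrix(points)
  n <- nrow(points)
  n_select <- as.integer(n_select)
  if (is.na(n_select) || n_select < 2L)
    stop_invalid("n_select must be at least 2")
  if (n_select > n)
    stop_invalid("n_select exceeds the number of candidates")

  d <- as.matrix(stats::dist(points))
  # farthest pair, ties resolved toward the smallest (i, j)
  idx <- which(d == max(d), arr.ind = TRUE)
  idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  sel <- c(idx[1L, 1L], idx[1L, 2L])

  mind <- pmin(d[, sel[1L]], d[, sel[2L]])
  while (length(sel) < n_select) {
    mind[sel] <- -Inf
    nxt <- which.max(mind)        # which.max takes the lowest index on ties
    sel <- c(sel, nxt)
    mind <- pmin(mind, d[, nxt])
  }
  as.integer(sel)
}

#' Sample-level calibration/prediction split
#'
#' Runs Kennard-Stone on the per-sample mean rows of a preprocessed
#' (typically fused) feature matrix, so that all replicate spectra of a
#' sample land on the same side of the split and replicate leakage is
#' impossible. Defaults reproduce a 26-sample calibration / 13-sample
#' prediction design (520/260 spectra at 20 spectra per sample).
#'
#' @param fused A [fuse_blocks()] result (or any list with matrix `x` and
#'   `meta` carrying `sample_id`).
#' @param n_calibration Number of calibration samples; default
#'   `round(2/3 * n_samples)`.
#' @return An object of class `split_plan`: `calibration_sample_ids`
#'   (in Kennard-Stone selection order), `prediction_sample_ids`, and the
#'   `distance_metric`.
#' @export
split_dataset <- function(fused, n_calibration = NULL) {
  stopifnot(!is.null(fused$x), !is.null(fused$meta$sample_id))
  ids <- fused$meta$sample_id
  uniq <- unique(ids)
  n_samp <- length(uniq)
  if (is.null(n_calibration)) n_calibration <- round(2 / 3 * n_samp)
  n_calibration <- as.integer(n_calibration)
  if (n_calibration > n_samp)
    stop_invalid("requested calibration size exceeds the sample count")

  means <- t(vapply(uniq, function(s)
    colMeans(fused$x[ids == s, , drop = FALSE]),
    numeric(ncol(fused$x))))
  sel <- kennard_stone(means, n_calibration)
  cal <- uniq[sel]
  pred <- setdiff(uniq, cal)
  if (length(pred) == 0L)
    warning("all samples selected for calibration; prediction set is empty")
  structure(list(calibration_sample_ids = cal,
                 prediction_sample_ids = pred,
                 distance_metric = "euclidean"),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %d calibration / %d prediction samples (%s)\n",
              length(x$calibration_sample_ids),
              length(x$prediction_sample_ids), x$distance_metric))
  invisible(x)
}

#' Serialize / load a split plan
#'
#' Stores the ordered calibration ids and the prediction ids as YAML so
#' an experiment's split is exactly reproducible.
#'
#' @param plan A `split_plan`.
#' @param path File path.
#' @export
write_split_plan <- function(plan, path) {
  stopifnot(inherits(plan, "split_plan"))
  yaml::write_yaml(unclass(plan), path)
  invisible(path)
}

#' @rdname write_split_plan
#' @export
read_split_plan <- function(path) {
  p <- yaml::read_yaml(path)
  structure(list(
    calibration_sample_ids = as.character(p$calibration_sample_ids),
    prediction_sample_ids = as.character(p$prediction_sample_ids),
    distance_metric = p$distance_metric %||% "euclidean"),
    class = "split_plan")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
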