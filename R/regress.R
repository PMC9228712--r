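#' Partial least squares regression (NIPALS)
#'
#' PLS1 fitted by NIPALS deflation on mean-centered data: each component
#' takes the unit-norm weight vector proportional to `X'y` (the direction
#' of maximal covariance with the response), computes scores and
#' loadings, and deflates `X`. With a univariate response the weight
#' update is closed-form, so no iteration is needed; successive score
#' vectors are mutually orthogonal by construction.
#'
#' @param x Mean-centered predictor matrix.
#' @param y Mean-centered response vector.
#' @param ncomp Number of latent variables (<= effective rank of `x`).
#' @return An object of class `lv_fit` with `weights`, `x_loadings`,
#'   `x_scores`, `y_loadings` and per-component regression vectors
#'   available through [regression_vector()].
#' @export
fit_pls <- function(x, y, ncomp) {
  x <- as.matrix(x); y <- as.numeric(y)
  if (nrow(x) != length(y)) stop_invalid("x rows must match length(y)")
  ncomp <- as.integer(ncomp)
  if (ncomp < 1L) stop_invalid("ncomp must be >= 1")
  n <- nrow(x); p <- ncol(x)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp); q <- numeric(ncomp)
  xd <- x
  tol <- 1e-10 * max(sum(x^2), .Machine$double.xmin)
  for (a in seq_len(ncomp)) {
    w <- crossprod(xd, y)
    nw <- sqrt(sum(w^2))
    if (!is.finite(nw) || nw^2 <= .Machine$double.xmin) {
      if (a == 1L) {
        # response orthogonal to all predictors: zero model, by convention
        return(structure(list(method = "pls", ncomp = 0L,
                              weights = W[, 0, drop = FALSE],
                              x_loadings = P[, 0, drop = FALSE],
                              x_scores = Tm[, 0, drop = FALSE],
                              y_loadings = numeric(0), p = p),
                         class = "lv_fit"))
      }
      stop_rank(sprintf("ncomp = %d exceeds the effective rank (%d usable)",
                        ncomp, a - 1L))
    }
    w <- w / nw
    tt <- drop(xd %*% w)
    ss <- sum(tt^2)
    if (ss <= tol)
      stop_rank(sprintf("ncomp = %d exceeds the effective rank (%d usable)",
                        ncomp, a - 1L))
    W[, a] <- w
    Tm[, a] <- tt
    P[, a] <- crossprod(xd, tt) / ss
    q[a] <- sum(y * tt) / ss
    xd <- xd - tcrossprod(tt, P[, a])
  }
  structure(list(method = "pls", ncomp = ncomp, weights = W,
                 x_loadings = P, x_scores = Tm, y_loadings = q, p = p),
            class = "lv_fit")
}

#' Principal component regression
#'
#' Singular value decomposition of the mean-centered predictors followed
#' by least-squares regression of the response on the leading component
#' scores. Unlike PLS the components are chosen to maximize predictor
#' variance only, ignoring the response.
#'
#' @inheritParams fit_pls
#' @param ncomp Number of principal components retained.
#' @return An object of class `lv_fit`.
#' @export
fit_pcr <- function(x, y, ncomp) {
  x <- as.matrix(x); y <- as.numeric(y)
  if (nrow(x) != length(y)) stop_invalid("x rows must match length(y)")
  ncomp <- as.integer(ncomp)
  if (ncomp < 1L) stop_invalid("ncomp must be >= 1")
  sv <- svd(x)
  r <- sum(sv$d > max(dim(x)) * .Machine$double.eps * sv$d[1L])
  if (ncomp > r)
    stop_rank(sprintf("ncomp = %d exceeds the rank of x (%d)", ncomp, r))
  structure(list(method = "pcr", ncomp = ncomp,
                 u = sv$u[, seq_len(ncomp), drop = FALSE],
                 d = sv$d[seq_len(ncomp)],
                 v = sv$v[, seq_len(ncomp), drop = FALSE],
                 uy = drop(crossprod(sv$u[, seq_len(ncomp), drop = FALSE], y)),
                 x_scores = sweep(sv$u[, seq_len(ncomp), drop = FALSE], 2L,
                                  sv$d[seq_len(ncomp)], `*`),
                 x_loadings = sv$v[, seq_len(ncomp), drop = FALSE],
                 p = ncol(x)),
            class = "lv_fit")
}

#' Regression vector of a latent-variable fit
#'
#' Collapses the first `k` components of a PLS or PCR fit into a single
#' regression vector `b` such that `yhat = X b` on centered data. For
#' PLS this is the standard closed form `W (P'W)^-1 q`.
#'
#' @param fit An `lv_fit` from [fit_pls()] or [fit_pcr()].
#' @param k Number of components to use (default: all fitted).
#' @return Numeric vector of length `ncol(x)`.
#' @export
regression_vector <- function(fit, k = fit$ncomp) {
  stopifnot(inherits(fit, "lv_fit"))
  if (k > fit$ncomp) stop_invalid("k exceeds the fitted component count")
  if (k == 0L) return(numeric(fit$p))
  i <- seq_len(k)
  if (fit$method == "pls") {
    W <- fit$weights[, i, drop = FALSE]
    P <- fit$x_loadings[, i, drop = FALSE]
    drop(W %*% solve(crossprod(P, W), fit$y_loadings[i]))
  } else {
    drop(fit$v[, i, drop = FALSE] %*% (fit$uy[i] / fit$d[i]))
  }
}

#' Calibration and prediction error metrics
#'
#' Root mean square error `sqrt(mean((yhat - y)^2))` and coefficient of
#' determination `1 - SS_res/SS_tot`. The same formula serves as RMSEC,
#' RMSECV or RMSEP depending on which pairs are supplied.
#'
#' @param y_true,y_pred Equal-length numeric vectors (n >= 2).
#' @param context Label recorded with the result:
#'   `"calibration"`, `"cv"` or `"prediction"`.
#' @return List with `rmse`, `r2` and `context`.
#' @export
compute_metrics <- function(y_true, y_pred,
                            context = c("calibration", "cv", "prediction")) {
  context <- match.arg(context)
  if (length(y_true) != length(y_pred) || length(y_true) < 2L)
    stop_invalid("y_true and y_pred must be equal length, n >= 2")
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0)
    stop_degenerate("R^2 undefined: y_true has zero variance")
  ss_res <- sum((y_pred - y_true)^2)
  list(rmse = sqrt(ss_res / length(y_true)), r2 = 1 - ss_res / ss_tot,
       context = context)
}

#' Grouped cross-validation error per component count
#'
#' Contiguous venetian-blind cross-validation over *samples*: unique
#' groups, in data order, are dealt into `n_splits` interleaved folds, so
#' all replicate spectra of a sample are always held out together. For
#' each fold the model is refit (including re-centering) without the
#' held-out samples and their responses are predicted with 1..`ncomp`
#' components.
#'
#' @param x Preprocessed (uncentered) feature matrix.
#' @param y Response vector (mg/mL).
#' @param groups Sample id per row; folds are formed from unique ids.
#' @param method `"pls"` or `"pcr"`.
#' @param ncomp Maximum component count to evaluate.
#' @param n_splits Number of interleaved folds (default 10).
#' @return data.frame with columns `ncomp` and `rmsecv`.
#' @export
cross_validate <- function(x, y, groups, method = c("pls", "pcr"),
                           ncomp, n_splits = 10L) {
  method <- match.arg(method)
  x <- as.matrix(x); y <- as.numeric(y)
  ug <- unique(groups)
  n_splits <- min(as.integer(n_splits), length(ug))
  fold_of <- setNames(((seq_along(ug) - 1L) %% n_splits) + 1L, ug)
  folds <- fold_of[as.character(groups)]
  sq_err <- matrix(NA_real_, length(y), ncomp)
  for (f in seq_len(n_splits)) {
    test <- folds == f
    if (stats::var(y[!test]) == 0) {
      warning(sprintf("degenerate fold %d: constant response in training", f))
      next
    }
    cen <- mean_center(x[!test, , drop = FALSE], x[test, , drop = FALSE])
    ym <- mean(y[!test])
    fit <- switch(method,
                  pls = fit_pls(cen$train, y[!test] - ym, ncomp),
                  pcr = fit_pcr(cen$train, y[!test] - ym, ncomp))
    for (k in seq_len(ncomp)) {
      pred <- drop(cen$apply_to %*% regression_vector(fit, k)) + ym
      sq_err[test, k] <- (pred - y[test])^2
    }
  }
  data.frame(ncomp = seq_len(ncomp),
             rmsecv = sqrt(colMeans(sq_err, na.rm = TRUE)))
}

# --- end-to-end calibration over raw blocks -------------------------------

#' Default fusion region masks
#'
#' The NIR block enters in full (1350-2500 nm); the MIR block is masked
#' to the fingerprint-containing 800-1800 cm-1 window (12500-5556 nm),
#' the region carrying the analyte and amide bands.
#'
#' @return Named list of `c(lo, hi)` windows (NULL = full axis).
#' @export
default_masks <- function() list(NIR = NULL, MIR = c(800, 1800))

#' Fit a calibration model on raw spectra
#'
#' Runs the full chain on an [simulate_dataset()]-style dataset:
#' per-block preprocessing ([preprocess_block()]), fusion over the chosen
#' blocks and masks, mean-centering on the calibration samples only, and
#' a PLS or PCR fit. Everything needed to reproduce the chain at
#' prediction time (preprocessing spec, masks, centering vectors,
#' provenance axis) is stored in the returned model.
#'
#' @param dataset An `ir_dataset` (raw blocks).
#' @param cal_ids Calibration sample ids (e.g. from [split_dataset()]).
#' @param method `"pls"` or `"pcr"`.
#' @param ncomp Latent variables / principal components.
#' @param preprocess A [preprocess_spec()].
#' @param blocks Which blocks to use, in fusion order; subset of
#'   `c("NIR", "MIR")`.
#' @param masks Named list of region windows, as [default_masks()].
#' @return An object of class `calibration_model`.
#' @export
build_model <- function(dataset, cal_ids, method = c("pls", "pcr"),
                        ncomp = 10L, preprocess = preprocess_spec(),
                        blocks = c("NIR", "MIR"), masks = default_masks()) {
  stopifnot(inherits(dataset, "ir_dataset"))
  fused <- prepare_features(dataset, preprocess, blocks, masks)
  fit_calibration(fused, cal_ids, method = method, ncomp = ncomp,
                  preprocess = preprocess, blocks = blocks, masks = masks)
}

#' Preprocess and fuse a dataset's blocks
#'
#' @inheritParams build_model
#' @return A [fuse_blocks()] result.
#' @export
prepare_features <- function(dataset, preprocess = preprocess_spec(),
                             blocks = c("NIR", "MIR"),
                             masks = default_masks()) {
  stopifnot(inherits(dataset, "ir_dataset"))
  blocks <- match.arg(blocks, c("NIR", "MIR"), several.ok = TRUE)
  pb <- lapply(dataset[blocks], preprocess_block, spec = preprocess)
  fuse_blocks(unname(pb), masks[blocks])
}

#' Fit a calibration model on an already-fused feature matrix
#'
#' Lower-level companion of [build_model()] for workflows that fuse
#' once and fit several model variants; the preprocessing state must be
#' passed explicitly for the model to accept raw data at prediction time.
#'
#' @param fused A [fuse_blocks()] result (preprocessed features).
#' @inheritParams build_model
#' @export
fit_calibration <- function(fused, cal_ids, method = c("pls", "pcr"),
                            ncomp = 10L, preprocess = NULL,
                            blocks = NULL, masks = NULL) {
  method <- match.arg(method)
  cal <- fused$meta$sample_id %in% cal_ids
  if (!any(cal)) stop_invalid("no calibration rows matched cal_ids")
  xc <- mean_center(fused$x[cal, , drop = FALSE])
  y <- fused$meta$concentration[cal]
  ym <- mean(y)
  fit <- switch(method,
                pls = fit_pls(xc$train, y - ym, ncomp),
                pcr = fit_pcr(xc$train, y - ym, ncomp))
  structure(list(
    method = method, n_components = as.integer(ncomp), fit = fit,
    regression_vector = regression_vector(fit),
    x_means = xc$means, y_mean = ym,
    axis = fused$axis, calibration_sample_ids = cal_ids,
    preprocess = preprocess, blocks = blocks, masks = masks),
    class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> %s, %d components, %d features (%s)\n",
              toupper(x$method), x$n_components, length(x$regression_vector),
              paste(unique(x$axis$modality), collapse = "+")))
  invisible(x)
}

#' Predict concentrations
#'
#' New raw spectra are pushed through the exact preprocessing state
#' stored in the model (same derivative filter, SNV, fusion masks and
#' calibration centering vector); a fused feature matrix is accepted
#' directly after its provenance axis is checked against the model's.
#'
#' @param object A `calibration_model`.
#' @param newdata An `ir_dataset` of raw blocks, or a `fused_block`.
#' @param ... Unused.
#' @return Numeric vector of predicted concentrations (mg/mL), one per
#'   spectrum row.
#' @export
predict.calibration_model <- function(object, newdata, ...) {
  if (inherits(newdata, "ir_dataset")) {
    if (is.null(object$preprocess))
      stop_invalid("model lacks stored preprocessing state; supply a fused_block")
    newdata <- prepare_features(newdata, object$preprocess,
                                object$blocks, object$masks)
  }
  stopifnot(inherits(newdata, "fused_block"))
  if (!isTRUE(all.equal(newdata$axis$value, object$axis$value)) ||
      !identical(newdata$axis$modality, object$axis$modality))
    stop_alignment("provenance axis of newdata does not match the model")
  xc <- sweep(newdata$x, 2L, object$x_means)
  drop(xc %*% object$regression_vector) + object$y_mean
}
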