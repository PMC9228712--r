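test_that("univariate PLS reproduces an exact linear relation", {
  x <- cbind(c(-1, 0, 1))
  y <- c(-2, 0, 2)
  fit <- fit_pls(x, y, 1)
  expect_equal(regression_vector(fit), 2)
  expect_equal(drop(x %*% regression_vector(fit)), y, tolerance = 1e-12)
})

test_that("PLS and PCR at full rank agree with ordinary least squares", {
  for (s in 1:5) {
    set.seed(100 + s)
    x <- scale(matrix(rnorm(10 * 6), 10), scale = FALSE)
    y <- drop(scale(rnorm(10), scale = FALSE))
    ols <- drop(x %*% solve(crossprod(x), crossprod(x, y)))
    for (f in list(fit_pls(x, y, 6), fit_pcr(x, y, 6))) {
      pred <- drop(x %*% regression_vector(f))
      expect_lt(max(abs(pred - ols)), 1e-8)
    }
  }
})

test_that("successive PLS score vectors are orthogonal", {
  set.seed(9)
  x <- scale(matrix(rnorm(30 * 12), 30), scale = FALSE)
  y <- drop(scale(rnorm(30), scale = FALSE))
  fit <- fit_pls(x, y, 5)
  g <- crossprod(fit$x_scores)
  expect_lt(max(abs(g[upper.tri(g)])) / max(diag(g)), 1e-10)
  expect_equal(colSums(fit$weights^2), rep(1, 5), tolerance = 1e-12)
})

test_that("a response orthogonal to the predictors gives a zero regression vector", {
  # columns orthogonal to y by construction
  y <- c(1, -1, 1, -1)
  x <- cbind(c(1, 1, 1, 1), c(2, 2, -1, -1))
  expect_equal(drop(crossprod(x, y)), c(0, 0))
  fit <- fit_pls(x, y, 1)
  expect_equal(regression_vector(fit, fit$ncomp), c(0, 0))
})

test_that("PCR needs more components than PLS when variance and response disagree", {
  set.seed(77)
  n <- 40
  t1 <- rnorm(n) * 10                             # dominant variance direction
  t2 <- stats::resid(stats::lm(rnorm(n) ~ t1))    # orthogonal weak direction
  t2 <- t2 / sd(t2) * 0.1                         # ... carrying the response
  e1 <- c(1, rep(0, 5)); e2 <- c(0, 1, rep(0, 4))
  x <- scale(outer(t1, e1) + outer(t2, e2), scale = FALSE)
  y <- drop(scale(t2, scale = FALSE))
  pcr1 <- compute_metrics(y, drop(x %*% regression_vector(fit_pcr(x, y, 1))),
                          "calibration")
  pls1 <- compute_metrics(y, drop(x %*% regression_vector(fit_pls(x, y, 1))),
                          "calibration")
  expect_lt(pcr1$r2, 0.1)
  expect_gt(pls1$r2, 0.95)
})

test_that("component counts beyond the rank raise rank-deficiency errors", {
  x <- scale(cbind(1:6, (1:6) * 2), scale = FALSE)  # rank 1
  y <- drop(scale(rnorm(6), scale = FALSE))
  expect_error(fit_pls(x, y, 2), class = "irfusion_rank_deficiency")
  expect_error(fit_pcr(x, y, 2), class = "irfusion_rank_deficiency")
})

test_that("prediction honors the stored centering state", {
  ds <- simulate_dataset(simulation_config(n_spectra_per_sample = 2L, seed = 41))
  fused <- prepare_features(ds)
  plan <- split_dataset(fused)
  model <- fit_calibration(fused, plan$calibration_sample_ids, "pls", 8L)
  cal <- fused$meta$sample_id %in% plan$calibration_sample_ids
  # a row equal to the calibration mean spectrum predicts the mean response
  mean_row <- fused
  mean_row$x <- rbind(colMeans(fused$x[cal, ]))
  mean_row$meta <- fused$meta[1, ]
  expect_equal(predict(model, mean_row),
               mean(fused$meta$concentration[cal]), tolerance = 1e-10)
  # axis mismatch is refused
  other <- fuse_blocks(list(preprocess_block(ds$NIR)))
  expect_error(predict(model, other), class = "irfusion_alignment")
})

test_that("prediction is invariant to consistent column permutation", {
  set.seed(55)
  x <- scale(matrix(rnorm(25 * 10), 25), scale = FALSE)
  y <- drop(scale(rnorm(25), scale = FALSE))
  perm <- sample(10)
  for (fitter in list(fit_pls, fit_pcr)) {
    b1 <- regression_vector(fitter(x, y, 4))
    b2 <- regression_vector(fitter(x[, perm], y, 4))
    expect_equal(drop(x %*% b1), drop(x[, perm] %*% b2), tolerance = 1e-9)
  }
})

test_that("noiseless spectra are recovered exactly at full rank", {
  ds <- noiseless_dataset(seed = 3, scatter = 0.01)
  pp <- preprocess_spec(apply_snv = FALSE)  # keep the chain exactly linear
  fused <- prepare_features(ds, pp)
  plan <- split_dataset(fused)
  model <- fit_calibration(fused, plan$calibration_sample_ids, "pls", 3L,
                           preprocess = pp)
  expect_lt(max(abs(predict(model, fused) - fused$meta$concentration)), 1e-6)
  # with every noise term off the data are rank one and one LV is exact
  ds0 <- noiseless_dataset(seed = 3)
  f0 <- prepare_features(ds0, preprocess_spec(apply_snv = FALSE))
  plan0 <- split_dataset(f0)
  m0 <- fit_calibration(f0, plan0$calibration_sample_ids, "pls", 1L)
  expect_lt(max(abs(predict(m0, f0) - f0$meta$concentration)), 1e-8)
})

test_that("cross-validation matches a hand-rolled two-fold computation", {
  set.seed(13)
  x <- matrix(rnorm(8 * 3), 8)
  y <- rnorm(8)
  groups <- rep(c("a", "b", "c", "d"), each = 2L)
  got <- cross_validate(x, y, groups, "pls", 2L, n_splits = 2L)
  # manual: fold 1 = {a, c}, fold 2 = {b, d} (interleaved by group order)
  sq <- matrix(NA_real_, 8, 2)
  for (test_g in list(c("a", "c"), c("b", "d"))) {
    te <- groups %in% test_g
    mu <- colMeans(x[!te, ]); ym <- mean(y[!te])
    xt <- sweep(x[!te, ], 2, mu)
    fit <- fit_pls(xt, y[!te] - ym, 2L)
    for (k in 1:2) {
      p <- drop(sweep(x[te, ], 2, mu) %*% regression_vector(fit, k)) + ym
      sq[te, k] <- (p - y[te])^2
    }
  }
  expect_equal(got$rmsecv, sqrt(colMeans(sq)), tolerance = 1e-12)
})

test_that("cross-validation is near zero on noiseless linear data and warns on degenerate folds", {
  ds <- noiseless_dataset(seed = 19, scatter = 0.01)
  fused <- prepare_features(ds, preprocess_spec(apply_snv = FALSE))
  cv <- cross_validate(fused$x, fused$meta$concentration,
                       fused$meta$sample_id, "pls", 3L)
  expect_lt(cv$rmsecv[3], 1e-6)
  # fold holding out {a, c} trains on the constant-response group b only
  expect_warning(
    cross_validate(matrix(rnorm(18), 6), c(1, 1, 2, 2, 3, 3),
                   rep(c("a", "b", "c"), each = 2), "pls", 1L, n_splits = 2L),
    "degenerate fold")
})

test_that("RMSECV falls steeply with early components and levels off past the optimum", {
  curves <- sapply(1:4, function(s) {
    ds <- simulate_dataset(simulation_config(seed = s))
    fused <- prepare_features(ds)
    plan <- split_dataset(fused)
    cal <- fused$meta$sample_id %in% plan$calibration_sample_ids
    cross_validate(fused$x[cal, ], fused$meta$concentration[cal],
                   fused$meta$sample_id[cal], "pls", 12L)$rmsecv
  })
  med <- apply(curves, 1, median)
  k_opt <- which.min(med)
  expect_gte(k_opt, 4L)                    # underfitting hurts
  expect_lt(med[k_opt], 0.5 * med[1])      # large early gains
  expect_gte(med[12], med[k_opt])          # no gain beyond the optimum
})

test_that("error metrics match their definitions", {
  expect_equal(compute_metrics(c(1, 2, 3), c(1, 2, 3), "prediction"),
               list(rmse = 0, r2 = 1, context = "prediction"))
  m <- compute_metrics(c(0, 2), c(1, 1), "prediction")
  expect_equal(m$rmse, 1)
  expect_equal(m$r2, 0)
  set.seed(2)
  y <- rnorm(50); p <- y + rnorm(50, sd = 0.3)
  m2 <- compute_metrics(y, p, "cv")
  expect_equal(m2$rmse, sqrt(mean((p - y)^2)))
  expect_equal(m2$r2, 1 - sum((p - y)^2) / sum((y - mean(y))^2))
  expect_error(compute_metrics(c(1, 1), c(1, 2), "cv"),
               class = "irfusion_degenerate")
  expect_error(compute_metrics(1, 1), class = "irfusion_invalid_input")
})

test_that("fused regression vector peaks at the analyte's MIR bands", {
  ds <- noiseless_dataset(seed = 5)
  fused <- prepare_features(ds)
  plan <- split_dataset(fused)
  model <- fit_calibration(fused, plan$calibration_sample_ids, "pls", 4L)
  b <- abs(model$regression_vector)
  mir <- which(model$axis$modality == "MIR")
  step <- 4
  top <- model$axis$value[mir[which.max(b[mir])]]
  expect_lte(abs(top - 1330), step)
  # the CH2 rocking region near 906 also carries strong coefficients
  strong <- model$axis$value[mir[order(b[mir], decreasing = TRUE)[1:6]]]
  expect_true(any(abs(strong - 906) <= step))
})
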