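test_that("Savitzky-Golay 2nd derivative is exact on polynomials", {
  sp <- preprocess_spec()  # window 15, order 2, deriv 2
  x <- (1:60)^2
  out <- savitzky_golay(x, sp, h = 1)
  expect_equal(out, rep(2, 60), tolerance = 1e-9)
  lin <- 3 * (1:60) + 7
  expect_equal(savitzky_golay(lin, sp, h = 1), rep(0, 60), tolerance = 1e-9)
  # spacing scaling: f(x) = x^2 sampled at h = 0.5 still has f'' = 2
  xs <- (seq(0, 30, by = 0.5))^2
  expect_equal(savitzky_golay(xs, sp, h = 0.5), rep(2, 61), tolerance = 1e-8)
})

test_that("Savitzky-Golay matches a per-window least-squares oracle", {
  set.seed(14)
  x <- cumsum(rnorm(80))
  sp <- preprocess_spec(sg_window = 11L)
  expect_equal(savitzky_golay(x, sp, h = 2), sg_window_lm(x, 11L, 2L, 2L, 2),
               tolerance = 1e-8)
  # first derivative of a cubic fit, same oracle
  sp1 <- preprocess_spec(sg_window = 9L, sg_polyorder = 3L, sg_deriv = 1L)
  expect_equal(savitzky_golay(x, sp1, h = 1), sg_window_lm(x, 9L, 3L, 1L, 1),
               tolerance = 1e-8)
})

test_that("Savitzky-Golay approximates the analytic second derivative of sin", {
  g <- seq(0, 2 * pi, length.out = 400)
  h <- g[2] - g[1]
  out <- savitzky_golay(sin(g), preprocess_spec(), h = h)
  interior <- 8:393
  # attenuation bound from the filter's response to this frequency,
  # computed by applying the filter to the pure tone analytically known
  tol <- max(abs(sg_window_lm(sin(g), 15L, 2L, 2L, h)[interior] + sin(g)[interior]))
  expect_lt(max(abs(out[interior] + sin(g)[interior])), tol + 1e-10)
  expect_lt(tol, 0.05)
})

test_that("Savitzky-Golay is exactly linear and validates its window", {
  set.seed(3)
  a <- matrix(rnorm(3 * 40), 3)
  b <- matrix(rnorm(3 * 40), 3)
  sp <- preprocess_spec()
  expect_equal(savitzky_golay(2 * a - 5 * b, sp),
               2 * savitzky_golay(a, sp) - 5 * savitzky_golay(b, sp),
               tolerance = 1e-12)
  expect_error(savitzky_golay(rnorm(10), sp), class = "irfusion_invalid_input")
  expect_error(preprocess_spec(sg_window = 14L), class = "irfusion_invalid_input")
  expect_error(preprocess_spec(sg_deriv = 3L, sg_polyorder = 2L),
               class = "irfusion_invalid_input")
})

test_that("SNV standardizes every row and flags constant rows", {
  expect_equal(snv(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(5)
  x <- matrix(rnorm(20 * 50, sd = runif(20, 0.1, 10)), 20)
  out <- snv(x)
  expect_equal(rowMeans(out), rep(0, 20), tolerance = 1e-12)
  expect_equal(apply(out, 1, sd), rep(1, 20), tolerance = 1e-12)
  # invariance to per-row affine transforms
  expect_equal(snv(5 * x[3, ] + 2), out[3, ], tolerance = 1e-12)
  err <- tryCatch(snv(rbind(x[1, ], rep(7, 50))), error = identity)
  expect_s3_class(err, "irfusion_degenerate")
  expect_match(conditionMessage(err), "row 2")
})

test_that("mean centering uses calibration statistics only", {
  set.seed(6)
  tr <- matrix(rnorm(30), 6)
  te <- matrix(rnorm(15), 3)
  cen <- mean_center(tr, te)
  expect_equal(colMeans(cen$train), rep(0, 5), tolerance = 1e-14)
  expect_equal(cen$apply_to, sweep(te, 2, colMeans(tr)))
  # identical training rows: centered train all zero, test shifted by the row
  r <- rnorm(4)
  cen2 <- mean_center(matrix(r, 3, 4, byrow = TRUE), matrix(rnorm(4), 1))
  expect_equal(cen2$train, matrix(0, 3, 4), ignore_attr = TRUE)
  expect_error(mean_center(tr, matrix(0, 2, 4)),
               class = "irfusion_invalid_input")
})

test_that("wavenumber-to-wavelength conversion matches the region labels", {
  expect_equal(to_wavelength(4000), 2500)
  expect_equal(to_wavelength(800), 12500)
  expect_equal(round(to_wavelength(1800), 1), 5555.6)
  out <- to_wavelength(seq(4000, 800, by = -4))
  expect_true(all(diff(out) > 0))
  expect_error(to_wavelength(c(100, -5)), class = "irfusion_invalid_input")
})

test_that("fusion concatenates masked blocks with provenance and guards", {
  ds <- simulate_dataset(simulation_config(n_spectra_per_sample = 2L, seed = 4))
  pp <- preprocess_spec()
  nir <- preprocess_block(ds$NIR, pp)
  mir <- preprocess_block(ds$MIR, pp)
  fused <- fuse_blocks(list(nir, mir), list(NULL, c(800, 1800)))
  m <- sum(ds$MIR$axis >= 800 & ds$MIR$axis <= 1800)
  expect_equal(ncol(fused$x), 141L + m)
  expect_equal(nrow(fused$x), nrow(ds$NIR$intensities))
  expect_identical(fused$meta, ds$NIR$meta)
  expect_equal(fused$axis$nm[fused$axis$modality == "MIR"],
               1e7 / fused$axis$value[fused$axis$modality == "MIR"])
  # single block, full mask = identity
  solo <- fuse_blocks(list(nir))
  expect_equal(solo$x, nir$intensities)
  # misaligned metadata
  bad <- mir
  bad$meta$sample_id <- rev(bad$meta$sample_id)
  expect_error(fuse_blocks(list(nir, bad)), class = "irfusion_alignment")
  expect_error(fuse_blocks(list(nir, mir), list(NULL, c(5000, 6000))),
               class = "irfusion_invalid_input")
})

test_that("swapping fusion block order leaves model error metrics unchanged", {
  ds <- simulate_dataset(simulation_config(n_spectra_per_sample = 2L, seed = 12))
  pp <- preprocess_spec()
  nir <- preprocess_block(ds$NIR, pp)
  mir <- preprocess_block(ds$MIR, pp)
  rmsec_of <- function(fused) {
    plan <- split_dataset(fused)
    m <- fit_calibration(fused, plan$calibration_sample_ids, "pls", 6L)
    cal <- fused$meta$sample_id %in% plan$calibration_sample_ids
    compute_metrics(fused$meta$concentration[cal],
                    predict(m, fused_subset_for_test(fused, cal)),
                    "calibration")$rmse
  }
  f1 <- fuse_blocks(list(nir, mir), list(NULL, c(800, 1800)))
  f2 <- fuse_blocks(list(mir, nir), list(c(800, 1800), NULL))
  expect_equal(rmsec_of(f1), rmsec_of(f2), tolerance = 1e-8)
})

test_that("the preprocessing chain refuses re-application", {
  ds <- simulate_dataset(simulation_config(n_spectra_per_sample = 1L, seed = 1))
  b <- preprocess_block(ds$NIR)
  expect_true(b$preprocessed)
  expect_error(preprocess_block(b), class = "irfusion_invalid_input")
})
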