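# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# Kennard-Stone by literal max-min search over all candidates.
ks_bruteforce <- function(points, n_select) {
  points <- as.matrix(points)
  n <- nrow(points)
  dfun <- function(i, j) sqrt(sum((points[i, ] - points[j, ])^2))
  best <- c(-1, 1L, 2L)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- dfun(i, j)
    if (d > best[1L]) best <- c(d, i, j)
  }
  sel <- as.integer(best[2:3])
  while (length(sel) < n_select) {
    cand <- setdiff(seq_len(n), sel)
    score <- vapply(cand, function(i)
      min(vapply(sel, function(j) dfun(i, j), numeric(1))), numeric(1))
    sel <- c(sel, cand[which.max(score)])
  }
  sel
}

# Savitzky-Golay by explicit per-window polynomial least squares (lm).
sg_window_lm <- function(x, window, polyorder, deriv, h = 1) {
  n <- length(x)
  k <- (window - 1L) %/% 2L
  out <- rep(NA_real_, n)
  for (i in (k + 1L):(n - k)) {
    idx <- (i - k):(i + k)
    t <- (idx - i) * h
    fit <- stats::lm(x[idx] ~ stats::poly(t, polyorder, raw = TRUE))
    out[i] <- stats::coef(fit)[deriv + 1L] * factorial(deriv)
  }
  out[seq_len(k)] <- out[k + 1L]
  out[(n - k + 1L):n] <- out[n - k]
  out
}

# count strict local maxima of a vector (interior points only)
count_local_maxima <- function(v) {
  sum(v[2:(length(v) - 1L)] > v[1:(length(v) - 2L)] &
        v[2:(length(v) - 1L)] > v[3:length(v)])
}

# row-subset of a fused feature block (tests only)
fused_subset_for_test <- function(fused, rows) {
  fused$x <- fused$x[rows, , drop = FALSE]
  fused$meta <- fused$meta[rows, , drop = FALSE]
  fused
}

# small noiseless dataset shared by several tests (scatter-only keeps the
# preprocessed features exactly linear in concentration at full rank)
noiseless_dataset <- function(seed = 3, scatter = 0) {
  simulate_dataset(simulation_config(
    noise_sd = 0, baseline_amplitude = 0, replicate_effect_sd = 0,
    scatter_sd = scatter, n_spectra_per_sample = 2L, seed = seed))
}
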