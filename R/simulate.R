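#' Simulation configuration
#'
#' Describes the spiking study design the simulator reproduces: a
#' 13-level glycine concentration series (0-50 mg/mL) spiked into each of
#' 3 biological serum replicates (39 samples), with 20 replicate spectra
#' recorded per sample on each instrument.
#'
#' Noise defaults are stated in absorbance units (AU): `noise_sd` is the
#' iid per-point detector noise, `baseline_amplitude` bounds a random
#' quadratic baseline per spectrum, `scatter_sd` is the relative SD of a
#' multiplicative scatter factor on the matrix contribution, and
#' `replicate_effect_sd` is the SD of a constant absorbance offset shared
#' by all spectra of one biological replicate.
#'
#' @param concentration_series Analyte spike levels in mg/mL (all >= 0).
#' @param n_biological_replicates Number of serum donors.
#' @param n_spectra_per_sample Replicate spectra per sample per instrument.
#' @param noise_sd Additive iid noise SD (AU).
#' @param baseline_amplitude Bound on the random baseline magnitude (AU).
#' @param scatter_sd Relative SD of the multiplicative scatter factor.
#' @param replicate_effect_sd SD of the per-replicate offset (AU).
#' @param seed Integer RNG seed; identical configs give bit-identical data.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(
    concentration_series = c(0, 0.01, 0.05, 0.1, 0.5, 1, 2.5, 5,
                             7.5, 10, 17.5, 25, 50),
    n_biological_replicates = 3L,
    n_spectra_per_sample = 20L,
    noise_sd = 0.002,
    baseline_amplitude = 0.01,
    scatter_sd = 0.01,
    replicate_effect_sd = 0.005,
    seed = 1L) {
  if (length(concentration_series) == 0L ||
      any(!is.finite(concentration_series)) ||
      any(concentration_series < 0))
    stop_invalid("concentration_series must be non-empty and all >= 0")
  if (n_biological_replicates < 1L || n_spectra_per_sample < 1L)
    stop_invalid("replicate and spectra counts must be positive")
  if (noise_sd < 0 || baseline_amplitude < 0 || scatter_sd < 0 ||
      replicate_effect_sd < 0)
    stop_invalid("noise parameters must be >= 0")
  structure(list(
    concentration_series = as.numeric(concentration_series),
    n_biological_replicates = as.integer(n_biological_replicates),
    n_spectra_per_sample = as.integer(n_spectra_per_sample),
    noise_sd = noise_sd, baseline_amplitude = baseline_amplitude,
    scatter_sd = scatter_sd, replicate_effect_sd = replicate_effect_sd,
    seed = as.integer(seed)),
    class = "simulation_config")
}

#' Simulate a paired MIR + NIR spiking dataset
#'
#' Generates both instrument blocks for the spiking design in
#' [simulation_config()]. Each spectrum follows an additive Beer-Lambert
#' model:
#'
#' `A = matrix * (1 + scatter) + conc * response * analyte
#'      + baseline + replicate_offset + noise`
#'
#' where `matrix` and `analyte` are the component spectra of the two band
#' libraries, `scatter` is a per-spectrum multiplicative factor,
#' `baseline` is a random quadratic per spectrum, and `noise` is iid
#' Gaussian per point. Absorbance is clipped at zero from below. The two
#' blocks share the sample/replicate/concentration metadata sequence but
#' have independent noise realizations.
#'
#' @param config A [simulation_config()].
#' @param analyte,matrix [component_library()] objects for the spiked
#'   analyte and the background matrix; defaults [glycine_library()] and
#'   [serum_library()].
#' @param nir,mir [axis_spec()] grids; defaults [nir_axis()], [mir_axis()].
#' @return An object of class `ir_dataset`: a list with elements `MIR`
#'   and `NIR` (both [spectral_block()]) and the `config` used.
#' @examples
#' ds <- simulate_dataset(simulation_config(n_spectra_per_sample = 2))
#' ds$MIR
#' @export
simulate_dataset <- function(config = simulation_config(),
                             analyte = glycine_library(),
                             matrix = serum_library(),
                             nir = nir_axis(), mir = mir_axis()) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(analyte, "component_library"),
            inherits(matrix, "component_library"))
  if (analyte$response_per_unit_conc <= 0)
    stop_invalid("analyte response_per_unit_conc must be > 0")

  series <- config$concentration_series
  n_rep <- config$n_biological_replicates
  n_per <- config$n_spectra_per_sample
  n_samples <- length(series) * n_rep

  sample_tab <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n_samples)),
    replicate_id = rep(sprintf("R%d", seq_len(n_rep)), each = length(series)),
    concentration = rep(series, times = n_rep),
    stringsAsFactors = FALSE
  )
  meta <- sample_tab[rep(seq_len(n_samples), each = n_per), ]
  rownames(meta) <- NULL
  rep_index <- rep(rep(seq_len(n_rep), each = length(series)), each = n_per)
  conc <- meta$concentration
  n_rows <- nrow(meta)

  simulate_block <- function(modality, axis_sp, unit) {
    grid <- realize_axis(axis_sp)
    p <- length(grid)
    m_spec <- component_spectrum(matrix, modality, grid)
    a_spec <- component_spectrum(analyte, modality, grid) *
      analyte$response_per_unit_conc

    rep_off <- stats::rnorm(n_rep) * config$replicate_effect_sd
    scatter <- stats::rnorm(n_rows) * config$scatter_sd
    bl_coef <- matrix(stats::runif(n_rows * 3, -1, 1), n_rows, 3)
    bl_amp <- stats::runif(n_rows) * config$baseline_amplitude
    noise <- matrix(stats::rnorm(n_rows * p), n_rows, p) * config$noise_sd

    t01 <- (grid - grid[1]) / (grid[p] - grid[1])
    bl_raw <- bl_coef %*% rbind(1, t01, t01^2)
    bl <- bl_raw / pmax(apply(abs(bl_raw), 1, max), .Machine$double.eps) *
      bl_amp

    x <- (1 + scatter) %o% m_spec + conc %o% a_spec + bl +
      rep_off[rep_index] + noise
    x <- pmax(x, 0)
    spectral_block(modality, grid, unit, x, meta)
  }

  with_seed(config$seed, {
    blk_mir <- simulate_block("MIR", mir, "cm-1")
    blk_nir <- simulate_block("NIR", nir, "nm")
    structure(list(MIR = blk_mir, NIR = blk_nir, config = config),
              class = "ir_dataset")
  })
}

#' @export
print.ir_dataset <- function(x, ...) {
  cat(sprintf("<ir_dataset> %d samples, %d spectra per block\n",
              length(unique(x$MIR$meta$sample_id)), nrow(x$MIR$intensities)))
  print(x$MIR); print(x$NIR)
  invisible(x)
}

#' Remove one concentration level from a dataset
#'
#' Drops every sample at the given spike level from both blocks, the
#' operation used to probe model robustness against the lowest-level
#' "blind" sample set.
#'
#' @param dataset An `ir_dataset`.
#' @param level Concentration (mg/mL) to remove; must be present.
#' @param protect_blank Refuse to remove the 0 mg/mL blanks (they are
#'   required for limit-of-blank estimation) unless set to `FALSE`.
#' @return The dataset without that level.
#' @export
exclude_level <- function(dataset, level, protect_blank = TRUE) {
  stopifnot(inherits(dataset, "ir_dataset"))
  conc <- dataset$MIR$meta$concentration
  if (!any(conc == level))
    stop_invalid(sprintf("level %g mg/mL not present in the dataset", level))
  if (protect_blank && level == 0)
    stop_invalid("refusing to remove the blank level: LoB needs blanks")
  keep <- conc != level
  dataset$MIR <- block_subset(dataset$MIR, keep)
  dataset$NIR <- block_subset(dataset$NIR, keep)
  dataset
}

#' Serialize / load a simulation configuration
#'
#' Round-trips a [simulation_config()] through a human-editable YAML file
#' so a simulated dataset is reproducible from its config alone.
#'
#' @param config A [simulation_config()].
#' @param path YAML file path.
#' @export
write_simulation_config <- function(config, path) {
  stopifnot(inherits(config, "simulation_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_simulation_config
#' @export
read_simulation_config <- function(path) {
  do.call(simulation_config, yaml::read_yaml(path))
}
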