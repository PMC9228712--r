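#' Model-variant definitions
#'
#' A variant is one row of the comparison design: which blocks enter the
#' model, the regression method, the component count, and whether the
#' lowest-concentration "blind" sample set is included. The defaults
#' reproduce the four canonical comparisons: NIR-only PLS (8 LVs),
#' ATR(MIR)-only PLS (10 LVs), fused NIR+MIR PLS (10 LVs) and fused
#' NIR+MIR PCR (10 PCs).
#'
#' @param label Human-readable variant name.
#' @param method `"pls"` or `"pcr"`.
#' @param blocks Blocks used, subset of `c("NIR", "MIR")`.
#' @param ncomp Latent variables / principal components.
#' @param include_blind Keep the lowest non-zero level in the data?
#' @return A list of class `model_variant`.
#' @export
model_variant <- function(label, method = c("pls", "pcr"),
                          blocks = c("NIR", "MIR"), ncomp = 10L,
                          include_blind = TRUE) {
  method <- match.arg(method)
  blocks <- match.arg(blocks, c("NIR", "MIR"), several.ok = TRUE)
  structure(list(label = label, method = method, blocks = blocks,
                 ncomp = as.integer(ncomp),
                 include_blind = isTRUE(include_blind)),
            class = "model_variant")
}

#' @rdname model_variant
#' @export
default_variants <- function() {
  list(
    model_variant("NIR-PLS", "pls", "NIR", 8L),
    model_variant("ATR-PLS", "pls", "MIR", 10L),
    model_variant("Fused-PLS", "pls", c("NIR", "MIR"), 10L),
    model_variant("Fused-PCR", "pcr", c("NIR", "MIR"), 10L)
  )
}

#' Experiment configuration
#'
#' Bundles everything one run needs: the simulation settings (or paths
#' to measured CSV spectra), the preprocessing spec, the model variants,
#' the calibration fraction and the seeds.
#'
#' @param simulation A [simulation_config()], or a named list
#'   `list(MIR = path, NIR = path)` of wide-CSV spectra files.
#' @param preprocess A [preprocess_spec()].
#' @param variants List of [model_variant()] objects.
#' @param masks Fusion region masks, as [default_masks()].
#' @param n_calibration Calibration samples for the Kennard-Stone split;
#'   default 2/3 of the available samples.
#' @param seeds Integer vector; the whole pipeline is rerun per seed.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(simulation = simulation_config(),
                              preprocess = preprocess_spec(),
                              variants = default_variants(),
                              masks = default_masks(),
                              n_calibration = NULL,
                              seeds = 1L) {
  if (length(variants) == 0L)
    stop_invalid("at least one model variant is required")
  structure(list(simulation = simulation, preprocess = preprocess,
                 variants = variants, masks = masks,
                 n_calibration = n_calibration,
                 seeds = as.integer(seeds)),
            class = "experiment_config")
}

# row-subset of a fused feature matrix, keeping the provenance axis
fused_subset <- function(fused, rows) {
  fused$x <- fused$x[rows, , drop = FALSE]
  fused$meta <- fused$meta[rows, , drop = FALSE]
  rownames(fused$meta) <- NULL
  fused
}

region_label <- function(axis) {
  lab <- vapply(split(axis$nm, axis$modality), function(nm)
    sprintf("%.0f-%.0f nm", max(nm), min(nm)), character(1))
  paste(lab[order(names(lab), decreasing = TRUE)], collapse = " + ")
}

#' Run the full comparison experiment
#'
#' For every seed: simulate (or load) the paired dataset, preprocess each
#' block once, and for every variant fuse the requested blocks, perform
#' the sample-level Kennard-Stone split, fit, and collect RMSEC, RMSECV
#' (grouped venetian-blind CV at the variant's component count), RMSEP
#' and prediction R^2, plus LoB/LoD from the model's predictions of the
#' blank and lowest-level replicates. Variants with
#' `include_blind = FALSE` drop the lowest non-zero level before the
#' split; their calibration size is scaled to keep the same fraction.
#' Everything downstream of the simulator is deterministic, so a given
#' seed always yields an identical report.
#'
#' @param config An [experiment_config()].
#' @return data.frame, one row per variant x seed, with the metric and
#'   LoD columns described above.
#' @export
run_experiment <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  rows <- list()
  for (seed in config$seeds) {
    dataset <- load_or_simulate(config$simulation, seed)
    pb <- list(NIR = preprocess_block(dataset$NIR, config$preprocess),
               MIR = preprocess_block(dataset$MIR, config$preprocess))
    conc_all <- dataset$MIR$meta$concentration
    blind_level <- suppressWarnings(min(conc_all[conc_all > 0]))
    for (v in config$variants) {
      fused <- fuse_blocks(unname(pb[v$blocks]), config$masks[v$blocks])
      if (!v$include_blind)
        fused <- fused_subset(fused, fused$meta$concentration != blind_level)
      n_samp <- length(unique(fused$meta$sample_id))
      n_cal <- config$n_calibration %||% round(2 / 3 * n_samp)
      if (!v$include_blind && !is.null(config$n_calibration))
        n_cal <- round(config$n_calibration / 39 * n_samp)
      plan <- split_dataset(fused, n_cal)
      model <- fit_calibration(fused, plan$calibration_sample_ids,
                               method = v$method, ncomp = v$ncomp,
                               preprocess = config$preprocess,
                               blocks = v$blocks, masks = config$masks)
      cal <- fused$meta$sample_id %in% plan$calibration_sample_ids
      y <- fused$meta$concentration
      cal_fit <- compute_metrics(y[cal],
                                 predict(model, fused_subset(fused, cal)),
                                 "calibration")
      cv <- cross_validate(fused$x[cal, , drop = FALSE], y[cal],
                           fused$meta$sample_id[cal], v$method, v$ncomp)
      pred_fit <- compute_metrics(y[!cal],
                                  predict(model, fused_subset(fused, !cal)),
                                  "prediction")
      lod <- lod_from_model(model, fused)
      rows[[length(rows) + 1L]] <- data.frame(
        seed = seed, variant = v$label, method = toupper(v$method),
        region = region_label(model$axis), n_components = v$ncomp,
        include_blind = v$include_blind,
        n_cal_samples = length(plan$calibration_sample_ids),
        n_pred_samples = length(plan$prediction_sample_ids),
        rmsec = cal_fit$rmse,
        rmsecv = cv$rmsecv[v$ncomp],
        rmsep = pred_fit$rmse, r2_pred = pred_fit$r2,
        mean_blank = lod$mean_blank, sd_blank = lod$sd_blank,
        sd_low = lod$sd_low, lob = lod$lob, lod = lod$lod,
        low_conc = lod$low_conc,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

load_or_simulate <- function(simulation, seed) {
  if (inherits(simulation, "simulation_config")) {
    simulation$seed <- as.integer(seed)
    simulate_dataset(simulation)
  } else if (is.list(simulation) &&
             all(c("MIR", "NIR") %in% names(simulation))) {
    structure(list(MIR = read_spectra(simulation$MIR, "MIR"),
                   NIR = read_spectra(simulation$NIR, "NIR"),
                   config = NULL),
              class = "ir_dataset")
  } else {
    stop_invalid("simulation must be a simulation_config or MIR/NIR file paths")
  }
}

#' Write an experiment report
#'
#' Saves the tidy report table as CSV plus a YAML run manifest (seeds,
#' preprocessing, variants, package version) alongside it.
#'
#' @param report data.frame from [run_experiment()].
#' @param config The [experiment_config()] that produced it.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report, file.path(dir, "report.csv"), row.names = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("irfusion")),
    seeds = config$seeds,
    preprocess = unclass(config$preprocess),
    masks = config$masks,
    variants = lapply(config$variants, unclass),
    simulation = if (inherits(config$simulation, "simulation_config"))
      unclass(config$simulation) else config$simulation)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
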