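# irfusion

Chemometric calibration pipeline for quantifying a low-molecular-weight
analyte (glycine, as a model compound) spiked into a serum matrix from
paired **mid-infrared** (ATR-FTIR, 4000–800 cm⁻¹) and **near-infrared**
(2500–1350 nm) absorbance spectra, and for asking whether **low-level
data fusion** — concatenating both preprocessed blocks into one
calibration — lowers the prediction error and the detection limit
compared with either instrument alone.

The package is aimed at spectroscopists and chemometricians who want a
tested, scriptable version of this workflow:

1. **Simulation** (`simulate_dataset()`): paired MIR+NIR datasets with the
   spiking-study structure — a 13-level concentration series (0–50 mg/mL)
   × 3 biological replicates (39 samples), 20 replicate spectra per
   sample per instrument — built from Gaussian/Lorentzian band models
   (glycine fingerprint bands at 906/1036/1111/1330/1414 cm⁻¹ and
   2110/2204/2375 nm on a serum-like background), with baseline,
   multiplicative scatter, replicate offsets and detector noise.
2. **Preprocessing** (`preprocess_block()`): Savitzky–Golay 2nd
   derivative (window 15, polynomial order 2) → standard normal variate
   per spectrum; fusion (`fuse_blocks()`) concatenates masked blocks with
   a provenance axis; mean-centering always uses calibration statistics.
3. **Splitting** (`split_dataset()`): Kennard–Stone max–min selection on
   per-sample mean spectra (26 calibration / 13 prediction samples by
   default; 520/260 spectra), so replicate spectra never leak across the
   split.
4. **Regression** (`build_model()`, `fit_pls()`, `fit_pcr()`):
   from-scratch PLS1 (NIPALS) and PCR with grouped venetian-blind
   cross-validation and the RMSEC/RMSECV/RMSEP/R² metric set. The PLS
   regression vector is `b = W (PᵀW)⁻¹ q`; predictions are
   `ŷ = (x − x̄_cal)ᵀ b + ȳ_cal`.
5. **Detection limits** (`lod_from_model()`):
   `LoB = mean_blank + 1.645·SD_blank`, `LoD = LoB + 1.645·SD_low`,
   applied to model-predicted concentrations of blank and
   low-concentration (0.01 mg/mL) replicate spectra.
6. **Experiment runner** (`run_experiment()`): config-driven comparison
   of NIR-only, ATR-only, fused-PLS and fused-PCR variants, with or
   without the lowest-level "blind" sample set, emitting a tidy report.

## Worked example

```r
library(irfusion)
report <- run_experiment(experiment_config(seeds = 1L))
report[, c("variant", "region", "n_components",
           "rmsec", "rmsecv", "rmsep", "r2_pred", "lob", "lod")]
```

```
   variant                       region n_components rmsec rmsecv rmsep r2_pred   lob   lod
   NIR-PLS                 2500-1350 nm            8 0.514  0.705 0.619   0.998 0.746 1.175
   ATR-PLS                12500-5556 nm           10 0.763  2.819 1.367   0.994 0.959 1.715
 Fused-PLS 2500-1350 nm + 12500-5556 nm           10 0.152  0.986 0.188   1.000 0.226 0.443
 Fused-PCR 2500-1350 nm + 12500-5556 nm           10 0.215  2.824 0.189   1.000 0.104 0.225
```

Each row is one model variant on the same simulated dataset (seed 1).
RMSEC/RMSECV/RMSEP are root mean square errors (mg/mL) on calibration,
cross-validation and the independent 13-sample prediction set; `r2_pred`
is the prediction-set coefficient of determination; `lob`/`lod` (mg/mL)
come from the model's predictions of the blank and 0.01 mg/mL replicate
spectra. The fused models cut RMSEP roughly threefold and the detection
limit two- to five-fold relative to the better single-block model —
the fusion benefit the package exists to study. Absolute values are
properties of the simulation, not of any laboratory dataset.

A thin CLI over the same functions lives in `inst/scripts/irfusion-cli.R`
(`simulate` and `run` subcommands); spectra exchange as wide CSV
(`write_spectra()`/`read_spectra()`), so externally measured data with
the same schema can be run through `run_experiment()` unchanged.

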