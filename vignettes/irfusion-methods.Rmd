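---
title: "Methods: MIR + NIR data fusion for serum analyte calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MIR + NIR data fusion for serum analyte calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Low-molecular-weight (LMW) metabolites in serum are hard to quantify
spectroscopically: the absorbance of abundant serum proteins dominates the
signal over most of the infrared range, and an analyte such as glycine at
physiological or near-physiological levels contributes only a small,
partially overlapped perturbation. Two instruments see complementary parts
of the chemistry. ATR-FTIR probes fundamental vibrations in the
mid-infrared (here 4000–800 cm⁻¹), where glycine has sharp fingerprint
bands (906, 1036, 1111, 1330, 1414 cm⁻¹, with 1330 and 906 cm⁻¹ the most
intense). Near-infrared spectroscopy (here 2500–1350 nm) records broad
overtone and combination bands (glycine at 2110, 2204, 2375 nm; serum
protein at 2055 and 2180 nm). `irfusion` implements and tests the claim
that concatenating both preprocessed blocks into a single calibration
("low-level data fusion") improves the prediction error and the detection
limit over either instrument alone.

## The calibration model

The quantitative core is latent-variable regression of analyte
concentration $y$ (mg/mL) on a preprocessed feature vector $x$:

* **PLS1 by NIPALS** (`fit_pls()`): components are extracted sequentially;
  each weight vector is proportional to $X^\top y$ (maximal covariance
  with the response), scores $t = Xw$, loadings $p = X^\top t / t^\top t$,
  then $X$ is deflated by $t p^\top$. With a univariate response the
  weight update is closed-form, so no inner iteration is required, and
  successive score vectors are orthogonal by construction. The collapsed
  regression vector is the standard $W (P^\top W)^{-1} q$.
* **PCR** (`fit_pcr()`): an SVD of the centered predictors followed by
  least squares of $y$ on the leading scores. PCR chooses directions by
  predictor variance alone, which is why it typically needs more
  components than PLS when the response lives in a low-variance direction
  — a property the test suite demonstrates with a constructed
  counterexample.

Both agree exactly with ordinary least squares at full rank, which is how
they are cross-checked.

Metrics follow the usual chemometric set: RMSEC on the calibration
spectra, RMSECV from grouped cross-validation, RMSEP and prediction $R^2$
on the held-out prediction samples.

## Preprocessing chain and its order

The fixed order is **Savitzky–Golay 2nd derivative → SNV → fusion →
mean-centering**, with defaults of a 15-point window and polynomial order
2 for the derivative. Decisions worth recording:

* **Per-block SNV before concatenation.** SNV across a heterogeneous
  fused vector would let the block with the larger derivative scale
  dominate; per-block SNV acts as implicit block scaling, and mirrors
  the practice of preprocessing each instrument's data in its own
  software before CSV export. Only mean-centering is computed on the
  fused matrix, always from calibration rows only.
* **Derivative edges.** The filter is exact on the interior; the
  `(window−1)/2` edge points replicate the nearest valid interior value
  so matrix width (and hence fusion bookkeeping) is preserved.
* **No common-grid interpolation.** Fusion is plain column concatenation
  with a provenance axis recording `(modality, native value, nm)` per
  column; the MIR block defaults to its 1800–800 cm⁻¹ fingerprint window
  (≈5556–12500 nm), the NIR block enters in full.
* **Re-application guard.** The chain is not idempotent; a preprocessed
  block refuses a second pass.

## Sample splitting

Kennard–Stone max–min selection on Euclidean distances, run on
**per-sample mean** preprocessed spectra rather than individual replicate
spectra, so all ~20 replicate spectra of a sample land on one side and
replicate leakage is impossible. Ties are broken toward the lowest index,
making the split deterministic. The default split keeps 2/3 of the
samples for calibration: 26 of 39 samples (520 of 780 spectra), with 13
samples (260 spectra) for prediction. Because Kennard–Stone selects
exterior points first, the blank and the 50 mg/mL extremes always end up
in calibration on clean data.

## Detection limits

`limit_of_blank()` and `limit_of_detection()` implement the replicate
protocol: LoB = mean(blank) + 1.645·SD(blank) and LoD = LoB +
1.645·SD(low), with the one-sided 95 % normal quantile and the sample
(n−1) standard deviation — the conventional choice for replicate-based
estimates. `lod_from_model()` applies them to *model-predicted*
concentrations of the blank and lowest-level (default 0.01 mg/mL)
replicate spectra. Negative predicted concentrations are deliberately
retained: clipping at zero would bias the blank SD downward and flatter
the LoD.

## What the simulator emulates

`simulate_dataset()` reproduces the statistical structure the analysis
assumes, not instrument physics. Each spectrum is

$$A = m\,(1+s) + c\,r\,g + b + \delta_{\text{rep}} + \varepsilon,$$

with $m$ the serum matrix spectrum (Gaussian band sums; amide I/II at the
literature-typical 1650/1540 cm⁻¹ plus broad envelopes, since the matrix
fingerprint positions are not tabulated anywhere authoritative), $g$ the
glycine spectrum, $r = 0.02$ AU/(mg/mL) its response, $s$ a per-spectrum
multiplicative scatter factor, $b$ a random quadratic baseline,
$\delta_{\text{rep}}$ a per-donor offset and $\varepsilon$ iid Gaussian
noise. Absorbance is clipped at zero after summation (physical
non-negativity). Default noise scales — noise SD 0.002 AU, baseline bound
0.01 AU, 1 % scatter, replicate offset SD 0.005 AU — are typical
magnitudes for dried-film FT-IR/NIR absorbance work relative to a ~1 AU
matrix signal, and they leave the matrix dominating the analyte at low
spike levels, which is exactly the masking problem fusion addresses.

The defaults reproduce the study design: a 13-level series (0, 0.01,
0.05, 0.1, 0.5, 1, 2.5, 5, 7.5, 10, 17.5, 25, 50 mg/mL) × 3 biological
replicates = 39 samples, 20 spectra per sample per instrument, a 141-point
NIR grid over 1350–2500 nm and a 4 cm⁻¹-spaced MIR grid over 800–4000 cm⁻¹
(8 cm⁻¹ resolution with zero-filling factor 2). Relative glycine band
amplitudes are fixed once so that 1330 > 906 ≫ the rest, matching the
qualitative intensity ordering; they are not fitted to any measured
spectrum.

What it does **not** emulate: water subtraction and drying physics,
wavelength-dependent (Mie-type) scatter needing MSC/EMSC,
heteroscedastic detector noise, instrument drift, or inter-donor
compositional differences beyond an additive offset. Passing tests
therefore show the pipeline's statistical machinery is correct and that
fusion helps *under these assumptions*; they do not certify the
real-serum detection limits, which depend on laboratory data this package
does not ship.

## Numerical choices and degenerate inputs

* NIPALS rank guard: a component whose score sum-of-squares falls below
  `1e-10 · ‖X‖²_F` triggers a rank-deficiency error rather than returning
  a numerically meaningless component; a response exactly orthogonal to
  the predictors returns the zero regression vector.
* Cross-validation is a contiguous venetian blind over samples with 10
  splits, grouped by sample id (a scheme has to be fixed; interleaving
  over the concentration-ordered samples keeps every fold spanning the
  range). Folds whose training response is constant warn and are skipped.
* SNV errors on constant rows, naming the offending row.
* SNV is a *nonlinear* map of the spectrum (each row is divided by its
  own SD), so after SNV the features of clean data are not affine in
  concentration. Exact-recovery statements (predictions within 1e-6
  mg/mL of truth on detector-noise-free data) are therefore made for the
  derivative-only chain, which is exactly linear and invertible at full
  rank; with SNV the relation is very nearly linear and default-noise
  prediction $R^2$ stays ≥ 0.99, but machine-precision recovery is not a
  mathematically available target. This is also why the exactness tests
  fit at the data's full rank (3 latent variables for the scatter-only
  design) rather than an arbitrary component count.
* The fused-PCR region and component defaults follow the fused-PLS ones;
  the variant table treats the occasional method/region inconsistencies
  a presentation layer would introduce as typographical.

## Problem sizes used by the test suite

The simulation studies in the tests use the full 39-sample × 20-spectra
design where counts themselves are under test, and 1–5 spectra per sample
where only the structure matters. The fusion-benefit study aggregates 25
seeds of the full design and compares medians: median fused-PLS LoD
against the better single-block median LoD, and median fused-PLS RMSEP
against fused-PCR. Blind-set robustness (including vs excluding the 0.01
mg/mL level) is likewise assessed as the median relative RMSEP change
over seeds, below 10 %; individual seeds can exceed that, which is
expected sampling variability of a 13-sample prediction set.

## Known limitations

* PLS1 only (univariate response); SIMPLS/kernel variants, variable
  selection and coefficient uncertainty are out of scope.
* The simulator's band libraries are stylized; absolute RMSEP/LoD values
  from simulations are not comparable to laboratory values, only
  orderings and qualitative behavior are.
* No vendor binary formats: spectra exchange as wide CSV only.
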