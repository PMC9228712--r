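Package: irfusion
Title: Mid- and Near-Infrared Data Fusion for Chemometric Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Chemometric calibration pipeline for quantifying a
    low-molecular-weight analyte (glycine) spiked into a serum matrix from
    paired mid-infrared (ATR-FTIR, 4000-800 1/cm) and near-infrared
    (2500-1350 nm) absorbance spectra. Provides a parametric synthetic
    spectrum generator (Gaussian/Lorentzian band models, baseline,
    multiplicative scatter, replicate structure, noise), Savitzky-Golay
    derivative and standard normal variate preprocessing, Kennard-Stone
    calibration subset selection, from-scratch PLS (NIPALS) and principal
    component regression with grouped cross-validation, low-level MIR+NIR
    block fusion, and replicate-based limit-of-blank / limit-of-detection
    estimation, together with a config-driven experiment runner that
    compares single-block and fused model variants.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
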