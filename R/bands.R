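#' Parametric absorption band
#'
#' A single absorption band used to synthesize pure-component spectra.
#' The peak value equals `amplitude` at `center` and falls to half the
#' amplitude at `center +/- fwhm/2` for both supported line shapes.
#'
#' @param center Band position, in the axis unit of the target grid.
#' @param fwhm Full width at half maximum (> 0), same unit.
#' @param amplitude Peak absorbance (>= 0).
#' @param shape `"gaussian"` (default) or `"lorentzian"`.
#' @return An object of class `band_model`.
#' @export
band_model <- function(center, fwhm, amplitude, shape = c("gaussian", "lorentzian")) {
  shape <- match.arg(shape)
  if (!is.numeric(fwhm) || fwhm <= 0) stop_invalid("fwhm must be > 0")
  if (!is.numeric(amplitude) || amplitude < 0)
    stop_invalid("amplitude must be >= 0")
  structure(list(center = center, fwhm = fwhm, amplitude = amplitude,
                 shape = shape),
            class = "band_model")
}

#' Evaluate a band on a grid
#'
#' @param band A [band_model()].
#' @param grid Strictly monotone numeric axis vector.
#' @return Non-negative intensity vector of `length(grid)`, maximal at the
#'   grid point nearest `band$center`.
#' @examples
#' g <- seq(1200, 1500, by = 2)
#' b <- band_model(1330, 20, 1)
#' max(evaluate_band(b, g))  # 1 at 1330
#' @export
evaluate_band <- function(band, grid) {
  stopifnot(inherits(band, "band_model"))
  d <- diff(grid)
  if (length(grid) < 2L || any(d == 0) || any(sign(d) != sign(d[1])))
    stop_invalid("grid must be strictly monotone")
  x <- grid - band$center
  switch(band$shape,
    gaussian = band$amplitude * exp(-4 * log(2) * (x / band$fwhm)^2),
    lorentzian = band$amplitude * (band$fwhm / 2)^2 /
      (x^2 + (band$fwhm / 2)^2)
  )
}

#' Pure-component band library
#'
#' Collects the MIR and NIR bands of one chemical component together with
#' its absorbance response per unit concentration (AU per mg/mL), the
#' Beer-Lambert proportionality used by the simulator.
#'
#' @param name Component name.
#' @param mir_bands,nir_bands Lists of [band_model()] objects.
#' @param response_per_unit_conc Absorbance per mg/mL scaling the
#'   component spectrum when the component is the spiked analyte.
#' @return An object of class `component_library`.
#' @export
component_library <- function(name, mir_bands = list(), nir_bands = list(),
                              response_per_unit_conc = 1) {
  ok <- function(l) is.list(l) && all(vapply(l, inherits, TRUE, "band_model"))
  if (!ok(mir_bands) || !ok(nir_bands))
    stop_invalid("bands must be lists of band_model objects")
  structure(list(name = name, mir_bands = mir_bands, nir_bands = nir_bands,
                 response_per_unit_conc = response_per_unit_conc),
            class = "component_library")
}

#' Sum a component's bands over a grid
#'
#' @param lib A [component_library()].
#' @param modality `"MIR"` or `"NIR"`; selects which band set to use.
#' @param grid Strictly monotone axis vector (cm-1 for MIR, nm for NIR).
#' @return Intensity vector: the sum of all evaluated bands.
#' @export
component_spectrum <- function(lib, modality = c("MIR", "NIR"), grid) {
  stopifnot(inherits(lib, "component_library"))
  modality <- match.arg(modality)
  bands <- if (modality == "MIR") lib$mir_bands else lib$nir_bands
  if (length(bands) == 0L)
    stop_invalid(sprintf("component '%s' has no %s bands", lib$name, modality))
  Reduce(`+`, lapply(bands, evaluate_band, grid = grid))
}

#' Default glycine band library
#'
#' Band positions follow the second-derivative assignments for dried
#' glycine deposits: MIR bands at 906 (CH2 rocking), 1036 (C-N stretch),
#' 1111 (NH3 rocking), 1330 (CH2 wagging) and 1414 cm-1 (O-C=O symmetric
#' stretch), with a shoulder at 884 cm-1; NIR combination bands at 2110,
#' 2204 and 2375 nm. Relative amplitudes are chosen so the 1330 and
#' 906 cm-1 bands dominate, with the global MIR maximum at 1330 cm-1; the
#' response is 0.02 AU per mg/mL so the 50 mg/mL top standard contributes
#' about 1 AU at the strongest band.
#'
#' @return A [component_library()].
#' @export
glycine_library <- function() {
  component_library(
    name = "glycine",
    mir_bands = list(
      band_model(884, 25, 0.30),
      band_model(906, 25, 0.85),
      band_model(1036, 25, 0.45),
      band_model(1111, 25, 0.40),
      band_model(1330, 25, 1.00),
      band_model(1414, 25, 0.55)
    ),
    nir_bands = list(
      band_model(2110, 60, 0.60),
      band_model(2204, 60, 0.50),
      band_model(2375, 60, 0.45)
    ),
    response_per_unit_conc = 0.02
  )
}

#' Default serum-matrix band library
#'
#' A serum-like background: NIR protein combination bands at 2055 nm
#' (N-H stretch / amide Ib) and 2180 nm (N-H bend overtone / C-H + C=O
#' combinations) on top of broad overtone envelopes; MIR amide I/II bands
#' at the literature-typical 1650 and 1540 cm-1 plus amide III, CH
#' deformation, a carbohydrate/phosphate envelope near 1080 cm-1 and the
#' broad N-H/O-H stretch around 3300 cm-1. Amplitudes make the matrix
#' dominate the analyte signal at low spike concentrations, reproducing
#' the dynamic-range masking problem the fusion approach addresses.
#'
#' @return A [component_library()].
#' @export
serum_library <- function() {
  component_library(
    name = "serum",
    mir_bands = list(
      band_model(3300, 350, 0.50),
      band_model(1650, 60, 1.00),
      band_model(1540, 50, 0.70),
      band_model(1450, 60, 0.30),
      band_model(1240, 80, 0.20),
      band_model(1080, 150, 0.25)
    ),
    nir_bands = list(
      band_model(1500, 200, 0.30),
      band_model(1940, 150, 0.40),
      band_model(2055, 70, 0.55),
      band_model(2180, 70, 0.50),
      band_model(2300, 200, 0.30)
    ),
    response_per_unit_conc = 1
  )
}
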