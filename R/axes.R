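#' Declare a spectral axis
#'
#' An axis specification describes the measurement grid of one instrument:
#' its unit (nanometres for NIR, inverse centimetres for MIR), its
#' endpoints, and the number of points. The realized grid is evenly spaced
#' and strictly monotone.
#'
#' @param unit Axis unit, `"nm"` (wavelength) or `"cm-1"` (wavenumber).
#' @param start,end Axis endpoints in `unit`; must differ.
#' @param n_points Number of grid points (at least 2).
#' @return An object of class `axis_spec`.
#' @examples
#' nir <- axis_spec("nm", 1350, 2500, 141)
#' head(realize_axis(nir))
#' @export
axis_spec <- function(unit = c("nm", "cm-1"), start, end, n_points) {
  unit <- match.arg(unit)
  if (!is.numeric(start) || !is.numeric(end) || start == end)
    stop_invalid("axis endpoints must be numeric and distinct")
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 2L)
    stop_invalid("axis needs at least 2 points")
  structure(list(unit = unit, start = start, end = end,
                 n_points = n_points),
            class = "axis_spec")
}

#' @rdname axis_spec
#' @param spec An `axis_spec`.
#' @export
realize_axis <- function(spec) {
  stopifnot(inherits(spec, "axis_spec"))
  seq(spec$start, spec$end, length.out = spec$n_points)
}

#' Default instrument grids
#'
#' `nir_axis()` is the handheld NIR spectrometer grid: 141 evenly spaced
#' points covering 1350-2500 nm (16 nm nominal resolution).
#' `mir_axis()` is the ATR-FTIR grid: 4000-800 cm-1 acquired at 8 cm-1
#' resolution with zero-filling factor 2, giving 4 cm-1 point spacing
#' (801 points). Both grids are stored in increasing axis order.
#'
#' @return An `axis_spec`.
#' @export
nir_axis <- function() axis_spec("nm", 1350, 2500, 141)

#' @rdname nir_axis
#' @export
mir_axis <- function() axis_spec("cm-1", 800, 4000, 801)

#' Convert wavenumbers to wavelengths
#'
#' Maps a wavenumber axis (cm-1) onto wavelength in nm via
#' `nm = 1e7 / cm-1` and reverses the order so the result is increasing
#' in nm. Callers reordering intensities must apply the same reversal.
#'
#' @param axis_cm Numeric vector of positive wavenumbers (cm-1).
#' @return Increasing numeric vector of wavelengths in nm.
#' @examples
#' to_wavelength(c(4000, 800))  # 2500 and 12500 nm
#' @export
to_wavelength <- function(axis_cm) {
  if (!is.numeric(axis_cm) || any(axis_cm <= 0))
    stop_invalid("wavenumbers must be positive to convert to wavelength")
  sort(1e7 / axis_cm)
}

# spacing of a uniform grid; errors if spacing varies beyond tolerance
grid_spacing <- function(grid) {
  d <- diff(grid)
  if (length(d) == 0L) stop_invalid("grid too short")
  if (any(d == 0) || any(sign(d) != sign(d[1])))
    stop_invalid("grid must be strictly monotone")
  if (max(abs(d - d[1])) > 1e-8 * abs(d[1]))
    stop_invalid("grid must be evenly spaced")
  abs(d[1])
}
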