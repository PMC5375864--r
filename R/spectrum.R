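#' Construct a Spectrum
#'
#' A `Spectrum` is the atomic unit of all spectral computation in shadespec:
#' a strictly increasing wavelength grid in nanometres paired with
#' non-negative, finite reflectance values.
#'
#' @param wavelength Numeric vector of band centres in nm, strictly increasing.
#' @param value Numeric vector of reflectance (unitless), same length as
#'   `wavelength`.
#' @return An object of class `"Spectrum"`: a list with elements `wavelength`
#'   and `value`.
#' @examples
#' s <- Spectrum(c(500, 600, 700), c(0.1, 0.3, 0.2))
#' s$value
#' @export
Spectrum <- function(wavelength, value) {
  wavelength <- as.numeric(wavelength)
  value <- as.numeric(value)
  if (length(wavelength) != length(value))
    stop("wavelength and value must have equal length", call. = FALSE)
  if (length(wavelength) < 2L)
    stop("a Spectrum needs at least 2 points", call. = FALSE)
  if (any(!is.finite(wavelength)) || is.unsorted(wavelength, strictly = TRUE))
    stop("wavelength must be finite and strictly increasing", call. = FALSE)
  if (any(!is.finite(value)) || any(value < 0))
    stop("value must be finite and >= 0", call. = FALSE)
  structure(list(wavelength = wavelength, value = value), class = "Spectrum")
}

#' @export
print.Spectrum <- function(x, ...) {
  cat(sprintf("Spectrum: %d bands, %.1f-%.1f nm, values in [%.4g, %.4g]\n",
              length(x$wavelength), min(x$wavelength), max(x$wavelength),
              min(x$value), max(x$value)))
  invisible(x)
}

#' Canopy component class codes
#'
#' The four canopy component classes: sunlit leaf (SL), shaded leaf (SHL),
#' sunlit panicle (SP) and shaded panicle (SHP).
#' @export
COMPONENT_CLASSES <- c("SL", "SHL", "SP", "SHP")

#' Growth stage labels
#'
#' Six critical growth stages of paddy rice: early tillering (ET), fully
#' tillering (FT), jointing (JT), booting (BT), heading (HD), filling (FL).
#' @export
GROWTH_STAGES <- c("ET", "FT", "JT", "BT", "HD", "FL")

#' Construct a SpectralLibrary
#'
#' A labelled collection of spectra (the region-of-interest pixel sets) on a
#' shared wavelength grid, tagged by canopy component class and growth stage.
#'
#' @param wavelength Shared wavelength grid (nm, strictly increasing).
#' @param values Numeric matrix, one spectrum per row, `length(wavelength)`
#'   columns.
#' @param class Character vector of component classes, one per row; each must
#'   be one of `COMPONENT_CLASSES`.
#' @param stage Character vector of growth stage labels, one per row.
#' @return An object of class `"SpectralLibrary"`.
#' @export
SpectralLibrary <- function(wavelength, values, class, stage) {
  values <- as.matrix(values)
  if (ncol(values) != length(wavelength))
    stop("values must have one column per wavelength", call. = FALSE)
  if (length(class) != nrow(values) || length(stage) != nrow(values))
    stop("class and stage must have one entry per spectrum", call. = FALSE)
  bad <- setdiff(unique(class), COMPONENT_CLASSES)
  if (length(bad))
    stop("unknown component class label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (is.unsorted(wavelength, strictly = TRUE))
    stop("wavelength must be strictly increasing", call. = FALSE)
  structure(list(wavelength = as.numeric(wavelength), values = values,
                 class = as.character(class), stage = as.character(stage)),
            class = "SpectralLibrary")
}

#' @export
print.SpectralLibrary <- function(x, ...) {
  cat(sprintf("SpectralLibrary: %d spectra, %d bands (%.1f-%.1f nm)\n",
              nrow(x$values), length(x$wavelength),
              min(x$wavelength), max(x$wavelength)))
  print(table(class = x$class, stage = x$stage))
  invisible(x)
}

#' Extract one entry of a SpectralLibrary as a Spectrum
#'
#' @param library A `SpectralLibrary`.
#' @param i Row index.
#' @return A `Spectrum`.
#' @export
library_spectrum <- function(library, i) {
  Spectrum(library$wavelength, library$values[i, ])
}

#' Mean spectrum of a class
#'
#' Pointwise arithmetic mean over all library spectra of one component class,
#' optionally restricted to a growth stage. This is the "mean reflectance
#' spectrum" each library spectrum is matched against.
#'
#' @param library A `SpectralLibrary`.
#' @param class One of `COMPONENT_CLASSES`.
#' @param stage Optional stage label to filter on (default: all stages).
#' @return A `Spectrum`.
#' @export
class_mean_spectrum <- function(library, class, stage = NULL) {
  keep <- library$class == class
  if (!is.null(stage)) keep <- keep & library$stage == stage
  if (!any(keep))
    stop(sprintf("no library entries for class '%s'%s", class,
                 if (is.null(stage)) "" else sprintf(" at stage '%s'", stage)),
         call. = FALSE)
  Spectrum(library$wavelength, colMeans(library$values[keep, , drop = FALSE]))
}

#' Nearest band lookup
#'
#' Index formulas name exact wavelengths (e.g. R670) but real grids sample at
#' ~2.8 nm; this resolves a target wavelength to the nearest sampled band.
#' Ties are broken toward the lower wavelength.
#'
#' @param wavelength Numeric wavelength grid in nm.
#' @param target Target wavelength in nm.
#' @param tol Maximum allowed |grid - target| in nm; default twice the median
#'   grid step.
#' @return Integer band index.
#' @export
nearest_band <- function(wavelength, target, tol = NULL) {
  if (is.null(tol)) tol <- 2 * stats::median(diff(wavelength))
  if (!is.finite(tol) || tol <= 0) stop("tol must be > 0", call. = FALSE)
  d <- abs(wavelength - target)
  i <- which.min(d)  # which.min returns the first (lower-wavelength) minimum
  if (d[i] > tol)
    stop(sprintf("no band within %.3g nm of %.4g nm (nearest: %.4g nm)",
                 tol, target, wavelength[i]), call. = FALSE)
  i
}
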