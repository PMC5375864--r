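#' Default continuum-removal windows
#'
#' The carotenoid absorption feature is analysed in the blue window
#' (400-550 nm) and the chlorophyll feature in the red window (550-750 nm).
#' Both windows are closed intervals.
#'
#' @param name `"blue"` or `"red"`.
#' @return Numeric `c(low, high)` in nm.
#' @export
continuum_window <- function(name = c("blue", "red")) {
  switch(match.arg(name), blue = c(400, 550), red = c(550, 750))
}

window_bands <- function(spectrum, window) {
  if (is.character(window)) window <- continuum_window(window)
  idx <- which(spectrum$wavelength >= window[1] &
               spectrum$wavelength <= window[2])
  if (length(idx) < 3L)
    stop(sprintf("fewer than 3 bands inside [%.4g, %.4g] nm",
                 window[1], window[2]), call. = FALSE)
  idx
}

# Upper convex hull of (x, y) by Andrew's monotone chain; x strictly
# increasing. Returns indices of hull vertices, first and last always kept.
upper_hull_indices <- function(x, y) {
  cross <- function(o, a, b)
    (x[a] - x[o]) * (y[b] - y[o]) - (y[a] - y[o]) * (x[b] - x[o])
  h <- integer(0)
  for (i in seq_along(x)) {
    while (length(h) >= 2L &&
           cross(h[length(h) - 1L], h[length(h)], i) >= 0) {
      h <- h[-length(h)]
    }
    h <- c(h, i)
  }
  h
}

#' Continuum hull of a spectrum over a window
#'
#' The upper convex hull of the (wavelength, reflectance) points restricted
#' to the window, evaluated at every in-window wavelength by linear
#' interpolation between hull vertices. The hull passes through the first and
#' last in-window points.
#'
#' @param spectrum A [Spectrum].
#' @param window `"blue"`, `"red"`, or a numeric `c(low, high)` in nm.
#' @return A [Spectrum] of hull values on the in-window grid.
#' @export
continuum_hull <- function(spectrum, window = "red") {
  idx <- window_bands(spectrum, window)
  wl <- spectrum$wavelength[idx]; v <- spectrum$value[idx]
  h <- upper_hull_indices(wl, v)
  hull <- stats::approx(wl[h], v[h], xout = wl)$y
  Spectrum(wl, hull)
}

#' Continuum-removed spectrum
#'
#' Pointwise division of the spectrum by its continuum hull within the
#' window. Output values lie in (0, 1] and equal 1 exactly where the spectrum
#' touches the hull, including both window endpoints. The result is invariant
#' to scaling the input by any positive constant.
#'
#' @inheritParams continuum_hull
#' @return A [Spectrum] of continuum-removed values on the in-window grid.
#' @export
continuum_remove <- function(spectrum, window = "red") {
  idx <- window_bands(spectrum, window)
  wl <- spectrum$wavelength[idx]; v <- spectrum$value[idx]
  hull <- continuum_hull(spectrum, window)$value
  if (any(hull <= 0))
    stop("continuum hull is zero inside the window; cannot divide",
         call. = FALSE)
  cr <- v / hull
  cr[cr > 1] <- 1  # guard against rounding above the hull
  Spectrum(wl, cr)
}

#' Absorption band depth of a continuum-removed spectrum
#'
#' One minus the minimum continuum-removed value: 0 for a featureless
#' spectrum, approaching 1 for a saturated absorption. The scalar summary
#' used for sunlit-versus-shaded absorption comparisons.
#'
#' @param cr_spectrum A continuum-removed [Spectrum].
#' @return Unitless depth in `[0, 1)`.
#' @export
band_depth <- function(cr_spectrum) {
  1 - min(cr_spectrum$value)
}

# Concatenated blue + red continuum-removed values: the matching space used
# when classifying on continuum-removed spectra (the shared 550 nm band is
# kept once).
cr_concat_values <- function(spectrum) {
  blue <- continuum_remove(spectrum, "blue")
  red <- continuum_remove(spectrum, "red")
  drop1 <- length(blue$value)
  c(blue$value[-drop1], red$value)
}
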