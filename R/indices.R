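#' Vegetation indices
#'
#' Narrow-band vegetation indices computed from a [Spectrum], with anchor
#' wavelengths resolved to the nearest sampled band:
#'
#' * `ndvi`: (R800 - R670) / (R800 + R670) — canopy greenness.
#' * `tcari`: 3 \[(R700 - R670) - 0.2 (R700 - R550) (R700 / R670)\] —
#'   chlorophyll absorption; unlike the ratio indices it scales linearly
#'   with overall amplitude, which is what makes it sensitive to shading.
#' * `pri`: (R531 - R570) / (R531 + R570) — xanthophyll-cycle
#'   photochemical reflectance.
#' * `ci_red_edge`: R800 / R720 - 1 — red-edge chlorophyll index.
#' * `evi`: 2.5 (NIR - Red) / (NIR + 6 Red - 7.5 Blue + 1) with anchors
#'   800/670/470 nm — soil-adjusted greenness, used for vegetation masking.
#'
#' @param s A [Spectrum] (reflectance).
#' @param tol Band-lookup tolerance in nm passed to [nearest_band()]
#'   (default: twice the grid step).
#' @return An object of class `"VIResult"`: list with `name`, `value`, and
#'   `bands` (the resolved target-nm to band-index map). Use `vi_value()` or
#'   `$value` for the bare number.
#' @name vegetation-indices
NULL

vi_result <- function(name, value, bands) {
  structure(list(name = name, value = value, bands = bands),
            class = "VIResult")
}

#' @export
print.VIResult <- function(x, ...) {
  cat(sprintf("%s = %.6g  (anchors: %s)\n", x$name, x$value,
              paste(sprintf("%snm->band %d", names(x$bands), x$bands),
                    collapse = ", ")))
  invisible(x)
}

#' @rdname vegetation-indices
#' @export
vi_value <- function(x) x$value

anchor_values <- function(s, targets, tol) {
  idx <- vapply(targets, function(t) nearest_band(s$wavelength, t, tol),
                integer(1))
  names(idx) <- as.character(targets)
  list(idx = idx, v = s$value[idx])
}

#' @rdname vegetation-indices
#' @export
ndvi <- function(s, tol = NULL) {
  a <- anchor_values(s, c(800, 670), tol)
  den <- a$v[1] + a$v[2]
  if (den == 0) stop("NDVI undefined: R800 + R670 = 0", call. = FALSE)
  vi_result("NDVI", unname((a$v[1] - a$v[2]) / den), a$idx)
}

#' @rdname vegetation-indices
#' @export
tcari <- function(s, tol = NULL) {
  a <- anchor_values(s, c(700, 670, 550), tol)
  r700 <- a$v[1]; r670 <- a$v[2]; r550 <- a$v[3]
  if (r670 == 0) stop("TCARI undefined: R670 = 0", call. = FALSE)
  vi_result("TCARI",
            3 * ((r700 - r670) - 0.2 * (r700 - r550) * (r700 / r670)),
            a$idx)
}

#' @rdname vegetation-indices
#' @export
pri <- function(s, tol = NULL) {
  a <- anchor_values(s, c(531, 570), tol)
  den <- a$v[1] + a$v[2]
  if (den == 0) stop("PRI undefined: R531 + R570 = 0", call. = FALSE)
  vi_result("PRI", unname((a$v[1] - a$v[2]) / den), a$idx)
}

#' @rdname vegetation-indices
#' @export
ci_red_edge <- function(s, tol = NULL) {
  a <- anchor_values(s, c(800, 720), tol)
  if (a$v[2] == 0) stop("CI_Red-edge undefined: R720 = 0", call. = FALSE)
  vi_result("CI_Red-edge", unname(a$v[1] / a$v[2] - 1), a$idx)
}

#' @rdname vegetation-indices
#' @export
evi <- function(s, tol = NULL) {
  a <- anchor_values(s, c(800, 670, 470), tol)
  nir <- a$v[1]; red <- a$v[2]; blue <- a$v[3]
  den <- nir + 6 * red - 7.5 * blue + 1
  if (den == 0) stop("EVI undefined: zero denominator", call. = FALSE)
  vi_result("EVI", unname(2.5 * (nir - red) / den), a$idx)
}

vi_fun <- function(name) {
  switch(tolower(name),
         ndvi = ndvi, tcari = tcari, pri = pri,
         cire = ci_red_edge, "ci_red-edge" = ci_red_edge,
         ci_red_edge = ci_red_edge, evi = evi,
         stop("unknown vegetation index: ", name, call. = FALSE))
}

#' Per-pixel vegetation index image
#'
#' Applies one vegetation index to every pixel of a reflectance cube.
#' Pixels where the index is undefined (or masked out) are `NA`; a bad pixel
#' never aborts the map.
#'
#' @param cube A reflectance [HyperCube].
#' @param name Index name: `"ndvi"`, `"tcari"`, `"pri"`, `"cire"`, `"evi"`.
#' @param mask Optional logical matrix (rows x cols); pixels with `FALSE`
#'   are returned as `NA`.
#' @return Numeric matrix (rows x cols) of index values.
#' @export
vi_image <- function(cube, name, mask = NULL) {
  stopifnot(cube$units == "reflectance")
  f <- vi_fun(name)
  # resolve anchors once on the shared grid by probing a unit spectrum
  probe <- f(Spectrum(cube$wavelengths,
                      rep(1, length(cube$wavelengths))))
  idx <- probe$bands
  m <- cube_matrix(cube)[, idx, drop = FALSE]
  val <- switch(probe$name,
    "NDVI" = {
      den <- m[, 1] + m[, 2]
      ifelse(den == 0, NA_real_, (m[, 1] - m[, 2]) / den)
    },
    "TCARI" = ifelse(m[, 2] == 0, NA_real_,
      3 * ((m[, 1] - m[, 2]) - 0.2 * (m[, 1] - m[, 3]) * (m[, 1] / m[, 2]))),
    "PRI" = {
      den <- m[, 1] + m[, 2]
      ifelse(den == 0, NA_real_, (m[, 1] - m[, 2]) / den)
    },
    "CI_Red-edge" = ifelse(m[, 2] == 0, NA_real_, m[, 1] / m[, 2] - 1),
    "EVI" = {
      den <- m[, 1] + 6 * m[, 2] - 7.5 * m[, 3] + 1
      ifelse(den == 0, NA_real_, 2.5 * (m[, 1] - m[, 2]) / den)
    })
  d <- dim(cube$data)
  out <- matrix(val, d[1], d[2], byrow = TRUE)
  if (!is.null(mask)) out[!mask] <- NA_real_
  out
}
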