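#' Construct a HyperCube
#'
#' The image data model: a rows x cols x bands array of raw digital numbers
#' (DN, sensor counts) or relative reflectance, with the band-centre
#' wavelengths in nm. Spatial coordinates are (row, col), row 1 at the top.
#'
#' @param data 3-D numeric array, rows x cols x bands.
#' @param wavelengths Band centres in nm, strictly increasing, length equal to
#'   `dim(data)[3]`.
#' @param units `"dn"` for raw counts or `"reflectance"`. Reflectance cubes
#'   must be non-negative (values > 1 are allowed: calibration is not
#'   clipped, so specular pixels can exceed the panel).
#' @param metadata Named list of free-form character metadata (acquisition
#'   date, stage label, exposure, ...).
#' @return An object of class `"HyperCube"`.
#' @examples
#' cube <- HyperCube(array(0.2, c(2, 2, 3)), c(500, 600, 700), "reflectance")
#' dim(cube$data)
#' @export
HyperCube <- function(data, wavelengths, units = c("reflectance", "dn"),
                      metadata = list()) {
  units <- match.arg(units)
  if (length(dim(data)) != 3L)
    stop("data must be a rows x cols x bands array", call. = FALSE)
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != dim(data)[3])
    stop("length(wavelengths) must equal the band dimension", call. = FALSE)
  if (is.unsorted(wavelengths, strictly = TRUE))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  if (units == "reflectance") {
    v <- data[is.finite(data)]
    if (length(v) && any(v < 0))
      stop("reflectance cube contains negative values", call. = FALSE)
  }
  structure(list(data = data, wavelengths = wavelengths, units = units,
                 metadata = metadata), class = "HyperCube")
}

#' @export
print.HyperCube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("HyperCube: %d x %d pixels, %d bands (%.1f-%.1f nm), units: %s\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths),
              x$units))
  invisible(x)
}

#' Extract one pixel of a HyperCube as a Spectrum
#'
#' @param cube A `HyperCube`.
#' @param row,col Pixel coordinates (1-based, row 1 at top).
#' @return A `Spectrum`.
#' @export
pixel_spectrum <- function(cube, row, col) {
  Spectrum(cube$wavelengths, cube$data[row, col, ])
}

# Flatten a cube to a pixels x bands matrix (row-major pixel order).
cube_matrix <- function(cube) {
  d <- dim(cube$data)
  m <- matrix(aperm(cube$data, c(3, 2, 1)), ncol = d[3], byrow = TRUE)
  m  # pixel order: (row 1, col 1), (row 1, col 2), ...
}

# Inverse of cube_matrix.
matrix_cube <- function(m, rows, cols) {
  aperm(array(t(m), c(ncol(m), cols, rows)), c(3, 2, 1))
}

#' Construct a LabelMap
#'
#' A per-pixel classification: a rows x cols integer matrix of class codes
#' plus the code table mapping codes to class names. Legal class names are
#' the four canopy components (`COMPONENT_CLASSES`) plus `"NONVEG"` and
#' `"UNLABELED"`.
#'
#' @param labels Integer matrix of class codes.
#' @param code_table Named integer vector: `code_table[["SL"]] == 1` etc.
#' @return An object of class `"LabelMap"`.
#' @export
LabelMap <- function(labels, code_table) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  allowed <- c(COMPONENT_CLASSES, "NONVEG", "UNLABELED")
  bad <- setdiff(names(code_table), allowed)
  if (length(bad))
    stop("illegal class name(s) in code_table: ", paste(bad, collapse = ", "),
         call. = FALSE)
  present <- unique(as.vector(labels))
  missing <- setdiff(present, as.integer(code_table))
  if (length(missing))
    stop("label code(s) absent from code_table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  structure(list(labels = labels,
                 code_table = stats::setNames(as.integer(code_table),
                                              names(code_table))),
            class = "LabelMap")
}

#' @export
print.LabelMap <- function(x, ...) {
  cat(sprintf("LabelMap: %d x %d pixels\n", nrow(x$labels), ncol(x$labels)))
  nm <- names(x$code_table)[match(as.vector(x$labels), x$code_table)]
  print(table(nm))
  invisible(x)
}

#' Class names of a LabelMap as a character matrix
#'
#' @param labels A `LabelMap`.
#' @return Character matrix of class names, same shape as `labels$labels`.
#' @export
label_names <- function(labels) {
  m <- matrix(names(labels$code_table)[match(as.vector(labels$labels),
                                             labels$code_table)],
              nrow(labels$labels), ncol(labels$labels))
  m
}
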