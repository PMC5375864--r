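#' Construct a CalibrationSet
#'
#' The dark-current and white-panel measurements needed to convert raw
#' digital numbers to relative reflectance.
#'
#' @param dn_noise Dark-current DN, scalar or per band (counts).
#' @param dn_panel White-reference panel DN, per band (counts); must exceed
#'   `dn_noise` at every band.
#' @param ref_panel Panel reflectance, scalar or per band, in (0, 1].
#' @return An object of class `"CalibrationSet"`.
#' @export
CalibrationSet <- function(dn_noise, dn_panel, ref_panel = 0.99) {
  n <- length(dn_panel)
  dn_noise <- rep_len(as.numeric(dn_noise), n)
  ref_panel <- rep_len(as.numeric(ref_panel), n)
  if (any(ref_panel <= 0 | ref_panel > 1))
    stop("ref_panel must lie in (0, 1]", call. = FALSE)
  if (any(dn_panel <= dn_noise))
    stop("dn_panel must exceed dn_noise at every band", call. = FALSE)
  structure(list(dn_noise = dn_noise, dn_panel = as.numeric(dn_panel),
                 ref_panel = ref_panel), class = "CalibrationSet")
}

#' Radiometric calibration: DN to relative reflectance
#'
#' Per band, reflectance = (DN - DN_noise) / (DN_panel - DN_noise) x
#' Ref_panel: dark-current subtraction followed by normalisation to the white
#' reference panel. Output is not clipped; specular pixels may exceed 1.
#'
#' @param cube A DN [HyperCube].
#' @param cal A [CalibrationSet] band-aligned with `cube`.
#' @return A reflectance [HyperCube] with the same shape and wavelengths.
#' @export
calibrate <- function(cube, cal) {
  stopifnot(inherits(cube, "HyperCube"), inherits(cal, "CalibrationSet"))
  if (cube$units != "dn")
    stop("calibrate expects a DN cube", call. = FALSE)
  nb <- dim(cube$data)[3]
  if (length(cal$dn_panel) != nb)
    stop("calibration set is not band-aligned with the cube", call. = FALSE)
  gain <- cal$ref_panel / (cal$dn_panel - cal$dn_noise)
  d <- sweep(cube$data, 3, cal$dn_noise, "-")
  d <- sweep(d, 3, gain, "*")
  d[d < 0] <- 0  # dark noise can push DN below the dark reference
  HyperCube(d, cube$wavelengths, "reflectance", cube$metadata)
}

#' Minimum noise fraction denoising
#'
#' Forward-plus-inverse MNF smoothing: the noise covariance is estimated
#' from horizontal (along-row) first differences divided by sqrt(2); the
#' data are whitened by that covariance; components of the whitened data
#' covariance are ranked by decreasing eigenvalue; and the cube is
#' reconstructed from the leading `k` components, leaving the output in the
#' same reflectance space as the input.
#'
#' @param cube A [HyperCube] with at least 2 columns.
#' @param k Number of retained components. `NULL` (default) keeps the
#'   components whose noise-whitened eigenvalue exceeds 1, i.e. those with
#'   more signal than noise.
#' @return A [HyperCube] of the same shape, units and wavelengths.
#' @export
mnf_denoise <- function(cube, k = NULL) {
  d <- dim(cube$data)
  if (d[2] < 2L)
    stop("MNF noise estimation needs at least 2 columns", call. = FALSE)
  nb <- d[3]
  x <- cube_matrix(cube)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)

  diffs <- cube$data[, -1L, , drop = FALSE] - cube$data[, -d[2], , drop = FALSE]
  n <- matrix(aperm(diffs, c(3, 2, 1)), ncol = nb, byrow = TRUE) / sqrt(2)
  sigma_n <- stats::cov(n)
  # regularize a (near-)singular noise covariance
  if (!all(is.finite(sigma_n)) ||
      rcond_sym(sigma_n) < .Machine$double.eps) {
    diag(sigma_n) <- diag(sigma_n) + 1e-10 * sum(diag(sigma_n)) / nb
  }
  en <- eigen(sigma_n, symmetric = TRUE)
  ev <- pmax(en$values, 1e-12 * max(en$values, 1e-300))
  if (max(ev) <= 0)
    stop("noise covariance is singular even after regularization",
         call. = FALSE)
  whiten <- en$vectors %*% diag(1 / sqrt(ev), nb)

  sigma_w <- crossprod(xc %*% whiten) / (nrow(xc) - 1L)
  ew <- eigen(sigma_w, symmetric = TRUE)        # decreasing eigenvalues
  tr <- whiten %*% ew$vectors                   # full MNF transform
  if (is.null(k)) k <- max(1L, sum(ew$values > 1))
  if (k < 1L || k > nb) stop("k must be in 1..bands", call. = FALSE)
  scores <- xc %*% tr[, seq_len(k), drop = FALSE]
  back <- solve(tr)[seq_len(k), , drop = FALSE]
  xr <- sweep(scores %*% back, 2, mu, "+")
  if (cube$units == "reflectance") xr[xr < 0] <- 0
  HyperCube(matrix_cube(xr, d[1], d[2]), cube$wavelengths, cube$units,
            cube$metadata)
}

rcond_sym <- function(m) {
  ev <- tryCatch(eigen(m, symmetric = TRUE, only.values = TRUE)$values,
                 error = function(e) NA_real_)
  if (anyNA(ev) || max(abs(ev)) == 0) return(0)
  min(abs(ev)) / max(abs(ev))
}

#' Subset a cube to a wavelength range
#'
#' Keeps bands with `low <= wavelength <= high`; the analysis retains
#' 400-900 nm, where the sensor is quiet.
#'
#' @param cube A [HyperCube].
#' @param low,high Range bounds in nm.
#' @return A [HyperCube] restricted to the closed interval.
#' @export
subset_bands <- function(cube, low = 400, high = 900) {
  if (low >= high) stop("low must be < high", call. = FALSE)
  keep <- which(cube$wavelengths >= low & cube$wavelengths <= high)
  if (!length(keep))
    stop(sprintf("no bands inside [%.4g, %.4g] nm", low, high),
         call. = FALSE)
  HyperCube(cube$data[, , keep, drop = FALSE], cube$wavelengths[keep],
            cube$units, cube$metadata)
}

#' EVI vegetation mask
#'
#' `TRUE` where the enhanced vegetation index strictly exceeds the
#' threshold; pixels at or below it (soil, water, background) are masked out.
#'
#' @param cube A reflectance [HyperCube] covering the 470/670/800 nm anchors.
#' @param threshold Unitless EVI threshold, default 0.45.
#' @return Logical matrix (rows x cols); `NA` EVI yields `FALSE`.
#' @export
evi_mask <- function(cube, threshold = 0.45) {
  e <- vi_image(cube, "evi")
  m <- !is.na(e) & e > threshold
  m
}
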