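#' Construct a ComponentModel
#'
#' Parametric reflectance model for one canopy component class. A smooth
#' plateau profile (visible baseline rising through a red-edge ramp to a NIR
#' plateau) is multiplied by Gaussian absorption features and, for shaded
#' classes, by an amplitude shade factor; shading additionally deepens the
#' absorption features by a multiplicative boost. The two shading knobs are
#' independent because they model different mechanisms: diffuse irradiance
#' attenuates amplitude, while multiple scattering within the canopy deepens
#' apparent absorption.
#'
#' @param class One of `COMPONENT_CLASSES`.
#' @param nir_plateau Reflectance level reached in the 750-900 nm plateau.
#' @param vis_base Visible-region continuum reflectance.
#' @param pigment_bands Data frame with columns `center` (nm), `width` (nm,
#'   Gaussian sigma) and `depth` (fractional absorption in `[0, 1)`).
#' @param shade_factor Amplitude scalar in (0, 1]; must be 1 for sunlit
#'   classes.
#' @param absorption_boost Multiplier >= 1 applied to band depths; 1 for
#'   sunlit classes.
#' @param pixel_noise_sd Standard deviation of per-band multiplicative
#'   log-normal pixel noise (uncorrelated across bands: sensor noise).
#' @param amplitude_sd Standard deviation of a per-pixel spectrally flat
#'   log-normal amplitude factor (illumination and geometry variation
#'   between pixels of one class; it moves the whole spectrum up or down
#'   and is invisible to ratio indices).
#' @param tilt_sd Standard deviation of a per-pixel spectral slope factor
#'   `1 + t (lambda - 450) / 450`: smooth tilting of the spectrum pivoted
#'   in the blue, from leaf-angle and multiple-scattering variation. It
#'   mostly perturbs the NIR plateau (large absolute changes) while leaving
#'   relative band ratios within the visible nearly untouched.
#' @return An object of class `"ComponentModel"`.
#' @export
ComponentModel <- function(class, nir_plateau, vis_base, pigment_bands,
                           shade_factor = 1, absorption_boost = 1,
                           pixel_noise_sd = 0.02, amplitude_sd = 0.05,
                           tilt_sd = 0.08) {
  class <- match.arg(class, COMPONENT_CLASSES)
  sunlit <- class %in% c("SL", "SP")
  if (shade_factor <= 0 || shade_factor > 1)
    stop("shade_factor must lie in (0, 1]", call. = FALSE)
  if (sunlit && shade_factor != 1)
    stop("sunlit classes must have shade_factor = 1", call. = FALSE)
  if (absorption_boost < 1)
    stop("absorption_boost must be >= 1", call. = FALSE)
  pigment_bands <- as.data.frame(pigment_bands)
  stopifnot(all(c("center", "width", "depth") %in% names(pigment_bands)))
  if (any(pigment_bands$depth < 0 | pigment_bands$depth >= 1))
    stop("band depths must lie in [0, 1)", call. = FALSE)
  if (any(pigment_bands$depth * absorption_boost >= 1))
    stop("boosted band depth reaches 1; reflectance would hit 0",
         call. = FALSE)
  structure(list(class = class, nir_plateau = nir_plateau,
                 vis_base = vis_base, pigment_bands = pigment_bands,
                 shade_factor = shade_factor,
                 absorption_boost = absorption_boost,
                 pixel_noise_sd = pixel_noise_sd,
                 amplitude_sd = amplitude_sd, tilt_sd = tilt_sd),
            class = "ComponentModel")
}

#' @export
print.ComponentModel <- function(x, ...) {
  cat(sprintf(
    "ComponentModel %s: NIR %.2f, visible %.2f, shade %.2f, boost %.2f, %d bands\n",
    x$class, x$nir_plateau, x$vis_base, x$shade_factor, x$absorption_boost,
    nrow(x$pigment_bands)))
  invisible(x)
}

# Red-edge ramp parameters shared by all component models.
RED_EDGE_CENTER <- 722
RED_EDGE_WIDTH <- 9

#' Plateau profile of a component model
#'
#' The absorption-free continuum: the visible baseline rising smoothly
#' (logistic ramp centred near 700 nm) to the NIR plateau.
#'
#' @param model A [ComponentModel].
#' @param grid Wavelengths in nm.
#' @return Numeric reflectance vector.
#' @export
plateau_profile <- function(model, grid) {
  ramp <- 1 / (1 + exp(-(grid - RED_EDGE_CENTER) / RED_EDGE_WIDTH))
  model$vis_base + (model$nir_plateau - model$vis_base) * ramp
}

absorption_factor <- function(model, grid) {
  f <- rep(1, length(grid))
  b <- model$pigment_bands
  for (i in seq_len(nrow(b))) {
    f <- f * (1 - b$depth[i] * model$absorption_boost *
                exp(-(grid - b$center[i])^2 / (2 * b$width[i]^2)))
  }
  f
}

#' Draw one pixel spectrum from a component model
#'
#' reflectance(lambda) = shade_factor x plateau x prod(1 - boosted Gaussian
#' absorptions) x log-normal pixel noise. Uses the current R random number
#' state; seed upstream for reproducibility.
#'
#' @param model A [ComponentModel].
#' @param grid Ascending wavelengths in nm within `[400, 900]`.
#' @return A [Spectrum] with values in (0, 1).
#' @export
component_spectrum <- function(model, grid) {
  base <- model$shade_factor * plateau_profile(model, grid) *
    absorption_factor(model, grid)
  if (any(base <= 0 | base >= 1))
    stop("component model drives reflectance outside (0, 1)", call. = FALSE)
  v <- base
  if (model$amplitude_sd > 0)
    v <- v * exp(stats::rnorm(1, 0, model$amplitude_sd))
  if (model$tilt_sd > 0)
    v <- v * pmax(1 + stats::rnorm(1, 0, model$tilt_sd) *
                    (grid - 450) / 450, 0.05)
  if (model$pixel_noise_sd > 0)
    v <- v * exp(stats::rnorm(length(grid), 0, model$pixel_noise_sd))
  v <- pmin(v, 1 - 1e-6)
  Spectrum(grid, v)
}

# Stage-level leaf chlorophyll trajectory (micrograms/cm^2): rises to a peak
# at heading with a local dip at jointing.
STAGE_LCC <- c(ET = 38, FT = 42, JT = 39.5, BT = 44, HD = 47, FL = 43)

# Stage-level leaf NIR plateau for leaves (rise to heading then fall) and the
# approximately stage-constant panicle plateau.
STAGE_LEAF_NIR <- c(ET = 0.38, FT = 0.42, JT = 0.45, BT = 0.49, HD = 0.54,
                    FL = 0.47)
PANICLE_NIR <- 0.52

#' Default component models for a growth stage
#'
#' Encodes the qualitative contrasts the analysis relies on: sunlit amplitude
#' exceeds shaded amplitude at every band; panicle visible reflectance
#' exceeds leaf visible reflectance; shaded continuum-removed absorption is
#' deeper than sunlit; the leaf NIR plateau rises to heading then falls while
#' the panicle plateau is stage-constant; panicles are pigment-poor (much
#' shallower absorption depths) and carry a double blue absorption feature.
#'
#' @param stage One of `GROWTH_STAGES`.
#' @param lcc Leaf chlorophyll content (micrograms/cm^2) driving the
#'   chlorophyll-linked band depths; defaults to the stage trajectory.
#' @param sunlit_saturation Optional depth cap (on the 0-1 depth scale)
#'   through which sunlit chlorophyll-linked depths saturate,
#'   `d -> cap (1 - exp(-d/cap))`; `Inf` (the default) disables it.
#' @param noise_sd Per-band pixel noise SD for all four models.
#' @param amplitude_sd Per-pixel amplitude noise SD for all four models.
#' @return Named list of four [ComponentModel]s (`SL`, `SHL`, `SP`, `SHP`).
#' @export
default_component_models <- function(stage, lcc = NULL,
                                     sunlit_saturation = Inf,
                                     noise_sd = 0.02, amplitude_sd = 0.05,
                                     tilt_sd = 0.08) {
  stage <- match.arg(stage, GROWTH_STAGES)
  if (is.null(lcc)) lcc <- STAGE_LCC[[stage]]
  rel <- lcc / 42  # chlorophyll-linked scaling, 1 at the season mean
  rel_leaf <- rel^0.7   # leaf absorption responds sublinearly (saturating)
  rel_pan <- 1 + 0.3 * (rel - 1)  # panicles are pigment-poor: weak coupling

  leaf_bands <- function(saturate) {
    d_blue <- 0.32                  # carotenoid + chlorophyll blue feature
    d_green <- min(0.28 * rel_leaf, 0.45)  # green-yellow chlorophyll shoulder
    d_red <- min(0.55 * rel_leaf, 0.75)    # red chlorophyll feature
    if (is.finite(saturate)) {
      d_green <- saturate * (1 - exp(-d_green / saturate))
      d_red <- saturate * (1 - exp(-d_red / saturate))
    }
    data.frame(center = c(460, 580, 668),
               width = c(35, 20, 28),
               depth = c(d_blue, d_green, d_red))
  }
  panicle_bands <- function(saturate) {
    d_red <- min(0.10 * rel_pan, 0.3)
    if (is.finite(saturate)) d_red <- saturate * (1 - exp(-d_red / saturate))
    data.frame(center = c(450, 492, 580, 668),
               width = c(13, 16, 20, 28),
               depth = c(0.32, 0.38, 0.05, d_red))
  }

  leaf_nir <- STAGE_LEAF_NIR[[stage]]
  list(
    SL = ComponentModel("SL", leaf_nir, 0.12, leaf_bands(sunlit_saturation),
                        1, 1, noise_sd, amplitude_sd, tilt_sd),
    SHL = ComponentModel("SHL", leaf_nir, 0.12, leaf_bands(Inf),
                         0.55, 1.18, noise_sd, amplitude_sd, tilt_sd),
    SP = ComponentModel("SP", PANICLE_NIR, 0.16,
                        panicle_bands(sunlit_saturation), 1, 1, noise_sd,
                        amplitude_sd, tilt_sd),
    SHP = ComponentModel("SHP", PANICLE_NIR, 0.16, panicle_bands(Inf),
                         0.65, 1.12, noise_sd, amplitude_sd, tilt_sd)
  )
}

#' Construct a SceneConfig
#'
#' @param rows,cols Scene size in pixels.
#' @param stage One of `GROWTH_STAGES`.
#' @param class_fractions Named areal fractions over `SL`, `SHL`, `SP`,
#'   `SHP`, `NONVEG`; non-negative, summing to 1. `NULL` uses the
#'   stage-dependent defaults (open canopy at early tillering with more
#'   sunlit than shaded foliage; closed canopy afterwards where shaded
#'   foliage dominates).
#' @param wl_start,wl_stop,wl_step Wavelength grid spec in nm; the default
#'   mirrors a 2.8 nm visible/NIR sensor after subsetting to 400-900 nm.
#' @param seed Integer RNG seed.
#' @return An object of class `"SceneConfig"`.
#' @export
SceneConfig <- function(rows = 50, cols = 50, stage = "HD",
                        class_fractions = NULL, wl_start = 400,
                        wl_stop = 900, wl_step = 2.8, seed = 1L) {
  stage <- match.arg(stage, GROWTH_STAGES)
  if (is.null(class_fractions)) {
    class_fractions <- if (stage == "ET")
      c(SL = 0.36, SHL = 0.22, SP = 0.05, SHP = 0.04, NONVEG = 0.33)
    else
      c(SL = 0.18, SHL = 0.42, SP = 0.10, SHP = 0.12, NONVEG = 0.18)
  }
  need <- c(COMPONENT_CLASSES, "NONVEG")
  if (!all(names(class_fractions) %in% need))
    stop("class_fractions names must be among SL, SHL, SP, SHP, NONVEG",
         call. = FALSE)
  if (any(class_fractions < 0) || abs(sum(class_fractions) - 1) > 1e-8)
    stop("class_fractions must be non-negative and sum to 1", call. = FALSE)
  if (wl_start > 400 || wl_stop < 900)
    stop("wavelength span must cover [400, 900] nm", call. = FALSE)
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 stage = stage, class_fractions = class_fractions,
                 wavelengths = seq(wl_start, wl_stop, by = wl_step),
                 seed = as.integer(seed)),
            class = "SceneConfig")
}

# Dull soil/water background: flat, low reflectance, EVI well below 0.45.
nonveg_base <- function(grid) {
  0.08 + 5e-5 * (grid - 400)
}

#' Generate a labelled synthetic scene
#'
#' Each pixel is assigned a class by sampling the areal fractions, then given
#' a spectrum drawn from its class model (or the flat soil background for
#' `NONVEG`). The truth labels are returned alongside the cube.
#'
#' @param config A [SceneConfig].
#' @param models Named list of [ComponentModel]s as from
#'   [default_component_models()]; defaults to the config's stage models.
#' @return List with elements `cube` (a reflectance [HyperCube]) and
#'   `labels` (a [LabelMap] over `SL`, `SHL`, `SP`, `SHP`, `NONVEG`).
#' @export
generate_scene <- function(config, models = NULL) {
  stopifnot(inherits(config, "SceneConfig"))
  if (is.null(models)) models <- default_component_models(config$stage)
  set.seed(config$seed)
  generate_scene_impl(config, models)
}

# Scene generation using the current RNG state (so a season draws many
# scenes from one seeded stream).
generate_scene_impl <- function(config, models) {
  grid <- config$wavelengths
  npx <- config$rows * config$cols
  nb <- length(grid)
  fr <- config$class_fractions
  classes <- sample(names(fr), npx, replace = TRUE, prob = fr)
  mat <- matrix(0, npx, nb)
  for (cl in unique(classes)) {
    idx <- which(classes == cl)
    base <- if (cl == "NONVEG") nonveg_base(grid)
            else {
              m <- models[[cl]]
              m$shade_factor * plateau_profile(m, grid) *
                absorption_factor(m, grid)
            }
    if (any(base <= 0 | base >= 1))
      stop("component model drives reflectance outside (0, 1)",
           call. = FALSE)
    sd <- if (cl == "NONVEG") 0.02 else models[[cl]]$pixel_noise_sd
    amp_sd <- if (cl == "NONVEG") 0.08 else models[[cl]]$amplitude_sd
    tilt_sd <- if (cl == "NONVEG") 0 else models[[cl]]$tilt_sd
    amp <- exp(stats::rnorm(length(idx), 0, amp_sd))
    tilt <- stats::rnorm(length(idx), 0, tilt_sd)
    slope <- pmax(1 + outer(tilt, (grid - 450) / 450), 0.05)
    noise <- exp(matrix(stats::rnorm(length(idx) * nb, 0, sd),
                        length(idx), nb))
    mat[idx, ] <- pmin(sweep(noise * amp * slope, 2, base, "*"), 1 - 1e-6)
  }
  code_table <- stats::setNames(seq_along(c(COMPONENT_CLASSES, "NONVEG")),
                                c(COMPONENT_CLASSES, "NONVEG"))
  lab <- matrix(code_table[classes], config$rows, config$cols, byrow = TRUE)
  list(cube = HyperCube(matrix_cube(mat, config$rows, config$cols), grid,
                        "reflectance",
                        metadata = list(stage = config$stage)),
       labels = LabelMap(lab, code_table))
}

# Stage-level leaf area index trajectory (m^2/m^2), peaking at booting so
# that canopy chlorophyll (LCC x LAI) peaks there while LCC peaks at heading.
STAGE_LAI <- c(ET = 0.6, FT = 1.8, JT = 3.2, BT = 6.2, HD = 4.9, FL = 4.0)
NRATE_LCC_EFFECT <- c(N0 = -6, N100 = -2, N200 = 0, N300 = 2.5)
NRATE_LAI_FACTOR <- c(N0 = 0.80, N100 = 0.95, N200 = 1.05, N300 = 1.15)

#' Generate a synthetic growing season
#'
#' For each plot and each of the six growth stages, draws plot-level
#' agronomic truth (SPAD readings, leaf and canopy chlorophyll, LAI) and a
#' labelled scene whose chlorophyll-linked absorption depths are tied to the
#' plot's realised leaf chlorophyll, so that index-to-chlorophyll regressions
#' are recoverable from the imagery. Leaf chlorophyll rises to a peak at
#' heading with a local dip at jointing; canopy chlorophyll peaks at booting.
#'
#' Sunlit components carry a scene-level illumination jitter that shaded
#' components do not: direct-beam irradiance varies between acquisitions with
#' sun angle and sky condition, so each scene's sunlit amplitude and apparent
#' absorption depths are perturbed by independent log-normal factors
#' (`sunlit_jitter_sd`). This makes index-to-chlorophyll coupling stronger
#' for shaded than for sunlit pixels, without changing their mean contrast.
#'
#' @param base_config A [SceneConfig] providing scene size and grid (its
#'   stage and seed are overridden per scene).
#' @param n_plots Number of plots (N-rate labels cycle over N0-N300).
#' @param seed Integer seed for the whole season.
#' @param sunlit_jitter_sd SD of the log-normal scene-level jitter applied
#'   to the amplitude and (independently) to the absorption depths of the
#'   sunlit classes; 0 disables the sunlit handicap.
#' @return List with `scenes` (list of `list(cube, labels, plot_id, stage)`)
#'   and `plots` (data frame of plot records: one row per plot x stage with
#'   SPAD readings, mean SPAD, LCC, LAI and CCC).
#' @export
generate_season <- function(base_config = SceneConfig(), n_plots = 4,
                            seed = 1L, sunlit_jitter_sd = 0.04) {
  stopifnot(n_plots >= 1)
  set.seed(seed)
  scenes <- list()
  recs <- list()
  k <- 0L
  for (p in seq_len(n_plots)) {
    nrate <- names(NRATE_LCC_EFFECT)[(p - 1L) %% 4L + 1L]
    for (stage in GROWTH_STAGES) {
      k <- k + 1L
      lcc_true <- STAGE_LCC[[stage]] + NRATE_LCC_EFFECT[[nrate]] +
        stats::rnorm(1, 0, 0.4)
      spad_true <- (lcc_true + 22.014) / 1.4498
      leaf_offsets <- stats::rnorm(3, 0, 0.5)
      readings <- matrix(spad_true + rep(leaf_offsets, each = 3) +
                           stats::rnorm(9, 0, 0.3), 3, 3)
      spad <- plant_mean_spad(readings)
      lcc <- spad_to_lcc(spad)
      lai <- STAGE_LAI[[stage]] * NRATE_LAI_FACTOR[[nrate]] *
        exp(stats::rnorm(1, 0, 0.04))
      ccc <- canopy_chl(lcc, lai)
      models <- default_component_models(stage, lcc = lcc)
      amp_jit <- exp(stats::rnorm(1, 0, sunlit_jitter_sd))
      depth_jit <- exp(stats::rnorm(1, 0, sunlit_jitter_sd))
      for (cl in c("SL", "SP")) {
        models[[cl]]$vis_base <- models[[cl]]$vis_base * amp_jit
        models[[cl]]$nir_plateau <- min(models[[cl]]$nir_plateau * amp_jit,
                                        0.9)
        models[[cl]]$pigment_bands$depth <-
          pmin(models[[cl]]$pigment_bands$depth * depth_jit, 0.85)
      }
      cfg <- base_config
      cfg$stage <- stage
      cfg$class_fractions <- SceneConfig(rows = cfg$rows, cols = cfg$cols,
                                         stage = stage)$class_fractions
      sc <- generate_scene_impl(cfg, models)
      scenes[[k]] <- list(cube = sc$cube, labels = sc$labels,
                          plot_id = p, stage = stage)
      recs[[k]] <- data.frame(plot_id = p, stage = stage, n_rate = nrate,
                              t(stats::setNames(as.vector(readings),
                                                paste0("spad_r", 1:9))),
                              spad = spad, lcc = lcc, lai = lai, ccc = ccc)
    }
  }
  list(scenes = scenes, plots = do.call(rbind, recs))
}
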