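#' Convert a SPAD reading to leaf chlorophyll content
#'
#' Linear meter calibration `LCC = 1.4498 x SPAD - 22.014`, in
#' micrograms/cm^2.
#'
#' @param spad SPAD reading(s).
#' @return Leaf chlorophyll content (micrograms/cm^2).
#' @export
spad_to_lcc <- function(spad) {
  1.4498 * spad - 22.014
}

#' Plant-level mean SPAD from the 3 x 3 reading protocol
#'
#' Three readings per leaf (one near the blade midpoint, two 3 cm either
#' side) on the three uppermost fully expanded leaves: per-leaf means are
#' averaged, which for the balanced design equals the grand mean.
#'
#' @param readings 3 x 3 numeric matrix (leaves x readings) or a length-9
#'   vector.
#' @return Mean SPAD value for the plant.
#' @export
plant_mean_spad <- function(readings) {
  readings <- as.numeric(readings)
  if (length(readings) != 9L || anyNA(readings))
    stop("expected 9 finite SPAD readings (3 leaves x 3 readings)",
         call. = FALSE)
  mean(colMeans(matrix(readings, 3, 3)))
}

#' Canopy chlorophyll content
#'
#' CCC (g/m^2) = LCC (micrograms/cm^2) x LAI (m^2/m^2) x 0.01, the factor
#' converting micrograms/cm^2 to g/m^2.
#'
#' @param lcc Leaf chlorophyll content (micrograms/cm^2), >= 0.
#' @param lai Leaf area index (m^2/m^2), >= 0.
#' @return Canopy chlorophyll content (g/m^2).
#' @export
canopy_chl <- function(lcc, lai) {
  stopifnot(all(lcc >= 0), all(lai >= 0))
  lcc * lai * 0.01
}

#' Squared Spearman correlation
#'
#' Rank correlation with average ranks for ties; the squared coefficient is
#' reported alongside a two-sided p-value from the large-sample t
#' approximation `t = rho sqrt((n - 2) / (1 - rho^2))`.
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @return An object of class `"CorrelationResult"`: list with
#'   `spearman_rho`, `r2_spearman` (= rho^2), `p_value`, `n`.
#' @export
spearman_r2 <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("x and y must have equal length >= 3", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("correlation undefined: zero variance in ranks", call. = FALSE)
  rho <- stats::cor(rx, ry)
  n <- length(x)
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  structure(list(spearman_rho = rho, r2_spearman = rho^2, p_value = p,
                 n = n), class = "CorrelationResult")
}

#' @export
print.CorrelationResult <- function(x, ...) {
  cat(sprintf("Spearman rho = %.4f (R^2 = %.4f), p = %.3g, n = %d\n",
              x$spearman_rho, x$r2_spearman, x$p_value, x$n))
  invisible(x)
}

#' Paired t-test
#'
#' Classic paired t on the differences, two-sided. Pairs are scene x stage
#' means when comparing sunlit and shaded components over a season.
#'
#' @param a,b Paired numeric vectors, n >= 2.
#' @return List with `t` and `p_value`.
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2)
    stop("a and b must be paired with length >= 2", call. = FALSE)
  d <- a - b
  if (stats::sd(d) == 0) {
    if (all(d == 0)) return(list(t = 0, p_value = 1))
    stop("degenerate test: zero-variance non-zero differences",
         call. = FALSE)
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), p_value = ht$p.value)
}

#' Z-score normalisation
#'
#' `(v - mean) / sd` with the sample (n-1) standard deviation; the output
#' has mean 0 and sample SD 1.
#'
#' @param values Numeric vector, n >= 2, positive SD.
#' @return Normalised vector.
#' @export
zscore <- function(values) {
  if (length(values) < 2) stop("need n >= 2", call. = FALSE)
  s <- stats::sd(values)
  if (s == 0) stop("cannot z-score a constant vector", call. = FALSE)
  (values - mean(values)) / s
}

#' Linear least-squares fit
#'
#' Ordinary least squares `y = c0 + c1 x` with the coefficient of
#' determination on the training data.
#'
#' @param x,y Numeric vectors, n >= 3.
#' @return An object of class `"RegressionResult"` with `model = "linear"`,
#'   `coefficients` (intercept, slope), `r2`, `n`.
#' @export
fit_linear <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need paired x, y with n >= 3", call. = FALSE)
  if (stats::sd(x) == 0) stop("zero variance in x", call. = FALSE)
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(model = "linear",
                 coefficients = c(intercept = unname(stats::coef(fit)[1]),
                                  slope = unname(stats::coef(fit)[2])),
                 r2 = 1 - ss_res / ss_tot, n = length(x)),
            class = "RegressionResult")
}

#' Exponential fit y = a exp(b x)
#'
#' Nonlinear least squares initialised from the log-linear fit of `ln y` on
#' `x`; the coefficient of determination is computed on the original scale.
#' `x` may be negative (z-scored predictors are expected); `y` must be
#' positive for the initialisation.
#'
#' @param x,y Numeric vectors, n >= 3, `y > 0`.
#' @return An object of class `"RegressionResult"` with
#'   `model = "exponential"`, `coefficients` (a, b), `r2`, `n`.
#' @export
fit_exponential <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need paired x, y with n >= 3", call. = FALSE)
  if (any(y <= 0)) stop("y must be positive for the exponential fit",
                        call. = FALSE)
  init <- stats::lm(log(y) ~ x)
  a0 <- exp(unname(stats::coef(init)[1])); b0 <- unname(stats::coef(init)[2])
  fit <- tryCatch(
    stats::nls(y ~ a * exp(b * x), start = list(a = a0, b = b0),
               control = stats::nls.control(maxiter = 200,
                                            warnOnly = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # fall back to the log-linear solution (exact when noise is log-normal,
    # and always a valid exponential curve)
    coefs <- c(a = a0, b = b0)
    pred <- a0 * exp(b0 * x)
  } else {
    coefs <- stats::coef(fit)
    pred <- stats::predict(fit)
  }
  ss_res <- sum((y - pred)^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(model = "exponential",
                 coefficients = c(a = unname(coefs["a"]),
                                  b = unname(coefs["b"])),
                 r2 = 1 - ss_res / ss_tot, n = length(x)),
            class = "RegressionResult")
}

#' @export
print.RegressionResult <- function(x, ...) {
  eq <- if (x$model == "linear")
    sprintf("y = %.4g + %.4g x", x$coefficients[1], x$coefficients[2])
  else
    sprintf("y = %.4g exp(%.4g x)", x$coefficients[1], x$coefficients[2])
  cat(sprintf("%s fit: %s, R^2 = %.4f, n = %d\n", x$model, eq, x$r2, x$n))
  invisible(x)
}

#' @export
coef.RegressionResult <- function(object, ...) object$coefficients

#' @export
predict.RegressionResult <- function(object, newdata, ...) {
  x <- if (is.list(newdata)) newdata$x else newdata
  cf <- object$coefficients
  if (object$model == "linear") cf[1] + cf[2] * x else cf[1] * exp(cf[2] * x)
}

#' Sunlit / shaded / combined regression comparison
#'
#' For each vegetation index: per-scene mean index over sunlit-leaf pixels
#' and over shaded-leaf pixels are regressed against the scene's canopy
#' chlorophyll, for the SL group, the SHL group and the pooled ("Combined")
#' data, with linear and exponential model forms. Indices are z-scored
#' within each group before fitting (the combined fit pools the two groups'
#' z-scores), which removes systematic between-group offsets; because
#' exponential fits need positive responses, the z-scored index is shifted
#' by a constant (min + 1) before fitting, identically in every group.
#'
#' @param scene_vi Data frame with one row per scene x class: columns
#'   `scene`, `class` (`"SL"` or `"SHL"`), `ccc`, and one column per index
#'   (e.g. `ndvi`, `tcari`, `pri`, `cire`).
#' @param indices Character vector of index column names to analyse.
#' @param normalize Z-score each group's index values before fitting
#'   (default `TRUE`).
#' @return Data frame with columns `vi`, `group` (SL/SHL/Combined), `model`
#'   (linear/exponential), `r2`, `n`.
#' @export
compare_groups <- function(scene_vi,
                           indices = c("ndvi", "tcari", "pri", "cire"),
                           normalize = TRUE) {
  stopifnot(all(c("scene", "class", "ccc") %in% names(scene_vi)))
  if (!all(indices %in% names(scene_vi)))
    stop("missing index column(s): ",
         paste(setdiff(indices, names(scene_vi)), collapse = ", "),
         call. = FALSE)
  sl <- scene_vi[scene_vi$class == "SL", ]
  shl <- scene_vi[scene_vi$class == "SHL", ]
  if (!nrow(sl) || !nrow(shl))
    stop("need both SL and SHL rows", call. = FALSE)
  out <- list()
  for (vi in indices) {
    ysl <- sl[[vi]]; yshl <- shl[[vi]]
    if (normalize) { ysl <- zscore(ysl); yshl <- zscore(yshl) }
    groups <- list(SL = list(x = sl$ccc, y = ysl),
                   SHL = list(x = shl$ccc, y = yshl),
                   Combined = list(x = c(sl$ccc, shl$ccc),
                                   y = c(ysl, yshl)))
    shift <- 1 - min(c(ysl, yshl))  # same shift in every group
    for (g in names(groups)) {
      x <- groups[[g]]$x; y <- groups[[g]]$y
      lin <- fit_linear(x, y)
      expf <- fit_exponential(x, y + shift)
      out[[length(out) + 1L]] <- data.frame(
        vi = vi, group = g,
        model = c("linear", "exponential"),
        r2 = c(lin$r2, expf$r2), n = length(x))
    }
  }
  do.call(rbind, out)
}

#' Per-scene class-mean vegetation indices
#'
#' Builds the regression input for [compare_groups()]: for every scene, the
#' mean NDVI, TCARI, PRI and red-edge chlorophyll index over the truth (or
#' classified) pixels of each requested class, joined with the scene's
#' canopy chlorophyll.
#'
#' @param season A season as returned by [generate_season()].
#' @param classes Classes to summarise (default SL and SHL).
#' @param labels `"truth"` to use the generator's label maps, or a list of
#'   [LabelMap]s (e.g. from [classify_image()]) parallel to
#'   `season$scenes`.
#' @return Data frame with columns `scene`, `plot_id`, `stage`, `class`,
#'   `ccc`, `ndvi`, `tcari`, `pri`, `cire`.
#' @export
season_class_vi <- function(season, classes = c("SL", "SHL"),
                            labels = "truth") {
  out <- list()
  for (i in seq_along(season$scenes)) {
    sc <- season$scenes[[i]]
    lab <- if (identical(labels, "truth")) sc$labels else labels[[i]]
    nm <- label_names(lab)
    rec <- season$plots[season$plots$plot_id == sc$plot_id &
                          season$plots$stage == sc$stage, ]
    maps <- lapply(c(ndvi = "ndvi", tcari = "tcari", pri = "pri",
                     cire = "cire"),
                   function(v) vi_image(sc$cube, v))
    for (cl in classes) {
      sel <- nm == cl
      if (!any(sel)) next
      out[[length(out) + 1L]] <- data.frame(
        scene = i, plot_id = sc$plot_id, stage = sc$stage, class = cl,
        ccc = rec$ccc,
        ndvi = mean(maps$ndvi[sel], na.rm = TRUE),
        tcari = mean(maps$tcari[sel], na.rm = TRUE),
        pri = mean(maps$pri[sel], na.rm = TRUE),
        cire = mean(maps$cire[sel], na.rm = TRUE))
    }
  }
  do.call(rbind, out)
}
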