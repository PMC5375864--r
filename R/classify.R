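#' Spectral angle mapper
#'
#' The angle between two spectra viewed as vectors:
#' `acos(<x, y> / (|x| |y|))`, in radians within `[0, pi]`. Invariant to
#' positive scaling of either argument, so amplitude (shading) is invisible
#' to it.
#'
#' @param x,y [Spectrum] objects on the same grid, or bare numeric vectors.
#' @return Angle in radians.
#' @export
sam <- function(x, y) {
  xv <- spectrum_values(x); yv <- spectrum_values(y)
  if (length(xv) != length(yv))
    stop("spectra must share one grid", call. = FALSE)
  nx <- sqrt(sum(xv^2)); ny <- sqrt(sum(yv^2))
  if (nx == 0 || ny == 0)
    stop("spectral angle undefined for a zero spectrum", call. = FALSE)
  acos(min(1, max(-1, sum(xv * yv) / (nx * ny))))
}

#' Spectral information divergence
#'
#' Each spectrum is normalised to a probability vector (divided by its sum)
#' and the symmetrised relative entropy `D(p||q) + D(q||p)` is returned
#' (natural logarithm). Values at or below zero are floored to 1e-6 before
#' normalisation so calibration zeros do not break the entropy.
#'
#' @param x,y [Spectrum] objects on the same grid, or bare numeric vectors.
#' @return Non-negative divergence; 0 iff the normalised spectra coincide.
#' @export
sid <- function(x, y) {
  xv <- spectrum_values(x); yv <- spectrum_values(y)
  if (length(xv) != length(yv))
    stop("spectra must share one grid", call. = FALSE)
  xv <- pmax(xv, 1e-6); yv <- pmax(yv, 1e-6)
  p <- xv / sum(xv); q <- yv / sum(yv)
  sum(p * log(p / q)) + sum(q * log(q / p))
}

spectrum_values <- function(x) {
  if (inherits(x, "Spectrum")) x$value else as.numeric(x)
}

match_space_values <- function(s, space) {
  switch(space,
         reflectance = spectrum_values(s),
         continuum_removed = cr_concat_values(s))
}

#' Classify a spectrum by matching against class mean spectra
#'
#' Assigns the class whose reference (mean) spectrum minimises the chosen
#' metric, either on raw reflectance or on the concatenated blue+red
#' continuum-removed segments. Ties break by the fixed class order SL, SHL,
#' SP, SHP.
#'
#' @param s A [Spectrum].
#' @param references Named list of reference [Spectrum]s, one per class.
#' @param metric `"sam"` or `"sid"`.
#' @param space `"reflectance"` or `"continuum_removed"`.
#' @return The winning class name.
#' @export
match_classify <- function(s, references, metric = c("sam", "sid"),
                           space = c("reflectance", "continuum_removed")) {
  metric <- match.arg(metric); space <- match.arg(space)
  if (!length(references)) stop("no reference spectra", call. = FALSE)
  f <- if (metric == "sam") sam else sid
  sv <- match_space_values(s, space)
  ord <- intersect(COMPONENT_CLASSES, names(references))
  d <- vapply(ord, function(cl) {
    f(sv, match_space_values(references[[cl]], space))
  }, numeric(1))
  ord[which.min(d)]
}

#' Class-by-class mean distance table
#'
#' Entry (i, j) is the mean metric value between every library spectrum of
#' class i and the mean spectrum of class j (so the table is not symmetric
#' in general). Small diagonals and large off-diagonals indicate separable
#' classes.
#'
#' @param library A [SpectralLibrary].
#' @param metric `"sam"` or `"sid"`.
#' @param space `"reflectance"` or `"continuum_removed"`.
#' @return Numeric class x class matrix in the order SL, SHL, SP, SHP
#'   (restricted to classes present).
#' @export
class_distance_table <- function(library, metric = c("sam", "sid"),
                                 space = c("reflectance",
                                           "continuum_removed")) {
  metric <- match.arg(metric); space <- match.arg(space)
  f <- if (metric == "sam") sam else sid
  classes <- intersect(COMPONENT_CLASSES, unique(library$class))
  refs <- lapply(classes, function(cl)
    match_space_values(class_mean_spectrum(library, cl), space))
  names(refs) <- classes
  out <- matrix(NA_real_, length(classes), length(classes),
                dimnames = list(truth = classes, reference = classes))
  for (ci in classes) {
    rows <- which(library$class == ci)
    vals <- lapply(rows, function(r)
      match_space_values(library_spectrum(library, r), space))
    for (cj in classes) {
      out[ci, cj] <- mean(vapply(vals, f, numeric(1), y = refs[[cj]]))
    }
  }
  out
}

#' Derive decision-tree thresholds from labelled index values
#'
#' The tree first separates leaves from panicles on PRI, then sunlit from
#' shaded within each branch on TCARI. Each split is the midpoint of the two
#' group means; class means are computed by first averaging within each
#' growth stage and then averaging the stage means, so every stage carries
#' equal weight over the season (`stage_weighting = "pooled"` averages all
#' samples directly instead).
#'
#' @param vi_samples Data frame with columns `class`, `stage`, `pri`,
#'   `tcari`; all four component classes must be present.
#' @param stage_weighting `"stage_means"` (default) or `"pooled"`.
#' @return An object of class `"Thresholds"`: list with `pri_split`,
#'   `tcari_leaf_split`, `tcari_panicle_split`.
#' @export
derive_thresholds <- function(vi_samples,
                              stage_weighting = c("stage_means", "pooled")) {
  stage_weighting <- match.arg(stage_weighting)
  need <- c("class", "stage", "pri", "tcari")
  if (!all(need %in% names(vi_samples)))
    stop("vi_samples needs columns class, stage, pri, tcari", call. = FALSE)
  missing <- setdiff(COMPONENT_CLASSES, unique(vi_samples$class))
  if (length(missing))
    stop("missing class(es) in vi_samples: ",
         paste(missing, collapse = ", "), call. = FALSE)
  class_mean <- function(cl, var) {
    rows <- vi_samples[vi_samples$class == cl, ]
    if (stage_weighting == "pooled") return(mean(rows[[var]]))
    mean(tapply(rows[[var]], rows$stage, mean))
  }
  leaf_pri <- mean(c(class_mean("SL", "pri"), class_mean("SHL", "pri")))
  pan_pri <- mean(c(class_mean("SP", "pri"), class_mean("SHP", "pri")))
  structure(list(
    pri_split = (leaf_pri + pan_pri) / 2,
    tcari_leaf_split = (class_mean("SL", "tcari") +
                          class_mean("SHL", "tcari")) / 2,
    tcari_panicle_split = (class_mean("SP", "tcari") +
                             class_mean("SHP", "tcari")) / 2),
    class = "Thresholds")
}

#' @export
print.Thresholds <- function(x, ...) {
  cat(sprintf(
    "Decision-tree thresholds:\n  PRI leaf/panicle split: %.4f\n  TCARI SL/SHL split: %.4f\n  TCARI SP/SHP split: %.4f\n",
    x$pri_split, x$tcari_leaf_split, x$tcari_panicle_split))
  invisible(x)
}

#' Decision-tree classification of one pixel
#'
#' Leaves have higher PRI than panicles; sunlit components have higher TCARI
#' than their shaded counterparts. Boundary equality goes to the
#' leaf/sunlit branch.
#'
#' @param pri_value,tcari_value Index values for the pixel.
#' @param thresholds A `Thresholds` object from [derive_thresholds()].
#' @return One of `"SL"`, `"SHL"`, `"SP"`, `"SHP"`.
#' @export
decision_tree_classify <- function(pri_value, tcari_value, thresholds) {
  if (pri_value >= thresholds$pri_split) {
    if (tcari_value >= thresholds$tcari_leaf_split) "SL" else "SHL"
  } else {
    if (tcari_value >= thresholds$tcari_panicle_split) "SP" else "SHP"
  }
}

#' Decision-tree classification of a whole cube
#'
#' Computes per-pixel PRI and TCARI and applies the decision tree. Pixels
#' outside the vegetation mask become `NONVEG`; pixels where either index is
#' undefined become `UNLABELED`.
#'
#' @param cube A reflectance [HyperCube].
#' @param thresholds A `Thresholds` object.
#' @param veg_mask Logical matrix (rows x cols), e.g. from [evi_mask()];
#'   `NULL` treats every pixel as vegetation.
#' @return A [LabelMap].
#' @export
classify_image <- function(cube, thresholds, veg_mask = NULL) {
  p <- vi_image(cube, "pri", veg_mask)
  t <- vi_image(cube, "tcari", veg_mask)
  d <- dim(cube$data)
  out <- matrix(6L, d[1], d[2])  # UNLABELED
  leaf <- !is.na(p) & !is.na(t) & p >= thresholds$pri_split
  pan <- !is.na(p) & !is.na(t) & p < thresholds$pri_split
  out[leaf & t >= thresholds$tcari_leaf_split] <- 1L  # SL
  out[leaf & t < thresholds$tcari_leaf_split] <- 2L   # SHL
  out[pan & t >= thresholds$tcari_panicle_split] <- 3L  # SP
  out[pan & t < thresholds$tcari_panicle_split] <- 4L   # SHP
  if (!is.null(veg_mask)) out[!veg_mask] <- 5L  # NONVEG
  LabelMap(out, c(SL = 1L, SHL = 2L, SP = 3L, SHP = 4L, NONVEG = 5L,
                  UNLABELED = 6L))
}

#' Stratified k-fold cross-validation of the decision tree
#'
#' Samples are split into stratified folds (per class, using the seeded
#' generator); in each fold the thresholds are re-derived on the training
#' samples and the held-out samples are classified. Confusion counts are
#' pooled over folds.
#'
#' @param vi_samples Data frame with columns `class`, `stage`, `pri`,
#'   `tcari`.
#' @param folds Fold count (default 10); every class needs at least `folds`
#'   samples.
#' @param seed Integer seed for fold assignment.
#' @return List with `confusion` (4 x 4 integer matrix, rows = truth in the
#'   order SL, SHL, SP, SHP) and `accuracy` (trace / total).
#' @export
cross_validate <- function(vi_samples, folds = 10, seed = 1L) {
  if (folds < 2) stop("folds must be >= 2", call. = FALSE)
  n <- nrow(vi_samples)
  counts <- table(factor(vi_samples$class, COMPONENT_CLASSES))
  if (any(counts < folds))
    stop("every class needs at least `folds` samples for stratification",
         call. = FALSE)
  set.seed(seed)
  fold <- integer(n)
  for (cl in COMPONENT_CLASSES) {
    idx <- which(vi_samples$class == cl)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  conf <- matrix(0L, 4, 4, dimnames = list(truth = COMPONENT_CLASSES,
                                           predicted = COMPONENT_CLASSES))
  for (f in seq_len(folds)) {
    train <- vi_samples[fold != f, ]
    test <- vi_samples[fold == f, ]
    th <- derive_thresholds(train)
    pred <- mapply(decision_tree_classify, test$pri, test$tcari,
                   MoreArgs = list(thresholds = th))
    tab <- table(factor(test$class, COMPONENT_CLASSES),
                 factor(pred, COMPONENT_CLASSES))
    conf <- conf + tab
  }
  list(confusion = conf, accuracy = sum(diag(conf)) / sum(conf))
}

#' Sunlit-to-shaded leaf pixel ratio
#'
#' `count(SL) / count(SHL)` in a classified map; background and panicle
#' pixels do not enter. Returns `NA` when there are no shaded-leaf pixels.
#'
#' @param labels A [LabelMap].
#' @return Unitless ratio, or `NA_real_`.
#' @export
sunlit_shaded_ratio <- function(labels) {
  nm <- label_names(labels)
  n_sl <- sum(nm == "SL"); n_shl <- sum(nm == "SHL")
  if (n_shl == 0) return(NA_real_)
  n_sl / n_shl
}
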