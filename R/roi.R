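#' Build a spectral library from labelled scenes
#'
#' Samples up to `n_per_class` pixels of each canopy component class from
#' every scene (region-of-interest sampling against the truth or classified
#' labels) and assembles them into a [SpectralLibrary] tagged with each
#' scene's growth stage.
#'
#' @param scenes List of `list(cube, labels, stage)` entries (e.g.
#'   `season$scenes` from [generate_season()]).
#' @param n_per_class Pixels sampled per class per scene (default 20).
#' @param seed Integer seed for the pixel sampling.
#' @return A [SpectralLibrary].
#' @export
roi_library <- function(scenes, n_per_class = 20, seed = 1L) {
  set.seed(seed)
  wl <- scenes[[1]]$cube$wavelengths
  rows <- list(); cls <- character(0); stg <- character(0)
  for (sc in scenes) {
    nm <- label_names(sc$labels)
    m <- cube_matrix(sc$cube)
    nm_vec <- as.vector(t(nm))  # row-major, matching cube_matrix order
    for (cl in COMPONENT_CLASSES) {
      idx <- which(nm_vec == cl)
      if (!length(idx)) next
      take <- if (length(idx) > n_per_class)
        sample(idx, n_per_class) else idx
      rows[[length(rows) + 1L]] <- m[take, , drop = FALSE]
      cls <- c(cls, rep(cl, length(take)))
      stg <- c(stg, rep(sc$stage, length(take)))
    }
  }
  SpectralLibrary(wl, do.call(rbind, rows), cls, stg)
}

#' Per-entry PRI and TCARI of a spectral library
#'
#' The labelled index samples that feed [derive_thresholds()] and
#' [cross_validate()].
#'
#' @param library A [SpectralLibrary].
#' @return Data frame with columns `class`, `stage`, `pri`, `tcari`.
#' @export
library_vi_table <- function(library) {
  n <- nrow(library$values)
  p <- numeric(n); t <- numeric(n)
  for (i in seq_len(n)) {
    s <- library_spectrum(library, i)
    p[i] <- pri(s)$value
    t[i] <- tcari(s)$value
  }
  data.frame(class = library$class, stage = library$stage, pri = p,
             tcari = t)
}

#' Classify every spectrum of a library by spectral matching
#'
#' Matches each library spectrum against season-pooled class mean reference
#' spectra with [match_classify()] and reports overall accuracy against the
#' library labels.
#'
#' @param library A [SpectralLibrary].
#' @param metric `"sam"` or `"sid"`.
#' @param space `"reflectance"` or `"continuum_removed"`.
#' @param per_stage Use per-stage reference means instead of season-pooled
#'   ones (default `FALSE`).
#' @return List with `predicted` (character vector), `confusion` (4 x 4
#'   matrix) and `accuracy`.
#' @export
match_classify_library <- function(library, metric = c("sam", "sid"),
                                   space = c("reflectance",
                                             "continuum_removed"),
                                   per_stage = FALSE) {
  metric <- match.arg(metric); space <- match.arg(space)
  classes <- intersect(COMPONENT_CLASSES, unique(library$class))
  make_refs <- function(stage) {
    refs <- lapply(classes, function(cl)
      class_mean_spectrum(library, cl, stage))
    names(refs) <- classes
    refs
  }
  pooled <- if (per_stage) NULL else make_refs(NULL)
  n <- nrow(library$values)
  pred <- character(n)
  ref_cache <- list()
  for (i in seq_len(n)) {
    refs <- if (per_stage) {
      st <- library$stage[i]
      if (is.null(ref_cache[[st]])) ref_cache[[st]] <- make_refs(st)
      ref_cache[[st]]
    } else pooled
    pred[i] <- match_classify(library_spectrum(library, i), refs, metric,
                              space)
  }
  conf <- table(factor(library$class, COMPONENT_CLASSES),
                factor(pred, COMPONENT_CLASSES))
  list(predicted = pred, confusion = conf,
       accuracy = sum(diag(conf)) / sum(conf))
}
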