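#' Read a spectral library from a delimited table
#'
#' One spectrum per row: a `class` column, a `stage` column, and one numeric
#' column per wavelength whose header is the band centre in nm. The grid is
#' taken from the numeric headers and sorted ascending.
#'
#' @param path CSV file path.
#' @return A [SpectralLibrary].
#' @export
read_spectral_library <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("class", "stage") %in% names(tab)))
    stop("spectral library table needs 'class' and 'stage' columns",
         call. = FALSE)
  wl_cols <- setdiff(names(tab), c("class", "stage"))
  wl <- suppressWarnings(as.numeric(wl_cols))
  if (anyNA(wl))
    stop("non-numeric wavelength column header(s): ",
         paste(wl_cols[is.na(wl)], collapse = ", "), call. = FALSE)
  o <- order(wl)
  vals <- as.matrix(tab[, wl_cols[o], drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric reflectance values", call. = FALSE)
  dimnames(vals) <- NULL
  bad <- setdiff(unique(tab$class), COMPONENT_CLASSES)
  if (length(bad))
    stop("unknown component class label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  SpectralLibrary(wl[o], vals, tab$class, tab$stage)
}

#' Write a spectral library to a delimited table
#'
#' @param library A [SpectralLibrary].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_spectral_library <- function(library, path) {
  stopifnot(inherits(library, "SpectralLibrary"))
  tab <- data.frame(class = library$class, stage = library$stage,
                    library$values, check.names = FALSE)
  names(tab)[-(1:2)] <- format(library$wavelength, digits = 15, trim = TRUE)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
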