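#' Read an ENVI-style hyperspectral cube
#'
#' Reads a header/binary pair as written by pushbroom instruments and by
#' [write_envi_cube()]. BSQ, BIL and BIP interleaves are accepted; bands are
#' returned in ascending wavelength order regardless of on-disk order.
#'
#' @param header_path Path to the `.hdr` text header. The binary payload is
#'   looked up by stripping the `.hdr` extension (or appending `.dat`).
#' @return A [HyperCube]. The units flag is taken from the `units` header key
#'   and defaults to `"dn"`.
#' @export
read_envi_cube <- function(header_path) {
  h <- parse_envi_header(header_path)
  need <- c("samples", "lines", "bands", "interleave", "data type")
  miss <- setdiff(need, names(h))
  if (length(miss))
    stop("ENVI header missing key(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(h[["wavelength"]]))
    stop("ENVI header has no wavelength list", call. = FALSE)
  cols <- as.integer(h[["samples"]]); rows <- as.integer(h[["lines"]])
  bands <- as.integer(h[["bands"]])
  wl <- as.numeric(h[["wavelength"]])
  if (anyNA(wl)) stop("non-numeric wavelength list", call. = FALSE)
  if (length(wl) != bands)
    stop("wavelength list length does not match band count", call. = FALSE)
  dtype <- as.integer(h[["data type"]])
  interleave <- tolower(h[["interleave"]])
  bin <- envi_binary_path(header_path)
  if (!file.exists(bin)) stop("ENVI payload not found: ", bin, call. = FALSE)
  bps <- switch(as.character(dtype), "4" = 4L, "12" = 2L, "3" = 4L,
                stop("unsupported ENVI data type: ", dtype, call. = FALSE))
  n <- rows * cols * bands
  if (file.size(bin) != n * bps)
    stop(sprintf("corrupt ENVI file: payload is %d bytes, header declares %d",
                 file.size(bin), n * bps), call. = FALSE)
  con <- file(bin, "rb"); on.exit(close(con))
  v <- switch(as.character(dtype),
    "4"  = readBin(con, "double", n, size = 4, endian = "little"),
    "12" = readBin(con, "integer", n, size = 2, signed = FALSE,
                   endian = "little"),
    "3"  = readBin(con, "integer", n, size = 4, endian = "little"))
  arr <- switch(interleave,
    bsq = aperm(array(v, c(cols, rows, bands)), c(2, 1, 3)),
    bil = aperm(array(v, c(cols, bands, rows)), c(3, 1, 2)),
    bip = aperm(array(v, c(bands, cols, rows)), c(3, 2, 1)),
    stop("unsupported interleave: ", interleave, call. = FALSE))
  if (is.unsorted(wl, strictly = TRUE)) {
    o <- order(wl)
    if (anyDuplicated(wl)) stop("duplicate wavelengths", call. = FALSE)
    wl <- wl[o]; arr <- arr[, , o, drop = FALSE]
  }
  units <- if (!is.null(h[["units"]]) &&
               tolower(h[["units"]]) == "reflectance") "reflectance" else "dn"
  meta <- h[setdiff(names(h), c(need, "wavelength", "units", "byte order",
                                "header offset", "file type"))]
  meta <- lapply(meta, paste, collapse = ", ")
  HyperCube(arr, wl, units, metadata = meta)
}

#' Write an ENVI-style hyperspectral cube
#'
#' Writes a BSQ header/binary pair: 32-bit little-endian floats for
#' reflectance cubes, 16-bit unsigned integers for DN cubes.
#'
#' @param cube A [HyperCube].
#' @param path Output path; `.hdr` is appended for the header and the payload
#'   is written at `path` itself.
#' @return Invisibly, the header path.
#' @export
write_envi_cube <- function(cube, path) {
  d <- dim(cube$data)
  dtype <- if (cube$units == "reflectance") 4L else 12L
  hdr <- c("ENVI",
           sprintf("samples = %d", d[2]),
           sprintf("lines = %d", d[1]),
           sprintf("bands = %d", d[3]),
           "header offset = 0",
           "file type = ENVI Standard",
           sprintf("data type = %d", dtype),
           "interleave = bsq",
           "byte order = 0",
           sprintf("units = %s", cube$units),
           sprintf("wavelength = { %s }",
                   paste(format(cube$wavelengths, digits = 15, trim = TRUE),
                         collapse = " , ")))
  for (k in names(cube$metadata))
    hdr <- c(hdr, sprintf("%s = %s", k, cube$metadata[[k]]))
  writeLines(hdr, paste0(path, ".hdr"))
  v <- as.vector(aperm(cube$data, c(2, 1, 3)))  # BSQ: samples fastest
  con <- file(path, "wb"); on.exit(close(con))
  if (dtype == 4L) {
    writeBin(v, con, size = 4, endian = "little")
  } else {
    vi <- as.integer(round(v))
    if (any(vi < 0 | vi > 65535))
      stop("DN values outside the 16-bit unsigned range", call. = FALSE)
    # writeBin has no unsigned 16-bit mode; map [32768,65535] to the
    # negative two's-complement range so the on-disk bytes are uint16.
    vi <- ifelse(vi > 32767L, vi - 65536L, vi)
    writeBin(vi, con, size = 2, endian = "little")
  }
  invisible(paste0(path, ".hdr"))
}

#' Write a classification map as an ENVI integer raster
#'
#' Single-band 32-bit integer raster; the code table is carried in the header
#' (`class names` / `class codes`) so the round trip through
#' [read_classification_map()] is lossless.
#'
#' @param labels A [LabelMap].
#' @param path Output path (header at `path.hdr`).
#' @return Invisibly, the header path.
#' @export
write_classification_map <- function(labels, path) {
  stopifnot(inherits(labels, "LabelMap"))
  d <- dim(labels$labels)
  hdr <- c("ENVI",
           sprintf("samples = %d", d[2]),
           sprintf("lines = %d", d[1]),
           "bands = 1",
           "header offset = 0",
           "file type = ENVI Classification",
           "data type = 3",
           "interleave = bsq",
           "byte order = 0",
           sprintf("classes = %d", length(labels$code_table)),
           sprintf("class names = { %s }",
                   paste(names(labels$code_table), collapse = " , ")),
           sprintf("class codes = { %s }",
                   paste(labels$code_table, collapse = " , ")))
  writeLines(hdr, paste0(path, ".hdr"))
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(as.integer(t(labels$labels)), con, size = 4, endian = "little")
  invisible(paste0(path, ".hdr"))
}

#' Read a classification map written by [write_classification_map()]
#'
#' @param header_path Path to the `.hdr` header.
#' @return A [LabelMap].
#' @export
read_classification_map <- function(header_path) {
  h <- parse_envi_header(header_path)
  cols <- as.integer(h[["samples"]]); rows <- as.integer(h[["lines"]])
  if (is.null(h[["class names"]]) || is.null(h[["class codes"]]))
    stop("classification header lacks class names/codes", call. = FALSE)
  bin <- envi_binary_path(header_path)
  con <- file(bin, "rb"); on.exit(close(con))
  v <- readBin(con, "integer", rows * cols, size = 4, endian = "little")
  LabelMap(matrix(v, rows, cols, byrow = TRUE),
           stats::setNames(as.integer(h[["class codes"]]), h[["class names"]]))
}

envi_binary_path <- function(header_path) {
  bin <- sub("\\.hdr$", "", header_path)
  if (identical(bin, header_path) || !file.exists(bin)) {
    alt <- paste0(bin, ".dat")
    if (file.exists(alt)) return(alt)
  }
  bin
}

# Parse "key = value" and "key = { multi-line list }" ENVI header entries.
parse_envi_header <- function(path) {
  if (!file.exists(path)) stop("header not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  out <- list(); i <- 1L
  while (i <= length(lines)) {
    ln <- lines[[i]]
    if (!grepl("=", ln, fixed = TRUE)) { i <- i + 1L; next }
    key <- tolower(trimws(sub("=.*", "", ln)))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (startsWith(val, "{")) {
      while (!grepl("}", val, fixed = TRUE) && i < length(lines)) {
        i <- i + 1L
        val <- paste(val, trimws(lines[[i]]))
      }
      val <- gsub("[{}]", "", val)
      items <- trimws(strsplit(val, ",")[[1]])
      out[[key]] <- items[nzchar(items)]
    } else {
      out[[key]] <- val
    }
    i <- i + 1L
  }
  out
}
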