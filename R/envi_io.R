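#' Write a cube as an ENVI header + binary pair
#'
#' Writes a plain-text `.hdr` header and a raw binary image file in BSQ
#' (band-sequential) interleave, 32-bit little-endian floats. Wavelengths are
#' stored in the header `wavelength` block so a round trip preserves the band
#' axis.
#'
#' @param cube a [ReflectanceCube-class] or raw H x W x B array
#' @param path output path without extension; writes `path` and `path.hdr`
#' @param wavelength band centres, required when `cube` is a bare array
#' @return invisibly, the data-file path
#' @export
writeENVI <- function(cube, path, wavelength = NULL) {
  if (is(cube, "ReflectanceCube")) {
    vals <- cube@values
    wavelength <- cube@wavelength
  } else {
    vals <- cube
    stopIfNot(!is.null(wavelength), "wavelength required for a bare array")
  }
  d <- dim(vals)
  hdr <- c("ENVI",
           "description = {msifusion export}",
           sprintf("samples = %d", d[2]),
           sprintf("lines = %d", d[1]),
           sprintf("bands = %d", d[3]),
           "header offset = 0",
           "file type = ENVI Standard",
           "data type = 4",
           "interleave = bsq",
           "byte order = 0",
           "wavelength units = Nanometers",
           paste0("wavelength = {", paste(sprintf("%.6f", wavelength),
                                          collapse = ", "), "}"))
  writeLines(hdr, paste0(path, ".hdr"))
  con <- file(path, "wb")
  on.exit(close(con))
  ## BSQ: band-major; within a band ENVI stores row-major (line by line)
  for (b in seq_len(d[3]))
    writeBin(as.numeric(t(vals[, , b])), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an ENVI header + binary pair
#'
#' Supports the subset of the format written by [writeENVI()]: BSQ
#' interleave, data type 4 (float32) or 12/2 (uint16/int16), byte order 0.
#'
#' @param path data-file path; the header is expected at `path.hdr`
#' @return a [ReflectanceCube-class] if the header carries wavelengths and the
#'   data are within reflectance range, otherwise a list with `values` and
#'   `wavelength`
#' @export
readENVI <- function(path) {
  hdrPath <- paste0(path, ".hdr")
  stopIfNot(file.exists(hdrPath), "missing header %s", hdrPath)
  hdr <- paste(readLines(hdrPath, warn = FALSE), collapse = "\n")
  getField <- function(name) {
    m <- regmatches(hdr, regexpr(sprintf("%s *= *[0-9]+", name), hdr))
    stopIfNot(length(m) == 1, "header field '%s' missing", name)
    as.integer(sub(".*= *", "", m))
  }
  ns <- getField("samples"); nl <- getField("lines"); nb <- getField("bands")
  dt <- getField("data type")
  inter <- regmatches(hdr, regexpr("interleave *= *[a-z]+", hdr))
  stopIfNot(grepl("bsq", inter), "only BSQ interleave is supported")
  wl <- regmatches(hdr, regexpr("wavelength *= *\\{[^}]*\\}", hdr))
  wavelength <- if (length(wl) == 1)
    as.numeric(strsplit(gsub(".*\\{|\\}", "", wl), ",")[[1]]) else NULL
  size <- switch(as.character(dt), "4" = 4L, "2" = 2L, "12" = 2L,
                 stop("unsupported ENVI data type ", dt, call. = FALSE))
  what <- if (dt == 4) "numeric" else "integer"
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- array(0, c(nl, ns, nb))
  for (b in seq_len(nb)) {
    plane <- readBin(con, what, n = ns * nl, size = size, endian = "little",
                     signed = dt != 12)
    vals[, , b] <- matrix(plane, nl, ns, byrow = TRUE)
  }
  if (!is.null(wavelength) && all(vals >= 0) && all(is.finite(vals)))
    reflectanceCube(vals, wavelength, provenance = list(source = path))
  else list(values = vals, wavelength = wavelength)
}

#' Write per-ROI mean spectra as CSV
#'
#' Columns: grain_id, raster_index, class (if given), band_1..band_B.
#'
#' @param spectra samples x bands matrix as returned by [extractMeanSpectra()]
#' @param path output CSV path
#' @param rois optional [GrainROISet-class] supplying raster indices
#' @param classes optional class labels, one per spectrum
#' @return invisibly, the path
#' @export
writeSpectraCSV <- function(spectra, path, rois = NULL, classes = NULL) {
  n <- nrow(spectra)
  df <- data.frame(grain_id = seq_len(n))
  df$raster_index <- if (!is.null(rois)) roiTable(rois)$rasterIndex
                     else seq_len(n)
  if (!is.null(classes)) df$class <- classes
  sp <- as.data.frame(spectra)
  names(sp) <- sprintf("band_%d", seq_len(ncol(spectra)))
  write.csv(cbind(df, sp), path, row.names = FALSE)
  invisible(path)
}
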