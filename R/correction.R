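#' Black/white reflectance correction
#'
#' Converts raw push-broom intensities to reflectance with the standard
#' two-reference normalisation
#' \deqn{R = (raw - dark) / (white - dark + \epsilon)}
#' applied per pixel and per band. The dark frame measures camera dark
#' current; the white frame measures the response over a reference whiteboard,
#' so the ratio cancels both dark current and uneven illumination. Negative
#' reflectances are clipped to 0; values above 1 (specular pixels) are kept.
#' Clip and reference-violation counts are recorded in the cube provenance.
#'
#' Reference frames may be full cubes (H x W x B), per-column line-scan
#' references (W x B, broadcast along the scan axis) or per-band vectors
#' (length B, broadcast over both spatial axes).
#'
#' @param raw H x W x B numeric array of raw intensities
#' @param white white-reference frame (H x W x B, W x B, or length B)
#' @param dark dark-current frame, same accepted shapes
#' @param wavelength band centres in nm, or a [WavelengthGrid-class]
#' @param epsilon denominator guard added to `white - dark`
#' @return a [ReflectanceCube-class]; provenance records `nClippedLow`,
#'   `nAboveOne`, `nWhiteBelowDark` and `epsilon`
#' @examples
#' raw <- array(130, c(4, 4, 3))
#' cube <- blackWhiteCorrect(raw, white = rep(230, 3), dark = rep(30, 3),
#'                           wavelength = c(900, 1000, 1100))
#' range(cubeValues(cube))  # 0.5
#' @export
blackWhiteCorrect <- function(raw, white, dark, wavelength,
                              epsilon = 1e-8) {
  d <- dim(raw)
  stopIfNot(length(d) == 3, "raw must be a 3-D array (H x W x B)")
  white <- broadcastReference(white, d, "white")
  dark <- broadcastReference(dark, d, "dark")
  denom <- white - dark
  nViol <- sum(denom < 0)
  ## an all-zero denominator plane means the band carries no reference signal
  planeDead <- vapply(seq_len(d[3]), function(b) all(denom[, , b] == 0),
                      logical(1))
  if (any(planeDead))
    stop(sprintf("white - dark is identically zero for band(s): %s",
                 paste(which(planeDead), collapse = ", ")), call. = FALSE)
  refl <- (raw - dark) / (denom + epsilon)
  nLow <- sum(refl < 0)
  nHigh <- sum(refl > 1)
  refl[refl < 0] <- 0
  reflectanceCube(refl, wavelength,
    provenance = list(correction = "black/white",
                      nClippedLow = nLow, nAboveOne = nHigh,
                      nWhiteBelowDark = nViol, epsilon = epsilon))
}

broadcastReference <- function(ref, d, what) {
  if (is.array(ref) && length(dim(ref)) == 3) {
    stopIfNot(all(dim(ref) == d), "%s frame shape mismatch", what)
    return(ref)
  }
  if (is.matrix(ref)) {
    stopIfNot(all(dim(ref) == d[2:3]),
              "%s per-column reference must be W x B", what)
    ## broadcast along the scan (row) axis
    return(aperm(array(ref, c(d[2], d[3], d[1])), c(3, 1, 2)))
  }
  if (is.numeric(ref) && is.null(dim(ref))) {
    if (length(ref) == 1) return(array(ref, d))
    stopIfNot(length(ref) == d[3],
              "%s per-band reference must have length B", what)
    return(aperm(array(ref, c(d[3], d[1], d[2])), c(2, 3, 1)))
  }
  stop(sprintf("unsupported %s reference shape", what), call. = FALSE)
}

#' Drop noisy head/tail bands
#'
#' Imager response is weak at both ends of the spectral range, so the first
#' and last bands have poor signal-to-noise. Dropping the first 9 and last 32
#' of a 512-band acquisition (the defaults) retains 471 effective bands.
#'
#' @param cube a [ReflectanceCube-class]
#' @param dropHead number of leading bands to drop
#' @param dropTail number of trailing bands to drop
#' @return a [ReflectanceCube-class] with the reduced band axis
#' @examples
#' cube <- reflectanceCube(array(0.5, c(2, 2, 512)), wavelengthGrid())
#' nBands(selectEffectiveBands(cube))  # 471
#' @export
selectEffectiveBands <- function(cube, dropHead = 9L, dropTail = 32L) {
  dropHead <- as.integer(dropHead); dropTail <- as.integer(dropTail)
  stopIfNot(dropHead >= 0 && dropTail >= 0, "drop counts must be >= 0")
  b <- nBands(cube)
  stopIfNot(dropHead + dropTail < b,
            "band screen (%d + %d) removes all %d bands",
            dropHead, dropTail, b)
  keep <- seq.int(dropHead + 1L, b - dropTail)
  prov <- cube@provenance
  prov$bandScreen <- c(dropHead = dropHead, dropTail = dropTail)
  reflectanceCube(cube@values[, , keep, drop = FALSE],
                  cube@wavelength[keep], prov)
}

#' Nearest band index for a target wavelength
#'
#' Maps a wavelength in nm to the index of the nearest band centre on an
#' evenly spaced grid. Ties (a target exactly between two centres) resolve to
#' the lower index. Indices are 1-based, consistent with R array indexing.
#'
#' @param grid a [WavelengthGrid-class], a [ReflectanceCube-class], or a
#'   numeric vector of band centres
#' @param nm target wavelength in nm
#' @return integer band index (1-based)
#' @examples
#' g <- wavelengthGrid()
#' bandIndexForWavelength(g, 954.15)  # 42 (0-based: 41)
#' @export
bandIndexForWavelength <- function(grid, nm) {
  wl <- if (is.numeric(grid)) grid else wavelengths(grid)
  stopIfNot(length(nm) == 1 && is.finite(nm), "nm must be a finite scalar")
  if (nm < min(wl) || nm > max(wl))
    stop(sprintf("wavelength %.2f nm outside grid range %.2f-%.2f nm",
                 nm, min(wl), max(wl)), call. = FALSE)
  dd <- abs(wl - nm)
  ## which.min already breaks ties toward the lower index
  as.integer(which.min(dd))
}
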