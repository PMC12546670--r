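#' Segmentation parameters for the grain ROI workflow
#'
#' Thresholds are on the 0--250 intensity scale: a coarse threshold (70)
#' plus optional polygon masking bound the effective region, then a fine
#' threshold (25) segments grains within it, followed by morphological
#' cleaning. `fineMethod = "otsu"` replaces the fixed fine threshold with
#' Otsu's method computed on the candidate region; both the fixed and the
#' Otsu value are then recorded in the result's attributes.
#'
#' @param coarseThreshold coarse intensity threshold (0--250)
#' @param fineThreshold fine intensity threshold (0--250)
#' @param polygonMask optional two-column (x, y) vertex matrix bounding the
#'   usable field; pixels outside the polygon are discarded
#' @param morphKernel odd diameter of the disc structuring element, pixels
#' @param minArea minimum connected-component area kept, pixels
#' @param nRows number of grain rows for raster ordering
#' @param fineMethod "fixed" (default) or "otsu"
#' @return a validated config list of class `SegmentationParams`
#' @export
segmentationParams <- function(coarseThreshold = 70, fineThreshold = 25,
                               polygonMask = NULL, morphKernel = 3L,
                               minArea = 80L, nRows = 5L,
                               fineMethod = c("fixed", "otsu")) {
  fineMethod <- match.arg(fineMethod)
  stopIfNot(fineThreshold > 0 && fineThreshold < coarseThreshold &&
            coarseThreshold <= 250,
            "need 0 < fineThreshold < coarseThreshold <= 250")
  stopIfNot(minArea >= 1, "minArea must be >= 1")
  stopIfNot(nRows >= 1, "nRows must be >= 1")
  structure(list(coarseThreshold = coarseThreshold,
                 fineThreshold = fineThreshold, polygonMask = polygonMask,
                 morphKernel = as.integer(morphKernel),
                 minArea = as.integer(minArea), nRows = as.integer(nRows),
                 fineMethod = fineMethod),
            class = "SegmentationParams")
}

#' Score image for thresholding
#'
#' Collapses a reflectance cube to a single 0--250 intensity plane: the mean
#' over a window of bands centred on `nm` (default: the false-colour R
#' channel band at 954.15 nm), scaled by 250 and clamped.
#'
#' @param cube a [ReflectanceCube-class]
#' @param nm centre wavelength of the band window, nm
#' @param window number of bands averaged (centred on the nearest band)
#' @return H x W numeric matrix in `[0, 250]`
#' @export
scoreImage <- function(cube, nm = 954.15, window = 1L) {
  b <- bandIndexForWavelength(cube, nm)
  half <- (as.integer(window) - 1L) %/% 2L
  idx <- max(1L, b - half):min(nBands(cube), b + half)
  plane <- apply(cube@values[, , idx, drop = FALSE], c(1, 2), mean)
  pmin(pmax(plane * 250, 0), 250)
}

#' Segment grains in a score image
#'
#' Coarse thresholding (plus optional polygon masking) marks bright grain
#' cores; a dilated envelope of those cores forms the candidate region, in
#' which the fine threshold recovers full grain extent. Morphological opening
#' removes isolated noise and closing plus hole filling completes grain
#' interiors.
#'
#' @param score H x W matrix on the 0--250 scale (see [scoreImage()])
#' @param params a [segmentationParams()]
#' @return logical H x W mask; when `fineMethod = "otsu"` the attribute
#'   `thresholds` records both the configured fixed and the computed Otsu
#'   fine threshold
#' @export
segmentGrains <- function(score, params = segmentationParams()) {
  stopIfNot(is.matrix(score), "score image must be a 2-D matrix")
  if (length(score) == 0 || all(score <= params$fineThreshold))
    return(matrix(FALSE, nrow(score), ncol(score)))
  coarse <- score > params$coarseThreshold
  if (!is.null(params$polygonMask))
    coarse <- coarse & pointsInPolygon(nrow(score), ncol(score),
                                       params$polygonMask)
  ## envelope of the bright cores: candidate region for fine segmentation
  brush <- EBImage::makeBrush(2L * params$morphKernel + 3L, "disc")
  candidate <- EBImage::dilate(ebi(coarse), brush) > 0.5

  fineThr <- params$fineThreshold
  otsuThr <- NA_real_
  if (params$fineMethod == "otsu" && any(candidate)) {
    otsuThr <- 250 * EBImage::otsu(ebi(score[candidate] / 250,
                                       asMatrix = TRUE), range = c(0, 1))
    fineThr <- otsuThr
  }
  mask <- candidate & (score > fineThr)

  kern <- EBImage::makeBrush(params$morphKernel, "disc")
  m <- EBImage::opening(ebi(mask), kern)
  m <- EBImage::closing(m, kern)
  m <- EBImage::fillHull(m)
  out <- matrix(as.numeric(m) > 0.5, nrow(score), ncol(score))
  attr(out, "thresholds") <- c(fixed = params$fineThreshold, otsu = otsuThr)
  out
}

## wrap a matrix as a grayscale EBImage Image
ebi <- function(m, asMatrix = FALSE) {
  if (asMatrix && !is.matrix(m)) m <- matrix(m, ncol = 1)
  EBImage::Image(m * 1.0)
}

## even-odd rule point-in-polygon, vectorised over the pixel grid
pointsInPolygon <- function(h, w, vertices) {
  stopIfNot(is.matrix(vertices) && ncol(vertices) == 2,
            "polygonMask must be a 2-column (x, y) matrix")
  px <- rep(seq_len(w), each = h)
  py <- rep(seq_len(h), w)
  n <- nrow(vertices)
  inside <- rep(FALSE, h * w)
  j <- n
  for (i in seq_len(n)) {
    xi <- vertices[i, 1]; yi <- vertices[i, 2]
    xj <- vertices[j, 1]; yj <- vertices[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi + 1e-300) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  matrix(inside, h, w)
}

#' Label connected components and filter small regions
#'
#' 8-connected component labelling of a binary mask; components smaller than
#' `minArea` pixels (isolated noise, dust specks) are dropped and survivors
#' are relabelled 1..N.
#'
#' @param mask logical H x W matrix
#' @param minArea minimum component area kept, pixels
#' @return a [GrainROISet-class] with `rasterIndex` unset (NA)
#' @export
labelAndFilter <- function(mask, minArea = 80L) {
  stopIfNot(is.matrix(mask), "mask must be a 2-D matrix")
  lab <- label8(mask)
  nLab <- max(lab)
  if (nLab == 0)
    return(new("GrainROISet",
               table = data.frame(label = integer(), centroidY = numeric(),
                                  centroidX = numeric(), area = integer(),
                                  rasterIndex = integer()),
               pixels = list()))
  areas <- tabulate(lab[lab > 0], nbins = nLab)
  keep <- which(areas >= minArea)
  pixels <- vector("list", length(keep))
  tb <- data.frame(label = seq_along(keep), centroidY = NA_real_,
                   centroidX = NA_real_, area = areas[keep],
                   rasterIndex = NA_integer_)
  for (i in seq_along(keep)) {
    idx <- which(lab == keep[i], arr.ind = TRUE)
    pixels[[i]] <- unname(idx)
    tb$centroidY[i] <- mean(idx[, 1])
    tb$centroidX[i] <- mean(idx[, 2])
  }
  new("GrainROISet", table = tb, pixels = pixels)
}

## 8-connected labelling: EBImage::bwlabel (4-connected) plus a union-find
## merge of diagonally adjacent labels
label8 <- function(mask) {
  lab <- matrix(as.integer(EBImage::bwlabel(ebi(mask))), nrow(mask))
  nLab <- max(lab)
  if (nLab <= 1) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-h, -w]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-1, -w]), as.vector(lab[-h, -1])))   # up-right
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(nLab)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (r in seq_len(nrow(pairs))) {
    a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(nLab), find, 0L)
  dense <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- dense[lab[lab > 0]]
  out
}

#' Assign raster order to ROIs
#'
#' Centroids are grouped into `nRows` rows by splitting the sorted Y
#' coordinates at the `nRows - 1` largest gaps (robust to row jitter), rows
#' are ordered top to bottom, and ROIs are sorted left to right within each
#' row. The returned set is reordered so that row i of the table is the ROI
#' with `rasterIndex` i.
#'
#' @param rois a [GrainROISet-class]
#' @param nRows number of rows in the physical layout
#' @return a [GrainROISet-class] with `rasterIndex` 1..N assigned
#' @export
orderROIs <- function(rois, nRows = 5L) {
  n <- nROIs(rois)
  stopIfNot(n >= 1, "no ROIs to order")
  stopIfNot(nRows <= n, "nRows (%d) exceeds the number of ROIs (%d)",
            nRows, n)
  tb <- roiTable(rois)
  ord <- order(tb$centroidY)
  rowId <- integer(n)
  if (nRows == 1L) {
    rowId[ord] <- 1L
  } else {
    gaps <- diff(tb$centroidY[ord])
    ## largest nRows-1 gaps split the rows; ties resolve to earlier gaps
    cutAfter <- sort(order(-gaps, seq_along(gaps))[seq_len(nRows - 1L)])
    grp <- cumsum(c(1L, as.integer(seq_len(n - 1L) %in% cutAfter)))
    rowId[ord] <- grp
  }
  finalOrd <- order(rowId, tb$centroidX)
  tb <- tb[finalOrd, , drop = FALSE]
  tb$rasterIndex <- seq_len(n)
  tb$label <- seq_len(n)
  rownames(tb) <- NULL
  new("GrainROISet", table = tb, pixels = roiPixels(rois)[finalOrd])
}

#' Extract per-ROI mean spectra
#'
#' For every ROI, averages the reflectance of its pixels in each band.
#'
#' @param cube a [ReflectanceCube-class]
#' @param rois a [GrainROISet-class]; if raster-ordered, spectra follow
#'   raster order (the set returned by [orderROIs()] already is)
#' @return nROIs x nBands matrix, one mean spectrum per row
#' @export
extractMeanSpectra <- function(cube, rois) {
  n <- nROIs(rois)
  stopIfNot(n >= 1, "no ROIs")
  d <- dim(cube@values)
  flat <- matrix(cube@values, d[1] * d[2], d[3])
  out <- matrix(NA_real_, n, d[3])
  px <- roiPixels(rois)
  for (i in seq_len(n)) {
    p <- px[[i]]
    stopIfNot(nrow(p) >= 1, "ROI %d is empty", i)
    stopIfNot(all(p[, 1] >= 1 & p[, 1] <= d[1] &
                  p[, 2] >= 1 & p[, 2] <= d[2]),
              "ROI %d has pixels outside the cube", i)
    idx <- (p[, 2] - 1L) * d[1] + p[, 1]
    out[i, ] <- colMeans(flat[idx, , drop = FALSE])
  }
  out
}

#' Render a false-colour RGB image from three bands
#'
#' Takes the nearest band planes to the requested R/G/B centre wavelengths
#' (954.15, 927.55 and 904.28 nm by default) and min-max scales each channel
#' independently to 0--255. A constant channel renders as mid-gray (128).
#'
#' @param cube a [ReflectanceCube-class]
#' @param rNm,gNm,bNm channel centre wavelengths, nm
#' @return H x W x 3 numeric array with values in `[0, 255]`; the attribute
#'   `bands` records the selected band indices
#' @export
renderFalseColorRGB <- function(cube, rNm = 954.15, gNm = 927.55,
                                bNm = 904.28) {
  idx <- c(bandIndexForWavelength(cube, rNm),
           bandIndexForWavelength(cube, gNm),
           bandIndexForWavelength(cube, bNm))
  d <- dim(cube@values)
  out <- array(0, c(d[1], d[2], 3))
  for (ch in 1:3) {
    plane <- cube@values[, , idx[ch]]
    rng <- range(plane)
    out[, , ch] <- if (rng[2] > rng[1])
      (plane - rng[1]) / (rng[2] - rng[1]) * 255 else 128
  }
  attr(out, "bands") <- idx
  out
}
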