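#' Configuration for the synthetic hypercube generator
#'
#' Lays grains out in a `gridRows x gridCols` matrix (5 x 5 by default, the
#' acquisition layout), each a disk of radius `grainRadiusPx` whose centre is
#' jittered by up to `rowJitterPx` pixels, plus `speckCount` sub-threshold
#' specks that the 80-pixel area filter must later reject. Raw intensities
#' are synthesised as `raw = dark + reflectance * (white - dark)`, so
#' black/white correction is exactly invertible on noiseless data. Grain and
#' background reflectance levels are chosen so the fixed 70/250 and 25/250
#' segmentation thresholds separate them by construction.
#'
#' @param gridRows,gridCols grain grid shape
#' @param grainRadiusPx grain disk radius, pixels
#' @param rowJitterPx maximum centre jitter in each axis, pixels
#' @param speckCount number of small specks to embed
#' @param speckAreaPx approximate speck area, pixels (must be < 80)
#' @param backgroundLevel background reflectance
#' @param cellPx grid cell pitch, pixels
#' @param marginPx empty border around the grid, pixels
#' @param seed integer seed
#' @return a validated config list of class `CubeSimConfig`
#' @export
cubeSimConfig <- function(gridRows = 5L, gridCols = 5L, grainRadiusPx = 7L,
                          rowJitterPx = 2L, speckCount = 3L,
                          speckAreaPx = 20L, backgroundLevel = 0.04,
                          cellPx = 20L, marginPx = 10L, seed = 1L) {
  stopIfNot(speckAreaPx < 80, "specks must stay below the 80-px area filter")
  ## adjacent centres are at least cellPx - 2*jitter apart; disks of radius r
  ## cannot touch when that spacing strictly exceeds the diameter
  stopIfNot(2 * grainRadiusPx < cellPx - 2 * rowJitterPx,
            "grains would overlap: need 2*radius < cellPx - 2*jitter")
  structure(list(gridRows = as.integer(gridRows),
                 gridCols = as.integer(gridCols),
                 grainRadiusPx = as.integer(grainRadiusPx),
                 rowJitterPx = as.integer(rowJitterPx),
                 speckCount = as.integer(speckCount),
                 speckAreaPx = as.integer(speckAreaPx),
                 backgroundLevel = backgroundLevel,
                 cellPx = as.integer(cellPx), marginPx = as.integer(marginPx),
                 seed = as.integer(seed)),
            class = "CubeSimConfig")
}

#' Generate a raw hypercube with reference frames and ground truth
#'
#' Each grid cell holds one grain carrying its class's spectral signature
#' (class mean plus per-pixel noise at the spectral config's `noiseSd`),
#' scaled into raw-intensity space against smooth white/dark reference
#' curves. Specks carry a grain-like signature so they pass intensity
#' thresholds and must be removed by the area filter.
#'
#' @param cfg a [cubeSimConfig()]
#' @param classes integer vector of class ids, one per grid cell in row-major
#'   order (length gridRows * gridCols)
#' @param spectralCfg a [spectralSimConfig()] supplying class signatures
#' @return list with `raw` (H x W x B array), `white` and `dark` (per-band
#'   reference vectors), `wavelength`, `truth` (data.frame: grainId,
#'   gridRow, gridCol, centroidY, centroidX, area, rasterIndex, class) and
#'   `masks` (list of logical H x W grain masks in raster order)
#' @examples
#' cfg <- cubeSimConfig()
#' sc <- spectralSimConfig(nBands = 64L, edgeHead = 2L, edgeTail = 4L,
#'                         nPerClass = 1L)
#' hc <- generateHypercube(cfg, rep(1:5, 5), sc)
#' nrow(hc$truth)  # 25
#' @export
generateHypercube <- function(cfg, classes, spectralCfg) {
  stopIfNot(inherits(cfg, "CubeSimConfig"), "cfg must be a CubeSimConfig")
  nCells <- cfg$gridRows * cfg$gridCols
  stopIfNot(length(classes) == nCells,
            "need one class per grid cell (%d)", nCells)
  stopIfNot(all(classes >= 1 & classes <= spectralCfg$nClasses),
            "class ids out of range")
  H <- 2L * cfg$marginPx + cfg$gridRows * cfg$cellPx
  W <- 2L * cfg$marginPx + cfg$gridCols * cfg$cellPx
  B <- spectralCfg$nBands
  means <- classMeanSpectra(spectralCfg)
  wl <- seq(spectralCfg$wavelengthStart, spectralCfg$wavelengthEnd,
            length.out = B)

  withSeed(childSeed(cfg$seed, 33), {
    refl <- array(cfg$backgroundLevel, c(H, W, B))
    yy <- matrix(seq_len(H), H, W)
    xx <- matrix(seq_len(W), H, W, byrow = TRUE)

    truth <- data.frame(grainId = integer(), gridRow = integer(),
                        gridCol = integer(), centroidY = numeric(),
                        centroidX = numeric(), area = integer(),
                        rasterIndex = integer(), class = integer())
    masks <- vector("list", nCells)
    occupied <- matrix(FALSE, H, W)
    k <- 0L
    for (gr in seq_len(cfg$gridRows)) for (gc in seq_len(cfg$gridCols)) {
      k <- k + 1L
      cy <- cfg$marginPx + (gr - 0.5) * cfg$cellPx +
        runif(1, -cfg$rowJitterPx, cfg$rowJitterPx)
      cx <- cfg$marginPx + (gc - 0.5) * cfg$cellPx +
        runif(1, -cfg$rowJitterPx, cfg$rowJitterPx)
      m <- (yy - cy)^2 + (xx - cx)^2 <= cfg$grainRadiusPx^2
      if (any(m & occupied)) stop("grain overlap after jitter", call. = FALSE)
      occupied <- occupied | m
      idx <- which(m)
      nPix <- length(idx)
      spec <- matrix(means[classes[k], ], nPix, B, byrow = TRUE)
      if (spectralCfg$noiseSd > 0)
        spec <- pmax(spec + matrix(rnorm(nPix * B, sd = spectralCfg$noiseSd),
                                   nPix), 0)
      for (b in seq_len(B)) {
        plane <- refl[, , b]
        plane[idx] <- spec[, b]
        refl[, , b] <- plane
      }
      masks[[k]] <- m
      truth <- rbind(truth, data.frame(
        grainId = k, gridRow = gr, gridCol = gc,
        centroidY = mean(yy[m]), centroidX = mean(xx[m]),
        area = nPix, rasterIndex = k, class = classes[k]))
    }

    ## sub-threshold specks between grains: grain-like spectrum, small area
    if (cfg$speckCount > 0) {
      rSpeck <- max(1, round(sqrt(cfg$speckAreaPx / pi)))
      placed <- 0L
      while (placed < cfg$speckCount) {
        sy <- runif(1, 3, H - 3); sx <- runif(1, 3, W - 3)
        m <- (yy - sy)^2 + (xx - sx)^2 <= rSpeck^2
        ## keep a one-pixel moat so morphology cannot bridge speck and grain
        halo <- (yy - sy)^2 + (xx - sx)^2 <= (rSpeck + 3)^2
        if (any(halo & occupied)) next
        occupied <- occupied | m
        idx <- which(m)
        for (b in seq_len(B)) {
          plane <- refl[, , b]
          plane[idx] <- means[classes[1], b]
          refl[, , b] <- plane
        }
        placed <- placed + 1L
      }
    }

    ## smooth reference curves; raw = dark + R * (white - dark)
    white <- 3000 * (0.85 + 0.15 * sin(pi * (wl - wl[1]) / (wl[B] - wl[1])))
    dark <- rep(100, B)
    raw <- refl * rep(white - dark, each = H * W) + rep(dark, each = H * W)

    list(raw = raw, white = white, dark = dark, wavelength = wl,
         truth = truth, masks = masks, reflectance = refl)
  })
}
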