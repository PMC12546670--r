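#' Configuration for the synthetic grain-image generator
#'
#' Emulates single-grain microscope frames: one ellipse-shaped grain with
#' class-dependent hue, axis ratio and speckle texture on a non-black,
#' softly textured background. Surface defects (dark spots) appear with
#' probability `defectProbability`, mirroring real grains whose black spots
#' and cracks are deliberately retained. A ground-truth foreground mask is
#' returned with every image for segmentation tests.
#'
#' @param nClasses number of classes
#' @param canvasSize square image side in pixels (>= 64)
#' @param classHue per-class HSV hue in `[0, 1)`
#' @param classAxisRatio per-class minor/major axis ratio in `(0, 1]`
#' @param classSpeckleDensity per-class speckle probability per grain pixel
#' @param defectProbability probability of one dark-spot defect per image
#' @param seed integer seed for the per-class parameter defaults
#' @return a validated config list of class `ImageSimConfig`
#' @export
imageSimConfig <- function(nClasses = 12L, canvasSize = 96L,
                           classHue = NULL, classAxisRatio = NULL,
                           classSpeckleDensity = NULL,
                           defectProbability = 0.1, seed = 1L) {
  stopIfNot(canvasSize >= 64, "canvasSize must be >= 64")
  stopIfNot(defectProbability >= 0 && defectProbability <= 1,
            "defectProbability must be in [0, 1]")
  nClasses <- as.integer(nClasses)
  if (is.null(classHue))
    classHue <- (seq_len(nClasses) - 1) * 0.83 / nClasses + 0.02
  if (is.null(classAxisRatio))
    classAxisRatio <- seq(0.55, 0.95, length.out = nClasses)
  if (is.null(classSpeckleDensity))
    classSpeckleDensity <- seq(0.002, 0.03, length.out = nClasses)
  stopIfNot(length(classHue) == nClasses &&
            length(classAxisRatio) == nClasses &&
            length(classSpeckleDensity) == nClasses,
            "per-class parameter vectors must have length nClasses")
  structure(list(nClasses = nClasses, canvasSize = as.integer(canvasSize),
                 classHue = classHue, classAxisRatio = classAxisRatio,
                 classSpeckleDensity = classSpeckleDensity,
                 defectProbability = defectProbability,
                 seed = as.integer(seed)),
            class = "ImageSimConfig")
}

#' Generate one synthetic grain image
#'
#' Deterministic given `(class, seed)`: two calls with the same arguments
#' yield identical pixel arrays.
#'
#' @param class class id, 1..nClasses
#' @param cfg an [imageSimConfig()]
#' @param seed integer seed for this image
#' @return list with `image` (array `(3, H, W)`, values in `[0, 1]`) and
#'   `mask` (H x W logical ground-truth foreground), plus `ellipseArea`
#'   (analytic pi*a*b of the generating ellipse, pixels)
#' @export
generateGrainImage <- function(class, cfg, seed = 1L) {
  stopIfNot(inherits(cfg, "ImageSimConfig"), "cfg must be an ImageSimConfig")
  stopIfNot(class >= 1 && class <= cfg$nClasses,
            "class must be in 1..%d", cfg$nClasses)
  s <- cfg$canvasSize
  withSeed(childSeed(seed, 100 + class), {
    yy <- matrix(seq_len(s), s, s)          # row coordinate
    xx <- matrix(seq_len(s), s, s, byrow = TRUE)

    ## textured, non-black background
    bg <- 0.50 + 0.05 * sin(2 * pi * xx / s) * cos(2 * pi * yy / s) +
      matrix(rnorm(s * s, sd = 0.015), s)
    img <- array(rep(bg, 3) * rep(c(1.0, 0.97, 0.92), each = s * s),
                 c(s, s, 3))

    ## grain ellipse, class-dependent shape, random pose
    a <- 0.30 * s * runif(1, 0.92, 1.08)
    b <- a * cfg$classAxisRatio[class] * runif(1, 0.96, 1.04)
    th <- runif(1, 0, pi)
    cy <- s / 2 + runif(1, -3, 3)
    cx <- s / 2 + runif(1, -3, 3)
    xr <- (xx - cx) * cos(th) + (yy - cy) * sin(th)
    yr <- -(xx - cx) * sin(th) + (yy - cy) * cos(th)
    mask <- (xr / a)^2 + (yr / b)^2 <= 1

    ## class colour with radial shading
    rgb0 <- grDevices::col2rgb(grDevices::hsv(cfg$classHue[class],
                                              0.65, 0.78)) / 255
    shade <- 1 - 0.25 * pmin((xr / a)^2 + (yr / b)^2, 1)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[mask] <- (rgb0[ch] * shade)[mask]
      img[, , ch] <- plane
    }

    ## class-dependent speckle texture (darkening factor, stays above 0.2)
    spk <- mask & matrix(runif(s * s) < cfg$classSpeckleDensity[class], s)
    if (any(spk)) for (ch in 1:3) {
      plane <- img[, , ch]
      plane[spk] <- plane[spk] * 0.55
      img[, , ch] <- plane
    }

    ## optional dark-spot defect fully inside the grain
    if (runif(1) < cfg$defectProbability) {
      repeat {
        dy <- cy + runif(1, -0.4, 0.4) * b
        dx <- cx + runif(1, -0.4, 0.4) * a
        dxr <- (dx - cx) * cos(th) + (dy - cy) * sin(th)
        dyr <- -(dx - cx) * sin(th) + (dy - cy) * cos(th)
        if ((dxr / a)^2 + (dyr / b)^2 < 0.5) break
      }
      defect <- (xx - dx)^2 + (yy - dy)^2 <= 3^2
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[defect & mask] <- 0.05
        img[, , ch] <- plane
      }
    }

    list(image = aperm(img, c(3, 1, 2)), mask = mask,
         ellipseArea = pi * a * b)
  })
}
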