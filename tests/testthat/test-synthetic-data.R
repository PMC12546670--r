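test_that("the default sampling design yields 3600 balanced, labelled spectra", {
  cfg <- spectralSimConfig()   # 12 classes x 300 grains, 512 bands
  sp <- generateSpectra(cfg)
  expect_equal(dim(sp$spectra), c(3600, 512))
  expect_equal(as.vector(table(sp$labels)), rep(300, 12))
  expect_equal(length(sp$wavelength), 512)
})

test_that("spectra generation is deterministic and degenerate without noise", {
  cfg <- tinySpectralCfg()
  expect_identical(generateSpectra(cfg), generateSpectra(cfg))

  cfg0 <- tinySpectralCfg(nPerClass = 3L, noiseSd = 0)
  sp0 <- generateSpectra(cfg0)
  ## noiseless: samples of one class are identical, class means differ
  for (cl in levels(sp0$labels)) {
    rows <- sp0$spectra[sp0$labels == cl, , drop = FALSE]
    expect_equal(max(apply(rows, 2, function(v) diff(range(v)))), 0)
  }
  means <- classMeanSpectra(cfg0)
  expect_gt(min(dist(means)), 0)
})

test_that("noiseless spectra are perfectly recovered by a nearest-class-mean classifier", {
  cfg <- spectralSimConfig(noiseSd = 0, edgeNoiseSd = 0)   # full 3600-sample design
  sp <- generateSpectra(cfg)
  means <- classMeanSpectra(cfg)
  d2 <- outer(rowSums(sp$spectra^2), rowSums(means^2), "+") -
    2 * sp$spectra %*% t(means)
  pred <- max.col(-d2, "first")
  expect_equal(mean(pred == as.integer(sp$labels)), 1)
})

test_that("edge bands carry inflated noise", {
  cfg <- spectralSimConfig(nClasses = 2L, nPerClass = 200L, nBands = 64L,
                           edgeHead = 2L, edgeTail = 4L, noiseSd = 0.005,
                           seed = 3L)
  sp <- generateSpectra(cfg)
  one <- sp$spectra[sp$labels == 1, ]
  sds <- apply(one, 2, sd)
  edge <- c(1:2, 61:64)
  expect_gt(min(sds[edge]), 5 * max(sds[-edge]))
  expect_error(spectralSimConfig(nBands = 40L), "edge-noise")
})

test_that("grain images are deterministic with plausible elliptical masks", {
  cfg <- imageSimConfig()
  a <- generateGrainImage(3, cfg, seed = 7)
  b <- generateGrainImage(3, cfg, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a$image,
                         generateGrainImage(3, cfg, seed = 8)$image))
  expect_equal(dim(a$image), c(3, 96, 96))
  ## rasterised mask area close to the analytic ellipse area pi*a*b
  for (cl in c(1, 6, 12)) for (sd in 1:3) {
    g <- generateGrainImage(cl, cfg, seed = sd)
    expect_gt(sum(g$mask) / g$ellipseArea, 0.95)
    expect_lt(sum(g$mask) / g$ellipseArea, 1.05)
  }
  expect_error(generateGrainImage(13, cfg), "class")
})

test_that("forced defects produce dark regions inside the mask", {
  cfg <- imageSimConfig(defectProbability = 1)
  for (sd in 1:5) {
    g <- generateGrainImage(5, cfg, seed = sd)
    lum <- apply(g$image, c(2, 3), mean)
    dark <- lum < 0.2 & g$mask
    expect_gt(sum(dark), 0)
  }
  ## and a zero defect probability produces none
  cfg0 <- imageSimConfig(defectProbability = 0)
  g0 <- generateGrainImage(5, cfg0, seed = 1)
  lum0 <- apply(g0$image, c(2, 3), mean)
  expect_equal(sum(lum0 < 0.2 & g0$mask), 0)
})

test_that("hypercube ground truth matches the 5x5 acquisition design", {
  hc <- tinyHypercube()
  expect_equal(nrow(hc$truth), 25)
  expect_equal(hc$truth$rasterIndex, 1:25)
  expect_equal(dim(hc$raw), c(120, 120, 64))
  ## grains do not overlap and areas agree with the masks
  expect_equal(hc$truth$area, vapply(hc$masks, sum, 0L))
  total <- Reduce(`+`, lapply(hc$masks, function(m) m * 1L))
  expect_lte(max(total), 1)
})

test_that("a cube with no grains and no specks is pure background", {
  cfg <- cubeSimConfig(speckCount = 0L)
  scfg <- tinySpectralCfg(nPerClass = 1L, noiseSd = 0)
  hc <- generateHypercube(cfg, rep(1L, 25), scfg)
  ## zero out the grains using ground truth, then everything is background
  cube <- correctedCube(hc)
  vals <- cubeValues(cube)
  inGrain <- Reduce(`|`, hc$masks)
  bg <- apply(vals, 3, function(pl) pl[!inGrain])
  expect_equal(range(bg), c(0.04, 0.04), tolerance = 1e-9)
})

test_that("averaging a grain's true mask recovers its class mean spectrum", {
  hc <- tinyHypercube(noiseSd = 0.01)
  cube <- correctedCube(hc)
  means <- classMeanSpectra(hc$spectralCfg)
  for (k in c(1, 13, 25)) {
    m <- hc$masks[[k]]
    avg <- apply(cubeValues(cube), 3, function(pl) mean(pl[m]))
    truth <- means[hc$truth$class[k], ]
    expect_lt(mean(abs(avg - truth)), 3 * 0.01 / sqrt(sum(m)))
  }
})

test_that("invalid cube configurations are rejected", {
  expect_error(cubeSimConfig(grainRadiusPx = 10L, cellPx = 20L,
                             rowJitterPx = 2L), "overlap")
  expect_error(cubeSimConfig(speckAreaPx = 90L), "area filter")
  cfg <- cubeSimConfig()
  expect_error(generateHypercube(cfg, rep(1L, 24), tinySpectralCfg()),
               "one class per grid cell")
})
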