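test_that("segmentation recovers 25 grain components from a synthetic cube", {
  hc <- tinyHypercube(speckCount = 0L)
  score <- scoreImage(correctedCube(hc))
  mask <- segmentGrains(score)
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1.0))
  expect_equal(max(lab), 25)
  ## grain pixels recovered (mask covers the true disks)
  truthMask <- Reduce(`|`, hc$masks)
  expect_gt(sum(mask & truthMask) / sum(truthMask), 0.95)
})

test_that("segmentation of an all-background image is empty, not an error", {
  empty <- matrix(10, 40, 40)
  m <- segmentGrains(empty)
  expect_equal(sum(m), 0)
  expect_error(segmentGrains(array(1, c(2, 2, 2))), "2-D")
})

test_that("morphology fills small holes inside grains", {
  img <- matrix(5, 60, 60)
  yy <- row(img); xx <- col(img)
  disk <- (yy - 30)^2 + (xx - 30)^2 <= 12^2
  img[disk] <- 200
  img[30, 30] <- 5                     # small interior hole
  img[28:30, 35:37] <- 5               # larger hole, still enclosed
  holesBefore <- sum(img[disk] < 50)
  m <- segmentGrains(img)
  expect_gt(holesBefore, 0)
  ## both holes are filled; opening may shave isolated 1-px boundary tips
  expect_true(m[30, 30])
  expect_true(all(m[28:30, 35:37]))
  expect_gte(mean(m[disk]), 0.99)
})

test_that("otsu mode reports both thresholds and still segments the cube", {
  hc <- tinyHypercube(speckCount = 0L)
  score <- scoreImage(correctedCube(hc))
  m <- segmentGrains(score, segmentationParams(fineMethod = "otsu"))
  thr <- attr(m, "thresholds")
  expect_equal(unname(thr["fixed"]), 25)
  expect_true(is.finite(thr["otsu"]))
  expect_equal(nROIs(labelAndFilter(m, 80)), 25)
})

test_that("area filtering keeps 80-px components and drops 79-px ones", {
  mask <- matrix(FALSE, 60, 60)
  mask[2:11, 2:9] <- TRUE              # 80 px: kept
  mask[20:29, 20:27] <- TRUE; mask[20, 20] <- FALSE   # 79 px: dropped
  mask[40:49, 40:49] <- TRUE           # 100 px: kept
  rois <- labelAndFilter(mask, 80)
  expect_equal(nROIs(rois), 2)
  expect_setequal(roiTable(rois)$area, c(80, 100))
  expect_equal(nROIs(labelAndFilter(matrix(FALSE, 5, 5), 80)), 0)
})

test_that("labelling is 8-connected", {
  mask <- matrix(FALSE, 10, 10)
  mask[2:4, 2:4] <- TRUE
  mask[5:7, 5:7] <- TRUE               # touches only diagonally
  rois <- labelAndFilter(mask, 1)
  expect_equal(nROIs(rois), 1)
  expect_equal(roiTable(rois)$area, 18)
})

test_that("sub-threshold specks are rejected by the full pipeline", {
  hc <- tinyHypercube(speckCount = 3L)
  score <- scoreImage(correctedCube(hc))
  rois <- orderROIs(labelAndFilter(segmentGrains(score), 80), 5)
  expect_equal(nROIs(rois), 25)
})

test_that("raster ordering reproduces the grid and ignores input permutation", {
  hc <- tinyHypercube()
  score <- scoreImage(correctedCube(hc))
  rois <- labelAndFilter(segmentGrains(score), 80)
  ordered <- orderROIs(rois, 5)
  tb <- roiTable(ordered)
  expect_equal(tb$rasterIndex, 1:25)
  ## matches the generator's row-major ground truth
  expect_true(all(abs(tb$centroidY - hc$truth$centroidY) < 2))
  expect_true(all(abs(tb$centroidX - hc$truth$centroidX) < 2))

  ## permutation invariance
  perm <- withr::with_seed(9, sample(25))
  shuffled <- new("GrainROISet", table = transform(
    roiTable(rois)[perm, ], label = 1:25),
    pixels = roiPixels(rois)[perm])
  ordered2 <- orderROIs(shuffled, 5)
  expect_equal(roiTable(ordered2)$centroidY, tb$centroidY)
  expect_equal(roiTable(ordered2)$centroidX, tb$centroidX)

  ## single ROI, one row
  single <- new("GrainROISet", table = roiTable(rois)[1, ],
                pixels = roiPixels(rois)[1])
  expect_equal(roiTable(orderROIs(single, 1))$rasterIndex, 1)
  expect_error(orderROIs(single, 5), "exceeds")
})

test_that("mean spectra match brute-force averaging oracles", {
  ## constant cube: every spectrum equals the constant
  cube <- reflectanceCube(array(0.7, c(10, 10, 5)),
                          seq(900, 1300, length.out = 5))
  px <- rbind(c(2, 2), c(3, 4))
  rois <- new("GrainROISet",
              table = data.frame(label = 1L, centroidY = 2.5, centroidX = 3,
                                 area = 2L, rasterIndex = 1L),
              pixels = list(px))
  expect_equal(as.vector(extractMeanSpectra(cube, rois)), rep(0.7, 5))

  ## two-pixel ROI with values 0.2 / 0.4 averages to 0.3 in every band
  vals <- array(0.7, c(10, 10, 5))
  vals[2, 2, ] <- 0.2; vals[3, 4, ] <- 0.4
  cube2 <- reflectanceCube(vals, seq(900, 1300, length.out = 5))
  expect_equal(as.vector(extractMeanSpectra(cube2, rois)), rep(0.3, 5))

  ## full synthetic cube against the generator's class means
  hc <- tinyHypercube()
  cube3 <- correctedCube(hc)
  rois3 <- orderROIs(labelAndFilter(segmentGrains(scoreImage(cube3)), 80), 5)
  spectra <- extractMeanSpectra(cube3, rois3)
  means <- classMeanSpectra(hc$spectralCfg)
  for (k in seq_len(25)) {
    tol <- 3 * 0.01 / sqrt(roiTable(rois3)$area[k])
    expect_lt(mean(abs(spectra[k, ] - means[hc$truth$class[k], ])), tol)
  }
})

test_that("extracted spectra scale linearly with the cube", {
  hc <- tinyHypercube()
  cube <- correctedCube(hc)
  rois <- orderROIs(labelAndFilter(segmentGrains(scoreImage(cube)), 80), 5)
  s1 <- extractMeanSpectra(cube, rois)
  scaled <- reflectanceCube(cubeValues(cube) * 2.5, wavelengths(cube))
  expect_equal(extractMeanSpectra(scaled, rois), s1 * 2.5, tolerance = 1e-12)
})

test_that("false-colour RGB picks the documented bands and scales channels", {
  g <- wavelengthGrid()
  cube <- reflectanceCube(array(runif(4 * 4 * 512), c(4, 4, 512)), g)
  fc <- renderFalseColorRGB(cube)
  expect_equal(attr(fc, "bands"), c(42, 26, 12))
  expect_equal(dim(fc), c(4, 4, 3))
  expect_true(all(fc >= 0 & fc <= 255))

  ## constant cube renders uniform mid-gray
  cc <- reflectanceCube(array(0.5, c(4, 4, 512)), g)
  expect_true(all(renderFalseColorRGB(cc) == 128))

  ## grain pixels brighter than background in all channels
  hc <- tinyHypercube()
  cube3 <- correctedCube(hc)
  fc3 <- renderFalseColorRGB(cube3)
  grain <- Reduce(`|`, hc$masks)
  for (ch in 1:3)
    expect_gt(mean(fc3[, , ch][grain]), mean(fc3[, , ch][!grain]))

  expect_error(renderFalseColorRGB(cube3, rNm = 3000), "outside")
})

test_that("polygon masking restricts the coarse segmentation region", {
  img <- matrix(5, 60, 60)
  yy <- row(img); xx <- col(img)
  img[(yy - 15)^2 + (xx - 15)^2 <= 8^2] <- 200
  img[(yy - 45)^2 + (xx - 45)^2 <= 8^2] <- 200
  poly <- cbind(x = c(1, 30, 30, 1), y = c(1, 1, 30, 30))
  m <- segmentGrains(img, segmentationParams(polygonMask = poly))
  expect_equal(max(EBImage::bwlabel(EBImage::Image(m * 1.0))), 1)
  expect_true(all(which(m, arr.ind = TRUE) < 35))
})
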