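test_that("black/white correction satisfies its defining identities", {
  wl <- c(900, 1000, 1100, 1200)
  white <- rep(230, 4); dark <- rep(30, 4)

  r1 <- blackWhiteCorrect(array(230, c(3, 3, 4)), white, dark, wl)
  expect_equal(unique(as.vector(cubeValues(r1))), 1, tolerance = 1e-9)

  r0 <- blackWhiteCorrect(array(30, c(3, 3, 4)), white, dark, wl)
  expect_true(all(cubeValues(r0) == 0))

  ## hand arithmetic: (130 - 30) / (230 - 30) = 0.5
  rh <- blackWhiteCorrect(array(130, c(3, 3, 4)), white, dark, wl)
  expect_equal(unique(as.vector(cubeValues(rh))), 0.5, tolerance = 1e-7)
})

test_that("correction clips negatives, counts violations, accepts all reference shapes", {
  wl <- c(900, 1000)
  raw <- array(10, c(2, 2, 2))
  cube <- blackWhiteCorrect(raw, white = rep(100, 2), dark = rep(20, 2), wl)
  expect_true(all(cubeValues(cube) == 0))
  expect_equal(cube@provenance$nClippedLow, 8)

  ## per-column (W x B) and full-cube references broadcast identically
  rawc <- array(runif(2 * 3 * 2, 20, 100), c(2, 3, 2))
  wMat <- matrix(100, 3, 2); dMat <- matrix(20, 3, 2)
  a <- blackWhiteCorrect(rawc, wMat, dMat, wl)
  b <- blackWhiteCorrect(rawc, array(100, dim(rawc)), array(20, dim(rawc)), wl)
  expect_equal(cubeValues(a), cubeValues(b))

  expect_error(blackWhiteCorrect(rawc, matrix(1, 4, 2), dMat, wl),
               "reference")
  expect_error(
    blackWhiteCorrect(rawc, array(20, dim(rawc)), array(20, dim(rawc)), wl),
    "identically zero")
})

test_that("band screening retains the expected effective bands", {
  cube512 <- reflectanceCube(array(0.5, c(2, 2, 512)), wavelengthGrid())
  expect_equal(nBands(selectEffectiveBands(cube512)), 471)

  expect_equal(nBands(selectEffectiveBands(cube512, 0, 0)), 512)
  expect_equal(cubeValues(selectEffectiveBands(cube512, 0, 0)),
               cubeValues(cube512))

  cube100 <- reflectanceCube(array(0.5, c(2, 2, 100)),
                             wavelengthGrid(nBands = 100))
  expect_equal(nBands(selectEffectiveBands(cube100, 9, 32)), 59)

  expect_error(selectEffectiveBands(cube100, 60, 40), "removes all")
})

test_that("band screening slices the wavelength axis consistently", {
  g <- wavelengthGrid()
  cube <- reflectanceCube(array(0.5, c(2, 2, 512)), g)
  red <- selectEffectiveBands(cube)
  expect_equal(wavelengths(red), wavelengths(g)[10:480])
  expect_true(!is.unsorted(wavelengths(red), strictly = TRUE))
})

test_that("nearest-band lookup matches the arithmetic oracle", {
  g <- wavelengthGrid()   # 512 bands, 886-1735.34 nm
  wl <- wavelengths(g)
  oracle <- function(nm) which.min(abs(wl - nm))
  for (nm in c(886, 954.15, 927.55, 904.28, 1735.34, 1300)) {
    expect_equal(bandIndexForWavelength(g, nm), oracle(nm))
  }
  ## the false-colour channel wavelengths land on (1-based) bands 42/26/12
  expect_equal(bandIndexForWavelength(g, 954.15), 42)
  expect_equal(bandIndexForWavelength(g, 927.55), 26)
  expect_equal(bandIndexForWavelength(g, 904.28), 12)
  expect_equal(bandIndexForWavelength(g, 886), 1)
  expect_error(bandIndexForWavelength(g, 2000), "outside")
  ## exact midpoint resolves to the lower band
  mid <- (wl[5] + wl[6]) / 2
  expect_equal(bandIndexForWavelength(g, mid), 5)
})

test_that("correction inverts the synthetic raw model and commutes with screening", {
  hc <- tinyHypercube(noiseSd = 0)
  cube <- correctedCube(hc)
  expect_equal(cubeValues(cube), hc$reflectance, tolerance = 1e-9)

  a <- selectEffectiveBands(cube, 2, 4)
  b <- blackWhiteCorrect(hc$raw[, , 3:60], hc$white[3:60], hc$dark[3:60],
                         hc$wavelength[3:60])
  expect_equal(cubeValues(a), cubeValues(b), tolerance = 1e-12)
  expect_equal(wavelengths(a), wavelengths(b))
})

test_that("ENVI writer and reader round-trip a cube", {
  hc <- tinyHypercube()
  cube <- correctedCube(hc)
  path <- file.path(tempdir(), "cube_test")
  writeENVI(cube, path)
  back <- readENVI(path)
  expect_s4_class(back, "ReflectanceCube")
  ## float32 storage: ~7 significant digits survive
  expect_equal(cubeValues(back), cubeValues(cube), tolerance = 1e-6)
  expect_equal(wavelengths(back), wavelengths(cube), tolerance = 1e-6)
  unlink(c(path, paste0(path, ".hdr")))
})
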