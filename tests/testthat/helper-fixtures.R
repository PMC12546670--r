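## Shared fixtures: small configs so individual tests stay fast.

## 64-band spectral config (edge regions shrunk proportionally)
tinySpectralCfg <- function(nPerClass = 2L, noiseSd = 0.01, seed = 1L,
                            nClasses = 12L)
  spectralSimConfig(nClasses = nClasses, nPerClass = nPerClass,
                    nBands = 64L, edgeHead = 2L, edgeTail = 4L,
                    noiseSd = noiseSd, edgeNoiseSd = 10 * noiseSd,
                    seed = seed)

## default 5x5 hypercube over the tiny spectral config
tinyHypercube <- function(speckCount = 3L, noiseSd = 0.01, seed = 1L) {
  cfg <- cubeSimConfig(speckCount = speckCount, seed = seed)
  scfg <- tinySpectralCfg(nPerClass = 1L, noiseSd = noiseSd, seed = seed)
  hc <- generateHypercube(cfg, rep(1:5, 5), scfg)
  hc$spectralCfg <- scfg
  hc
}

correctedCube <- function(hc)
  blackWhiteCorrect(hc$raw, hc$white, hc$dark, hc$wavelength)

## central finite-difference gradient of f at x
numGrad <- function(f, x, eps = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}
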