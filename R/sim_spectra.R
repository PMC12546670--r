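#' Configuration for the synthetic NIR spectra generator
#'
#' Describes a 12-variety, 300-grain-per-variety sampling design on a
#' 512-band 886--1735.34 nm grid. Class signatures are smooth baselines minus
#' Gaussian absorption dips centred near the O-H/C-H/N-H overtone bands at
#' 920, 980, 1030, 1130, 1230 and 1480 nm; classes share the dip locations
#' (varieties share spectral trends) but differ in relative dip depths, drawn
#' once per class from a Dirichlet-scaled template. The first `edgeHead` and
#' last `edgeTail` bands receive additional noise, emulating the weak imager
#' response at the range ends that motivates band screening.
#'
#' @param nClasses number of varieties
#' @param nPerClass grains per variety
#' @param nBands spectral bands
#' @param wavelengthStart,wavelengthEnd grid limits, nm
#' @param peakCenters absorption dip centres, nm
#' @param classPeakDepths optional nClasses x length(peakCenters) matrix of
#'   dip depths (reflectance units); drawn from the seeded Dirichlet template
#'   when NULL
#' @param totalDepth summed dip depth per class used for the default template
#' @param peakSigma Gaussian dip width in nm
#' @param baselineLevel baseline reflectance
#' @param noiseSd i.i.d. per-band noise standard deviation (reflectance)
#' @param edgeNoiseSd additional noise s.d. on the edge bands (default
#'   10 x noiseSd)
#' @param edgeHead,edgeTail number of corrupted leading/trailing bands
#' @param seed integer seed; every draw is reproducible given it
#' @return a validated config list of class `SpectralSimConfig`
#' @examples
#' cfg <- spectralSimConfig(nPerClass = 5)
#' dim(generateSpectra(cfg)$spectra)
#' @export
spectralSimConfig <- function(nClasses = 12L, nPerClass = 300L,
                              nBands = 512L, wavelengthStart = 886,
                              wavelengthEnd = 1735.34,
                              peakCenters = c(920, 980, 1030, 1130, 1230, 1480),
                              classPeakDepths = NULL, totalDepth = 0.45,
                              peakSigma = 15, baselineLevel = 0.85,
                              noiseSd = 0.01, edgeNoiseSd = 10 * noiseSd,
                              edgeHead = 9L, edgeTail = 32L, seed = 1L) {
  stopIfNot(wavelengthEnd > wavelengthStart, "wavelengthEnd must exceed start")
  stopIfNot(nBands >= edgeHead + edgeTail,
            "need nBands >= %d to place the edge-noise regions",
            edgeHead + edgeTail)
  stopIfNot(noiseSd >= 0 && edgeNoiseSd >= 0, "noise sds must be >= 0")
  stopIfNot(all(peakCenters > wavelengthStart & peakCenters < wavelengthEnd),
            "peak centres must lie inside the wavelength range")
  cfg <- list(nClasses = as.integer(nClasses),
              nPerClass = as.integer(nPerClass), nBands = as.integer(nBands),
              wavelengthStart = wavelengthStart, wavelengthEnd = wavelengthEnd,
              peakCenters = peakCenters, peakSigma = peakSigma,
              totalDepth = totalDepth, baselineLevel = baselineLevel,
              noiseSd = noiseSd, edgeNoiseSd = edgeNoiseSd,
              edgeHead = as.integer(edgeHead), edgeTail = as.integer(edgeTail),
              seed = as.integer(seed))
  if (is.null(classPeakDepths)) {
    classPeakDepths <- withSeed(childSeed(seed, 11), {
      g <- matrix(stats::rgamma(cfg$nClasses * length(peakCenters), shape = 4),
                  cfg$nClasses)
      totalDepth * g / rowSums(g)
    })
  }
  stopIfNot(all(classPeakDepths >= 0), "dip depths must be >= 0")
  stopIfNot(nrow(classPeakDepths) == cfg$nClasses &&
            ncol(classPeakDepths) == length(peakCenters),
            "classPeakDepths must be nClasses x nPeaks")
  cfg$classPeakDepths <- classPeakDepths
  structure(cfg, class = "SpectralSimConfig")
}

#' Noiseless class-mean spectra
#'
#' The deterministic component of each class signature: a gently sloping
#' baseline minus the class's Gaussian dips.
#'
#' @param cfg a [spectralSimConfig()]
#' @return nClasses x nBands matrix of mean reflectance
#' @export
classMeanSpectra <- function(cfg) {
  wl <- seq(cfg$wavelengthStart, cfg$wavelengthEnd, length.out = cfg$nBands)
  base <- cfg$baselineLevel +
    0.03 * sin(2 * pi * (wl - cfg$wavelengthStart) /
               (cfg$wavelengthEnd - cfg$wavelengthStart))
  dips <- vapply(seq_along(cfg$peakCenters), function(p)
    exp(-(wl - cfg$peakCenters[p])^2 / (2 * cfg$peakSigma^2)),
    numeric(cfg$nBands))                       # nBands x nPeaks
  means <- matrix(base, cfg$nClasses, cfg$nBands, byrow = TRUE) -
    cfg$classPeakDepths %*% t(dips)
  pmax(means, 0)
}

#' Generate labelled synthetic spectra
#'
#' Each spectrum is its class mean plus i.i.d. Gaussian noise, with an
#' additional noise term of s.d. `edgeNoiseSd` on the first `edgeHead` and
#' last `edgeTail` bands. Reproducible given the config seed.
#'
#' @param cfg a [spectralSimConfig()]
#' @return list with `spectra` (N x nBands matrix, N = nClasses * nPerClass),
#'   `labels` (factor), and `wavelength` (band centres, nm)
#' @export
generateSpectra <- function(cfg) {
  stopIfNot(inherits(cfg, "SpectralSimConfig"), "cfg must be a SpectralSimConfig")
  means <- classMeanSpectra(cfg)
  n <- cfg$nClasses * cfg$nPerClass
  labels <- factor(rep(seq_len(cfg$nClasses), each = cfg$nPerClass))
  edge <- c(seq_len(cfg$edgeHead),
            seq.int(cfg$nBands - cfg$edgeTail + 1L, cfg$nBands))
  spectra <- withSeed(childSeed(cfg$seed, 12), {
    x <- means[as.integer(labels), , drop = FALSE]
    if (cfg$noiseSd > 0)
      x <- x + matrix(rnorm(n * cfg$nBands, sd = cfg$noiseSd), n)
    if (cfg$edgeNoiseSd > 0)
      x[, edge] <- x[, edge] +
        matrix(rnorm(n * length(edge), sd = cfg$edgeNoiseSd), n)
    x
  })
  list(spectra = pmax(spectra, 0), labels = labels,
       wavelength = seq(cfg$wavelengthStart, cfg$wavelengthEnd,
                        length.out = cfg$nBands))
}
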