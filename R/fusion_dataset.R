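#' Build a paired spectral/image sample set
#'
#' Generates one NIR spectrum and one grain image per sample with aligned
#' class labels (both modalities informative), screens the noisy edge bands,
#' and preprocesses images to normalised model input. This is the plain
#' synthetic counterpart of the instrument dataset: 12 varieties x 300 grains
#' at the default configs.
#'
#' @param spectralCfg a [spectralSimConfig()]
#' @param imageCfg an [imageSimConfig()] (class count must match)
#' @param imageSize model input side (images are resized and normalised)
#' @param screenBands apply the default head/tail band screen to the spectra
#' @param seed integer seed
#' @return a [MultiModalSet-class]
#' @export
makeSyntheticMultiModalSet <- function(spectralCfg = spectralSimConfig(),
                                       imageCfg = imageSimConfig(
                                         nClasses = spectralCfg$nClasses),
                                       imageSize = 224L, screenBands = TRUE,
                                       seed = 1L) {
  stopIfNot(imageCfg$nClasses == spectralCfg$nClasses,
            "spectral and image configs disagree on the class count")
  sp <- generateSpectra(spectralCfg)
  spectra <- sp$spectra
  if (screenBands)
    spectra <- spectra[, (spectralCfg$edgeHead + 1):
                         (ncol(spectra) - spectralCfg$edgeTail), drop = FALSE]
  n <- nrow(spectra)
  images <- vector("list", n)
  for (i in seq_len(n))
    images[[i]] <- prepareModelInput(
      generateGrainImage(as.integer(sp$labels[i]), imageCfg,
                         seed = childSeed(seed, 5000 + i))$image,
      size = imageSize)
  new("MultiModalSet", spectra = spectra, images = images,
      labels = sp$labels, sampleId = sprintf("grain_%04d", seq_len(n)))
}

#' Build the fusion-advantage synthetic set
#'
#' A 12-class paired dataset in which class information is deliberately split
#' across modalities. Classes 1--10 are distinct (spectral archetype, visual
#' archetype) pairs drawn from 4 spectral signatures x 4 visual appearances,
#' so neither modality alone identifies a class (a spectrum narrows 12
#' classes to ~3, an image to ~3). Classes 11 and 12 are crossed mixtures
#' over the same two spectral and two visual archetypes -- their marginal
#' distributions per modality are identical, so any decision-level
#' combination of unimodal posteriors cannot separate them, while the joint
#' (feature-level) observation identifies them exactly. Consequences, by
#' construction: fused models can exceed both unimodal models; feature-level
#' fusion can exceed decision-level fusion; and resolving classes 11/12
#' requires a multiplicative cross-modal interaction of the kind the CMA
#' block provides (a linear head on concatenated features cannot express it).
#'
#' Scaled for desk experiments: 30 samples per class, 192 raw bands (screened
#' to 151), images preprocessed to `imageSize` (32 px default).
#'
#' @param nPerClass samples per class
#' @param nBands raw spectral bands before screening
#' @param imageSize preprocessed image side, pixels
#' @param noiseSd spectral noise s.d.
#' @param seed integer seed
#' @return a [MultiModalSet-class]; attributes `spectralArchetype` and
#'   `visualArchetype` record the generating archetypes per sample
#' @export
makeFusionAdvantageSet <- function(nPerClass = 30L, nBands = 192L,
                                   imageSize = 32L, noiseSd = 0.01,
                                   seed = 1L) {
  pairTable <- rbind(
    c(1, 1), c(1, 2), c(1, 3), c(2, 1), c(2, 2),
    c(2, 4), c(3, 1), c(3, 2), c(4, 1), c(4, 2))
  xorA <- rbind(c(3, 3), c(4, 4))   # class 11
  xorB <- rbind(c(3, 4), c(4, 3))   # class 12

  specCfg <- spectralSimConfig(nClasses = 4L, nPerClass = 1L,
                               nBands = as.integer(nBands),
                               noiseSd = noiseSd,
                               edgeNoiseSd = 10 * noiseSd,
                               seed = childSeed(seed, 81))
  means <- classMeanSpectra(specCfg)
  imgCfg <- imageSimConfig(nClasses = 4L,
                           classHue = c(0.02, 0.3, 0.55, 0.8),
                           classAxisRatio = c(0.55, 0.95, 0.7, 0.85),
                           classSpeckleDensity = c(0.002, 0.03, 0.01, 0.02),
                           seed = childSeed(seed, 82))

  nPerClass <- as.integer(nPerClass)
  n <- 12L * nPerClass
  sArch <- integer(n); vArch <- integer(n)
  labels <- rep(1:12, each = nPerClass)
  for (cl in 1:12) {
    idx <- which(labels == cl)
    if (cl <= 10) {
      sArch[idx] <- pairTable[cl, 1]; vArch[idx] <- pairTable[cl, 2]
    } else {
      tab <- if (cl == 11) xorA else xorB
      half <- seq_len(nPerClass) <= nPerClass / 2
      sArch[idx] <- ifelse(half, tab[1, 1], tab[2, 1])
      vArch[idx] <- ifelse(half, tab[1, 2], tab[2, 2])
    }
  }

  edge <- c(seq_len(specCfg$edgeHead),
            seq.int(nBands - specCfg$edgeTail + 1L, nBands))
  spectra <- withSeed(childSeed(seed, 83), {
    x <- means[sArch, , drop = FALSE]
    if (noiseSd > 0) {
      x <- x + matrix(rnorm(n * nBands, sd = noiseSd), n)
      x[, edge] <- x[, edge] +
        matrix(rnorm(n * length(edge), sd = 10 * noiseSd), n)
    }
    pmax(x, 0)
  })
  spectra <- spectra[, (specCfg$edgeHead + 1):(nBands - specCfg$edgeTail),
                     drop = FALSE]

  images <- vector("list", n)
  for (i in seq_len(n))
    images[[i]] <- prepareModelInput(
      generateGrainImage(vArch[i], imgCfg,
                         seed = childSeed(seed, 6000 + i))$image,
      size = imageSize)

  out <- new("MultiModalSet", spectra = spectra, images = images,
             labels = factor(labels, levels = 1:12),
             sampleId = sprintf("fa_%04d", seq_len(n)))
  attr(out, "spectralArchetype") <- sArch
  attr(out, "visualArchetype") <- vArch
  out
}
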