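#' Wavelength grid of a hyperspectral acquisition
#'
#' Evenly spaced wavelength axis of a hypercube. The default constructor
#' arguments describe a 512-band near-infrared acquisition spanning
#' 886--1735.34 nm (5 nm optical resolution, push-broom line scan).
#'
#' @slot start first band centre, nm
#' @slot end last band centre, nm
#' @slot nBands number of bands
#' @export
setClass("WavelengthGrid",
  representation(start = "numeric", end = "numeric", nBands = "integer"),
  validity = function(object) {
    if (length(object@start) != 1 || length(object@end) != 1)
      return("start and end must be scalars")
    if (!is.finite(object@start) || !is.finite(object@end))
      return("start and end must be finite")
    if (object@end <= object@start) return("end must exceed start")
    if (object@nBands < 2L) return("need at least 2 bands")
    TRUE
  })

#' Construct a wavelength grid
#'
#' @param start first band centre in nm
#' @param end last band centre in nm
#' @param nBands number of evenly spaced bands
#' @return a [WavelengthGrid-class] object
#' @examples
#' g <- wavelengthGrid()
#' nBands(g)
#' @export
wavelengthGrid <- function(start = 886, end = 1735.34, nBands = 512L) {
  new("WavelengthGrid", start = start, end = end, nBands = as.integer(nBands))
}

#' Reflectance hypercube
#'
#' An H x W x B array of reflectance values in `[0, +Inf)` (values above 1 are
#' kept: specular pixels carry masking information) together with its
#' wavelength axis and correction provenance.
#'
#' @slot values numeric array, height x width x bands
#' @slot wavelength numeric vector of band centres, nm
#' @slot provenance list of correction metadata (clip counts, epsilon, ...)
#' @export
setClass("ReflectanceCube",
  representation(values = "array", wavelength = "numeric", provenance = "list"),
  validity = function(object) {
    d <- dim(object@values)
    if (length(d) != 3) return("values must be a 3-D array (H x W x B)")
    if (d[3] != length(object@wavelength))
      return("band dimension must match wavelength length")
    if (any(!is.finite(object@values))) return("values must be finite")
    if (any(object@values < 0)) return("reflectance must be non-negative")
    if (is.unsorted(object@wavelength, strictly = TRUE))
      return("wavelength axis must be strictly increasing")
    TRUE
  })

#' Construct a reflectance cube
#'
#' @param values H x W x B numeric array
#' @param wavelength numeric vector of band centres (nm), or a
#'   [WavelengthGrid-class]
#' @param provenance optional list of metadata
#' @return a [ReflectanceCube-class]
#' @export
reflectanceCube <- function(values, wavelength, provenance = list()) {
  if (is(wavelength, "WavelengthGrid")) wavelength <- wavelengths(wavelength)
  new("ReflectanceCube", values = values, wavelength = as.numeric(wavelength),
      provenance = provenance)
}

#' Set of grain regions of interest
#'
#' Connected pixel regions (grains) found in a hypercube, with centroids,
#' areas and -- after ordering -- row-major raster indices. Pixel coordinates
#' are 1-based `(row, col)` matrices, matching R's array indexing.
#'
#' @slot table data.frame with columns label, centroidY, centroidX, area,
#'   rasterIndex (NA until [orderROIs()] is applied)
#' @slot pixels list of integer matrices, one per ROI, columns (row, col)
#' @export
setClass("GrainROISet",
  representation(table = "data.frame", pixels = "list"),
  validity = function(object) {
    tb <- object@table
    need <- c("label", "centroidY", "centroidX", "area", "rasterIndex")
    if (!all(need %in% names(tb))) return("table missing required columns")
    if (nrow(tb) != length(object@pixels))
      return("one pixel matrix per table row required")
    if (nrow(tb) > 0 && any(tb$area != vapply(object@pixels, nrow, 0L)))
      return("area must equal the number of pixels")
    ri <- tb$rasterIndex
    if (any(!is.na(ri)) && anyDuplicated(ri[!is.na(ri)]))
      return("rasterIndex must be unique")
    TRUE
  })

#' Paired spectral/image sample set
#'
#' The training record collection: one NIR spectrum, one RGB image and one
#' class label per grain.
#'
#' @slot spectra numeric matrix, samples x bands
#' @slot images list of numeric arrays `(3, H, W)`, values in `[0, 1]`
#' @slot labels factor of class labels, one per sample
#' @slot sampleId character vector of grain identifiers
#' @export
setClass("MultiModalSet",
  representation(spectra = "matrix", images = "list", labels = "factor",
                 sampleId = "character"),
  validity = function(object) {
    n <- nrow(object@spectra)
    if (length(object@images) != n) return("one image per spectrum required")
    if (length(object@labels) != n) return("one label per spectrum required")
    if (length(object@sampleId) != n) return("one id per spectrum required")
    TRUE
  })

#' Architecture configuration for MSI-FusionNet
#'
#' Single source of truth for model construction and parameter accounting.
#' `fusion` selects the ablation variant: `"cma"` (full cross-modal attention
#' fusion), `"concat"` (feature concatenation, no fusion attention),
#' `"spectral"` (1D branch only) or `"image"` (2D branch only).
#'
#' @slot inputLength spectral input length (bands fed to the 1D branch)
#' @slot numClasses number of output classes
#' @slot backbone registered 2D backbone name
#' @slot imageSize square input side for the image branch, pixels
#' @slot fusion one of "cma", "concat", "spectral", "image"
#' @slot spectralAttention apply CBAM-style channel attention in the 1D branch
#' @slot imageAttention apply the SE block in the 2D branch
#' @slot scaleMode attention logit scaling, "sqrt" (divide by sqrt(C')) or
#'   "dim" (divide by C')
#' @slot tieShared use one weight-tied shared 128->64 layer for both branches
#' @slot leakySlope negative slope of the post-fusion leaky ReLU
#' @export
setClass("ModelSpec",
  representation(inputLength = "integer", numClasses = "integer",
                 backbone = "character", imageSize = "integer",
                 fusion = "character", spectralAttention = "logical",
                 imageAttention = "logical", scaleMode = "character",
                 tieShared = "logical", leakySlope = "numeric"),
  validity = function(object) {
    if (!object@fusion %in% c("cma", "concat", "spectral", "image"))
      return("fusion must be one of cma/concat/spectral/image")
    if (!object@scaleMode %in% c("sqrt", "dim"))
      return("scaleMode must be 'sqrt' or 'dim'")
    if (object@inputLength < 40L)
      return("inputLength too short for the six stride-2 layers")
    if (object@numClasses < 2L) return("need at least 2 classes")
    if (object@imageSize < 32L) return("imageSize must be at least 32")
    TRUE
  })

#' Construct a ModelSpec
#'
#' @param inputLength spectral input length (default 480)
#' @param numClasses number of classes (default 12)
#' @param backbone backbone name, see [listBackbones()]
#' @param imageSize image input side (default 224)
#' @param fusion "cma", "concat", "spectral" or "image"
#' @param spectralAttention,imageAttention attention on/off flags
#' @param scaleMode "sqrt" or "dim"
#' @param tieShared weight-tie the shared 128->64 layer across branches
#' @param leakySlope negative slope of the fused-feature leaky ReLU
#' @return a [ModelSpec-class]
#' @examples
#' spec <- modelSpec(numClasses = 12)
#' @export
modelSpec <- function(inputLength = 480L, numClasses = 12L,
                      backbone = "shufflenet_v2", imageSize = 224L,
                      fusion = "cma", spectralAttention = TRUE,
                      imageAttention = TRUE, scaleMode = "sqrt",
                      tieShared = TRUE, leakySlope = 0.01) {
  new("ModelSpec", inputLength = as.integer(inputLength),
      numClasses = as.integer(numClasses), backbone = backbone,
      imageSize = as.integer(imageSize), fusion = fusion,
      spectralAttention = spectralAttention, imageAttention = imageAttention,
      scaleMode = scaleMode, tieShared = tieShared, leakySlope = leakySlope)
}

#' Classification evaluation report
#'
#' @slot accuracy overall fraction correct
#' @slot precision macro-averaged precision
#' @slot recall macro-averaged recall
#' @slot perClass data.frame: class, precision, recall, f1, support
#' @slot confusion integer confusion matrix (rows: truth, cols: prediction)
#' @slot confusionPct row-normalised confusion matrix, percent
#' @slot embeddings named list of N x 2 coordinate matrices (pca/tsne/umap)
#' @export
setClass("EvalReport",
  representation(accuracy = "numeric", precision = "numeric",
                 recall = "numeric", perClass = "data.frame",
                 confusion = "matrix", confusionPct = "matrix",
                 embeddings = "list"),
  validity = function(object) {
    if (nrow(object@confusion) != ncol(object@confusion))
      return("confusion matrix must be square")
    tot <- sum(object@confusion)
    if (tot > 0) {
      acc <- sum(diag(object@confusion)) / tot
      if (abs(acc - object@accuracy) > 1e-12)
        return("accuracy must equal trace/total")
    }
    TRUE
  })
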