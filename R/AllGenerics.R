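#' Band centres of a wavelength grid or cube
#' @param x a WavelengthGrid or ReflectanceCube
#' @return numeric vector of band centres in nm
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' Number of spectral bands
#' @param x a WavelengthGrid or ReflectanceCube
#' @return integer band count
#' @export
setGeneric("nBands", function(x) standardGeneric("nBands"))

#' Reflectance values of a cube
#' @param x a ReflectanceCube
#' @return H x W x B numeric array
#' @export
setGeneric("cubeValues", function(x) standardGeneric("cubeValues"))

#' ROI geometry table
#' @param x a GrainROISet
#' @return data.frame of per-ROI geometry
#' @export
setGeneric("roiTable", function(x) standardGeneric("roiTable"))

#' ROI pixel coordinate lists
#' @param x a GrainROISet
#' @return list of (row, col) integer matrices
#' @export
setGeneric("roiPixels", function(x) standardGeneric("roiPixels"))

#' Number of regions of interest
#' @param x a GrainROISet
#' @return integer count
#' @export
setGeneric("nROIs", function(x) standardGeneric("nROIs"))

#' @describeIn wavelengths band centres of the grid
#' @export
setMethod("wavelengths", "WavelengthGrid", function(x)
  seq(x@start, x@end, length.out = x@nBands))

#' @describeIn wavelengths band centres of the cube axis
#' @export
setMethod("wavelengths", "ReflectanceCube", function(x) x@wavelength)

#' @describeIn nBands bands in the grid
#' @export
setMethod("nBands", "WavelengthGrid", function(x) x@nBands)

#' @describeIn nBands bands in the cube
#' @export
setMethod("nBands", "ReflectanceCube", function(x) length(x@wavelength))

#' @describeIn cubeValues raw array access
#' @export
setMethod("cubeValues", "ReflectanceCube", function(x) x@values)

#' @describeIn roiTable geometry table access
#' @export
setMethod("roiTable", "GrainROISet", function(x) x@table)

#' @describeIn roiPixels pixel list access
#' @export
setMethod("roiPixels", "GrainROISet", function(x) x@pixels)

#' @describeIn nROIs ROI count
#' @export
setMethod("nROIs", "GrainROISet", function(x) nrow(x@table))

#' @export
setMethod("show", "WavelengthGrid", function(object) {
  st <- (object@end - object@start) / (object@nBands - 1)
  cat(sprintf("WavelengthGrid: %d bands, %.2f-%.2f nm (step %.4f nm)\n",
              object@nBands, object@start, object@end, st))
})

#' @export
setMethod("show", "ReflectanceCube", function(object) {
  d <- dim(object@values)
  cat(sprintf("ReflectanceCube: %d x %d pixels, %d bands (%.2f-%.2f nm)\n",
              d[1], d[2], d[3], min(object@wavelength), max(object@wavelength)))
  if (length(object@provenance))
    cat("  provenance:", paste(names(object@provenance), collapse = ", "), "\n")
})

#' @export
setMethod("show", "GrainROISet", function(object) {
  cat(sprintf("GrainROISet: %d ROIs", nrow(object@table)))
  if (nrow(object@table) > 0) {
    cat(sprintf(", areas %d-%d px", min(object@table$area),
                max(object@table$area)))
    if (all(!is.na(object@table$rasterIndex))) cat(", raster-ordered")
  }
  cat("\n")
})

#' @export
setMethod("show", "MultiModalSet", function(object) {
  cat(sprintf("MultiModalSet: %d samples, %d bands, %d classes\n",
              nrow(object@spectra), ncol(object@spectra),
              nlevels(object@labels)))
})

#' @export
setMethod("show", "ModelSpec", function(object) {
  cat("ModelSpec (MSI-FusionNet)\n")
  cat(sprintf("  spectral input length: %d\n", object@inputLength))
  cat(sprintf("  backbone: %s (image %dx%d)\n", object@backbone,
              object@imageSize, object@imageSize))
  cat(sprintf("  fusion: %s | spectral attention: %s | image attention: %s\n",
              object@fusion, object@spectralAttention, object@imageAttention))
  cat(sprintf("  classes: %d\n", object@numClasses))
})

#' @export
setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: accuracy %.4f, macro precision %.4f, macro recall %.4f\n",
              object@accuracy, object@precision, object@recall))
  cat(sprintf("  %d classes, %d samples\n", nrow(object@confusion),
              sum(object@confusion)))
})

#' Number of samples in a multimodal set
#' @param x a MultiModalSet
#' @return integer sample count
#' @export
setMethod("length", "MultiModalSet", function(x) nrow(x@spectra))

#' Subset a multimodal set by sample index
#' @param x a MultiModalSet
#' @param i integer or logical index
#' @param j,drop,... ignored
#' @return a MultiModalSet
#' @export
setMethod("[", "MultiModalSet", function(x, i, j, ..., drop = FALSE) {
  new("MultiModalSet", spectra = x@spectra[i, , drop = FALSE],
      images = x@images[i],
      labels = factor(x@labels[i], levels = levels(x@labels)),
      sampleId = x@sampleId[i])
})

#' Labels of a multimodal set
#' @param object a MultiModalSet
#' @return factor of class labels
#' @export
setGeneric("sampleLabels", function(object) standardGeneric("sampleLabels"))

#' @describeIn sampleLabels label access
#' @export
setMethod("sampleLabels", "MultiModalSet", function(object) object@labels)
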