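## MSI-FusionNet assembly: spectral branch (Table-style six-layer 1D CNN with
## channel attention), image branch (registered 2-D backbone + SE), CMA
## fusion, classifier head.

walkModules <- function(module, fn) {
  fn(module)
  for (ch in module$children) walkModules(ch, fn)
  invisible(NULL)
}

clearCaches <- function(module) {
  walkModules(module, function(m) m$stack <- list())
}

## Table of the six spectral conv layers: channels 1->16->32->64->128->256
## ->512, kernels 7/7/5/5/3/3, stride 2, padding 1, BN + ReLU after each.
spectralLayerTable <- function() {
  data.frame(layer = paste0("Conv", 1:6),
             inChannels = c(1L, 16L, 32L, 64L, 128L, 256L),
             outChannels = c(16L, 32L, 64L, 128L, 256L, 512L),
             kernel = c(7L, 7L, 5L, 5L, 3L, 3L),
             stride = 2L, padding = 1L, batchNorm = TRUE,
             activation = "ReLU")
}

#' Per-layer feature sizes of the spectral branch
#'
#' Propagates an input length through the six stride-2 convolution layers and
#' reports each layer's output length and the flattened feature count.
#'
#' @param inputLength spectral input length (default 480)
#' @return data.frame with the layer table plus `featureSize` (output length
#'   per layer); the attribute `flatten` holds the flattened length
#' @examples
#' attr(spectralShapePlan(480), "flatten")  # 3584
#' @export
spectralShapePlan <- function(inputLength = 480L) {
  tb <- spectralLayerTable()
  L <- as.integer(inputLength)
  sizes <- integer(6)
  for (i in 1:6) {
    L <- convOutLen(L, tb$kernel[i], tb$stride[i], tb$padding[i])
    stopIfNot(L >= 1, "input length %d collapses at %s", inputLength,
              tb$layer[i])
    sizes[i] <- L
  }
  tb$featureSize <- sizes
  attr(tb, "flatten") <- tb$outChannels[6] * sizes[6]
  tb
}

buildSpectralBranch <- function(inputLength, attention, shared) {
  plan <- spectralShapePlan(inputLength)
  flat <- attr(plan, "flatten")
  mods <- list()
  for (i in 1:6)
    mods <- c(mods, list(
      nnConv1d(plan$inChannels[i], plan$outChannels[i], plan$kernel[i],
               plan$stride[i], plan$padding[i]),
      nnBatchNorm(plan$outChannels[i]), nnReLU()))
  if (attention) mods <- c(mods, list(nnChannelAttention1d(512L, 8L)))
  mods <- c(mods, list(nnFlatten(),
                       nnLinear(flat, 256L), nnReLU(),
                       nnLinear(256L, 128L), nnReLU(),
                       shared, nnReLU()))
  branch <- do.call(nnSequential, mods)
  branch$type <- "spectral_branch"
  branch$inputLength <- as.integer(inputLength)
  branch$flatten <- flat
  branch
}

buildImageBranch <- function(backbone, attention, shared) {
  trunk <- getBackboneConstructor(backbone)()
  mods <- list(trunk)
  if (attention) mods <- c(mods, list(nnSEBlock(trunk$outChannels, 16L)))
  mods <- c(mods, list(nnGlobalAvgPool(),
                       nnLinear(trunk$outChannels, 128L), nnReLU(),
                       shared, nnReLU()))
  branch <- do.call(nnSequential, mods)
  branch$type <- "image_branch"
  branch$outChannels <- trunk$outChannels
  branch
}

#' Build an MSI-FusionNet model
#'
#' Constructs the network described by a [ModelSpec-class]: a six-layer 1D
#' convolutional spectral branch ending in a 64-dimensional embedding, a 2-D
#' backbone image branch ending in a 64-dimensional embedding (the final
#' 128->64 layer is weight-tied across branches when `tieShared`), a
#' cross-modal attention fusion block, and a softmax classifier head.
#' Ablation variants (`fusion` in the spec) share the same builder.
#'
#' @param spec a [modelSpec()]
#' @param seed integer seed for weight initialisation
#' @return a model object (environment) accepted by [modelForward()],
#'   [trainModel()], [countParameters()] and friends
#' @export
buildModel <- function(spec, seed = 1L) {
  stopIfNot(is(spec, "ModelSpec"), "spec must be a ModelSpec")
  withSeed(childSeed(seed, 7), {
    self <- newModule("msi_fusion_net")
    self$spec <- spec
    shared <- if (spec@tieShared) nnLinear(128L, 64L) else NULL
    sharedS <- if (is.null(shared)) nnLinear(128L, 64L) else shared
    sharedI <- if (is.null(shared)) nnLinear(128L, 64L) else shared
    self$spectral <- if (spec@fusion != "image")
      buildSpectralBranch(spec@inputLength, spec@spectralAttention, sharedS)
    self$image <- if (spec@fusion != "spectral")
      buildImageBranch(spec@backbone, spec@imageAttention, sharedI)
    self$cma <- if (spec@fusion == "cma")
      nnCMAFusion(64L, spec@scaleMode, spec@leakySlope)
    clsIn <- if (spec@fusion == "concat") 128L else 64L
    self$classifier <- nnLinear(clsIn, spec@numClasses)
    self$children <- Filter(Negate(is.null),
                            list(self$spectral, self$image, self$cma,
                                 self$classifier))
    self
  })
}

## forward to logits; batch inputs: spectra (1, L, B), images (3, S, S, B)
modelLogits <- function(model, spectra = NULL, images = NULL,
                        training = TRUE) {
  f <- model$spec@fusion
  if (f %in% c("spectral", "cma", "concat")) {
    stopIfNot(!is.null(spectra), "this model variant needs spectra")
    stopIfNot(dim(spectra)[2] == model$spectral$inputLength,
              "expected spectral input length %d, got %d",
              model$spectral$inputLength, dim(spectra)[2])
  }
  if (f %in% c("image", "cma", "concat"))
    stopIfNot(!is.null(images), "this model variant needs images")
  if (f %in% c("cma", "concat"))
    stopIfNot(dim(spectra)[3] == dim(images)[4],
              "unpaired batch: %d spectra vs %d images",
              dim(spectra)[3], dim(images)[4])
  switch(f,
    spectral = model$classifier$forward(
      model$spectral$forward(spectra, training), training),
    image = model$classifier$forward(
      model$image$forward(images, training), training),
    cma = {
      fs <- model$spectral$forward(spectra, training)
      fi <- model$image$forward(images, training)
      model$classifier$forward(model$cma$forward(fi, fs, training), training)
    },
    concat = {
      fs <- model$spectral$forward(spectra, training)
      fi <- model$image$forward(images, training)
      model$classifier$forward(cbind(fi, fs), training)
    })
}

modelBackward <- function(model, gLogits) {
  f <- model$spec@fusion
  g <- model$classifier$backward(gLogits)
  switch(f,
    spectral = model$spectral$backward(g),
    image = model$image$backward(g),
    cma = {
      gf <- model$cma$backward(g)
      model$image$backward(gf$gimg)
      model$spectral$backward(gf$gspec)
    },
    concat = {
      model$image$backward(g[, 1:64, drop = FALSE])
      model$spectral$backward(g[, 65:128, drop = FALSE])
    })
  invisible(NULL)
}

#' Forward pass to class probabilities
#'
#' @param model a model from [buildModel()]
#' @param spectra B x L matrix of spectra (or NULL for image-only models)
#' @param images `(3, S, S, B)` array of images (or NULL for spectral-only)
#' @return B x numClasses matrix of softmax probabilities (rows sum to 1)
#' @export
modelForward <- function(model, spectra = NULL, images = NULL) {
  xs <- if (!is.null(spectra))
    aperm(array(spectra, c(nrow(spectra), 1L, ncol(spectra))), c(2, 3, 1))
  logits <- modelLogits(model, xs, images, training = FALSE)
  clearCaches(model)
  softmaxRows(logits)
}

#' 64-dimensional branch embeddings
#'
#' @param model a model from [buildModel()]
#' @param spectra B x L matrix
#' @return B x 64 feature matrix
#' @export
spectralFeatures <- function(model, spectra) {
  stopIfNot(!is.null(model$spectral), "model has no spectral branch")
  xs <- aperm(array(spectra, c(nrow(spectra), 1L, ncol(spectra))), c(2, 3, 1))
  f <- model$spectral$forward(xs, training = FALSE)
  clearCaches(model)
  f
}

#' @rdname spectralFeatures
#' @param images `(3, S, S, B)` array
#' @export
imageFeatures <- function(model, images) {
  stopIfNot(!is.null(model$image), "model has no image branch")
  f <- model$image$forward(images, training = FALSE)
  clearCaches(model)
  f
}

#' Fuse branch features through cross-modal attention
#'
#' @param model a model with a CMA fusion block
#' @param imageFeat,spectralFeat B x 64 feature matrices
#' @return B x 64 fused features
#' @export
cmaFuse <- function(model, imageFeat, spectralFeat) {
  stopIfNot(!is.null(model$cma), "model has no CMA fusion block")
  f <- model$cma$forward(imageFeat, spectralFeat, training = FALSE)
  clearCaches(model)
  f
}

#' Count trainable parameters and float32 model size
#'
#' @param x a model from [buildModel()] or a [ModelSpec-class] (which is then
#'   built with seed 1)
#' @return list with `count` (trainable parameters) and `sizeMiB` (float32
#'   size, `count * 4 / 2^20`, rounded to 2 decimals)
#' @examples
#' modelSizeMiB(5492844)  # 20.95
#' @export
countParameters <- function(x) {
  model <- if (is(x, "ModelSpec")) buildModel(x, seed = 1L) else x
  cnt <- nParams(model)
  list(count = cnt, sizeMiB = modelSizeMiB(cnt))
}

#' @rdname countParameters
#' @param count a parameter count
#' @export
modelSizeMiB <- function(count) round(count * 4 / 2^20, 2)

#' Architecture summary of the spectral branch
#'
#' The layer table (in/out channels, kernel, stride, padding, BN, activation,
#' per-layer feature size) for a given input length, suitable for CSV export.
#'
#' @param spec a [modelSpec()] (only `inputLength` is used)
#' @return data.frame, one row per layer including the dense head
#' @export
architectureSummary <- function(spec = modelSpec()) {
  plan <- spectralShapePlan(spec@inputLength)
  flat <- attr(plan, "flatten")
  head <- data.frame(
    layer = c("Flatten", "FC1", "FC2", "Share_FC", "Softmax"),
    inChannels = c(NA, flat, 256L, 128L, 64L),
    outChannels = c(flat, 256L, 128L, 64L, spec@numClasses),
    kernel = NA_integer_, stride = NA_integer_, padding = NA_integer_,
    batchNorm = FALSE,
    activation = c("", "ReLU", "ReLU", "ReLU", "Softmax"),
    featureSize = c(flat, 256L, 128L, 64L, spec@numClasses))
  rbind(plan, head)
}
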