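## 2-D backbone registry and native backbone implementations.

.backbones <- new.env(parent = emptyenv())

#' Register a 2-D backbone constructor
#'
#' A backbone constructor is a zero/one-argument function returning a module
#' that maps an image batch `(3, H, W, B)` to a feature map `(C, h, w, B)`
#' and carries an `outChannels` field.
#'
#' @param name backbone name
#' @param constructor constructor function
#' @return invisibly, the name
#' @export
registerBackbone <- function(name, constructor) {
  assign(name, constructor, envir = .backbones)
  invisible(name)
}

#' List registered backbones
#' @return character vector of registered backbone names
#' @export
listBackbones <- function() sort(ls(.backbones))

getBackboneConstructor <- function(name) {
  if (!exists(name, envir = .backbones, inherits = FALSE))
    stop(sprintf("unknown backbone '%s'; registered backbones: %s",
                 name, paste(listBackbones(), collapse = ", ")),
         call. = FALSE)
  get(name, envir = .backbones, inherits = FALSE)
}

## concatenate two (C, H, W, B) maps along channels
bindChannels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1] + db[1], da[2], da[3], da[4]))
  out[seq_len(da[1]), , , ] <- a
  out[da[1] + seq_len(db[1]), , , ] <- b
  out
}

## ShuffleNetV2 basic unit (stride 1): channel split, one half through a
## pw-dw-pw branch, concat, channel shuffle.
shuffleUnitBasic <- function(C) {
  half <- C %/% 2L
  branch <- nnSequential(
    nnConv2d(half, half, 1L, bias = FALSE), nnBatchNorm(half), nnReLU(),
    nnDepthwiseConv2d(half, 3L, 1L, 1L, bias = FALSE), nnBatchNorm(half),
    nnConv2d(half, half, 1L, bias = FALSE), nnBatchNorm(half), nnReLU())
  shuffle <- nnChannelShuffle(C, 2L)
  self <- newModule("shuffle_basic")
  self$children <- list(branch, shuffle)
  self$forward <- function(x, training = TRUE) {
    x1 <- x[seq_len(half), , , , drop = FALSE]
    y2 <- branch$forward(x[half + seq_len(half), , , , drop = FALSE], training)
    shuffle$forward(bindChannels(x1, y2), training)
  }
  self$backward <- function(gy) {
    g <- shuffle$backward(gy)
    g2 <- branch$backward(g[half + seq_len(half), , , , drop = FALSE])
    bindChannels(g[seq_len(half), , , , drop = FALSE], g2)
  }
  self
}

## ShuffleNetV2 downsampling unit (stride 2): both halves convolved.
shuffleUnitDown <- function(cin, cout) {
  half <- cout %/% 2L
  b1 <- nnSequential(
    nnDepthwiseConv2d(cin, 3L, 2L, 1L, bias = FALSE), nnBatchNorm(cin),
    nnConv2d(cin, half, 1L, bias = FALSE), nnBatchNorm(half), nnReLU())
  b2 <- nnSequential(
    nnConv2d(cin, half, 1L, bias = FALSE), nnBatchNorm(half), nnReLU(),
    nnDepthwiseConv2d(half, 3L, 2L, 1L, bias = FALSE), nnBatchNorm(half),
    nnConv2d(half, half, 1L, bias = FALSE), nnBatchNorm(half), nnReLU())
  shuffle <- nnChannelShuffle(cout, 2L)
  self <- newModule("shuffle_down")
  self$children <- list(b1, b2, shuffle)
  self$forward <- function(x, training = TRUE) {
    shuffle$forward(bindChannels(b1$forward(x, training),
                                 b2$forward(x, training)), training)
  }
  self$backward <- function(gy) {
    g <- shuffle$backward(gy)
    ## backward in reverse order of the forward calls
    g2 <- b2$backward(g[half + seq_len(half), , , , drop = FALSE])
    g1 <- b1$backward(g[seq_len(half), , , , drop = FALSE])
    g1 + g2
  }
  self
}

## ShuffleNetV2, 1.0x width: stem conv + maxpool, three stages of
## split/shuffle units, final 1x1 conv to 1024 channels.
buildShuffleNetV2 <- function(widthMult = 1.0) {
  stageOut <- switch(sprintf("%.1f", widthMult),
                     "0.5" = c(24L, 48L, 96L, 192L, 1024L),
                     "1.0" = c(24L, 116L, 232L, 464L, 1024L),
                     "1.5" = c(24L, 176L, 352L, 704L, 1024L),
                     stop("unsupported width multiplier ", widthMult))
  repeats <- c(4L, 8L, 4L)
  mods <- list(nnConv2d(3L, stageOut[1], 3L, 2L, 1L, bias = FALSE),
               nnBatchNorm(stageOut[1]), nnReLU(), nnMaxPool2d(3L, 2L, 1L))
  cin <- stageOut[1]
  for (st in 1:3) {
    cout <- stageOut[st + 1]
    mods <- c(mods, list(shuffleUnitDown(cin, cout)))
    for (i in seq_len(repeats[st] - 1L))
      mods <- c(mods, list(shuffleUnitBasic(cout)))
    cin <- cout
  }
  mods <- c(mods, list(nnConv2d(cin, stageOut[5], 1L, bias = FALSE),
                       nnBatchNorm(stageOut[5]), nnReLU()))
  self <- do.call(nnSequential, mods)
  self$type <- "shufflenet_v2"
  self$outChannels <- stageOut[5]
  self
}

## VGG16 convolutional trunk (13 conv layers, 5 max-pools).
buildVGG16Trunk <- function(...) {
  cfg <- list(64L, 64L, "M", 128L, 128L, "M", 256L, 256L, 256L, "M",
              512L, 512L, 512L, "M", 512L, 512L, 512L, "M")
  mods <- list()
  cin <- 3L
  for (v in cfg) {
    if (identical(v, "M")) {
      mods <- c(mods, list(nnMaxPool2d(2L, 2L, 0L)))
    } else {
      mods <- c(mods, list(nnConv2d(cin, v, 3L, 1L, 1L), nnReLU()))
      cin <- v
    }
  }
  self <- do.call(nnSequential, mods)
  self$type <- "vgg16"
  self$outChannels <- 512L
  self
}

.onLoad <- function(libname, pkgname) {
  registerBackbone("shufflenet_v2", buildShuffleNetV2)
  registerBackbone("vgg16", buildVGG16Trunk)
}
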