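#' Composite a foreground onto a pure black background
#'
#' Keeps image pixels where the mask is set and zeroes everything else,
#' removing background interference so only grain shape, size, texture and
#' colour remain. Idempotent.
#'
#' @param image `(3, H, W)` or H x W x 3 numeric array
#' @param mask logical H x W foreground mask
#' @return array of the same shape as `image`
#' @export
compositeBlack <- function(image, mask) {
  d <- dim(image)
  channelFirst <- d[1] == 3 && length(d) == 3 && !(d[3] == 3 && d[1] != 3)
  hw <- if (channelFirst) d[2:3] else d[1:2]
  stopIfNot(all(dim(mask) == hw), "mask shape does not match image")
  m <- as.numeric(mask)
  if (channelFirst) {
    out <- image * rep(m, each = 3)
  } else {
    out <- image * array(m, d)
  }
  out
}

#' ImageNet channel normalisation statistics
#'
#' Default normalisation for the 2-D branch input (the backbones are
#' ImageNet-era designs); both vectors are per-channel over RGB.
#' @return list with `mean` and `sd`
#' @export
imagenetStats <- function() list(mean = c(0.485, 0.456, 0.406),
                                 sd = c(0.229, 0.224, 0.225))

#' Prepare an image as model input
#'
#' Resizes to `size` x `size` (bilinear), optionally applies a random
#' horizontal flip (training only), and standardises each channel with the
#' given statistics. With `training = FALSE` the function is pure: the output
#' does not depend on the random state.
#'
#' @param image `(3, H, W)` or H x W x 3 array with values in `[0, 1]`
#' @param size output side length, pixels (224 for the full protocol)
#' @param training apply augmentation?
#' @param flipProb horizontal flip probability when training
#' @param stats list with `mean` and `sd` per channel (default ImageNet)
#' @return `(3, size, size)` normalised array
#' @export
prepareModelInput <- function(image, size = 224L, training = FALSE,
                              flipProb = 0.5, stats = imagenetStats()) {
  d <- dim(image)
  stopIfNot(length(d) == 3 && (d[1] == 3 || d[3] == 3),
            "input must be a 3-channel RGB array")
  if (d[1] == 3 && d[3] != 3) image <- aperm(image, c(2, 3, 1))
  resized <- EBImage::resize(EBImage::Image(image, colormode = "Color"),
                             w = size, h = size)
  arr <- array(as.numeric(resized), c(size, size, 3))
  if (training && stats::runif(1) < flipProb)
    arr <- arr[, rev(seq_len(size)), , drop = FALSE]
  for (ch in 1:3)
    arr[, , ch] <- (arr[, , ch] - stats$mean[ch]) / stats$sd[ch]
  aperm(arr, c(3, 1, 2))
}
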