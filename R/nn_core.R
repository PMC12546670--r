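## Minimal neural-network core on base-R arrays.
##
## Layouts: 1D feature maps are (C, L, B) arrays, 2D feature maps are
## (C, H, W, B) arrays, dense features are (B, F) matrices -- channel-first so
## per-channel broadcasts recycle correctly in column-major R.
##
## Every layer is an environment with params/grads lists, a forward(x,
## training) that pushes a cache, and a backward(gy) that pops it (LIFO, so a
## weight-tied layer used twice per step backpropagates correctly). Gradients
## accumulate until zeroGrads().

newModule <- function(type) {
  self <- new.env(parent = globalenv())
  self$type <- type
  self$params <- list()
  self$grads <- list()
  self$stack <- list()
  self$children <- list()
  self
}

pushCache <- function(self, cache) self$stack[[length(self$stack) + 1L]] <- cache

popCache <- function(self) {
  n <- length(self$stack)
  stopIfNot(n > 0, "backward called without a matching forward (%s)", self$type)
  cache <- self$stack[[n]]
  self$stack[[n]] <- NULL
  cache
}

accumGrad <- function(self, name, val) {
  if (is.null(self$grads[[name]])) self$grads[[name]] <- val
  else self$grads[[name]] <- self$grads[[name]] + val
}

## All parameter-bearing modules in a tree, deduplicated by identity so a
## shared (weight-tied) layer is updated once per optimizer step.
collectModules <- function(module, seen = list()) {
  isSeen <- any(vapply(seen, identical, logical(1), module))
  if (!isSeen && length(module$params)) seen[[length(seen) + 1L]] <- module
  for (ch in module$children) seen <- collectModules(ch, seen)
  seen
}

zeroGrads <- function(module) {
  for (m in collectModules(module)) m$grads <- list()
  invisible(NULL)
}

nParams <- function(module) {
  sum(vapply(collectModules(module),
             function(m) sum(vapply(m$params, length, 0L)), 0))
}

uinit <- function(n, fanIn) runif(n, -sqrt(1 / fanIn), sqrt(1 / fanIn))

## ---- dense -----------------------------------------------------------------

nnLinear <- function(nIn, nOut, bias = TRUE) {
  self <- newModule("linear")
  self$params$W <- matrix(uinit(nIn * nOut, nIn), nOut, nIn)
  if (bias) self$params$b <- uinit(nOut, nIn)
  self$forward <- function(x, training = TRUE) {
    pushCache(self, x)
    y <- x %*% t(self$params$W)
    if (!is.null(self$params$b)) y <- sweep(y, 2, self$params$b, "+")
    y
  }
  self$backward <- function(gy) {
    x <- popCache(self)
    accumGrad(self, "W", crossprod(gy, x))
    if (!is.null(self$params$b)) accumGrad(self, "b", colSums(gy))
    gy %*% self$params$W
  }
  self
}

## ---- activations -----------------------------------------------------------

nnReLU <- function() {
  self <- newModule("relu")
  self$forward <- function(x, training = TRUE) {
    pushCache(self, x > 0)
    x * (x > 0)
  }
  self$backward <- function(gy) gy * popCache(self)
  self
}

nnLeakyReLU <- function(slope = 0.01) {
  self <- newModule("leaky_relu")
  self$forward <- function(x, training = TRUE) {
    pos <- x > 0
    pushCache(self, pos)
    x * ifelse(pos, 1, slope)
  }
  self$backward <- function(gy) {
    pos <- popCache(self)
    gy * ifelse(pos, 1, slope)
  }
  self
}

sigmoidFn <- function(x) 1 / (1 + exp(-x))

## ---- batch normalisation ---------------------------------------------------

## Core works on a (C, N) matrix view; wrappers reshape feature maps.
nnBatchNorm <- function(C, eps = 1e-5, momentum = 0.1) {
  self <- newModule("batchnorm")
  self$params$gamma <- rep(1, C)
  self$params$beta <- rep(0, C)
  self$runningMean <- rep(0, C)
  self$runningVar <- rep(1, C)
  self$nUpdates <- 0L
  self$forward <- function(x, training = TRUE) {
    d <- dim(x)
    xm <- matrix(x, C)
    n <- ncol(xm)
    if (training) {
      mu <- rowMeans(xm)
      v <- rowMeans(xm^2) - mu^2
      ## seed the running moments from the first batch: an initialisation of
      ## (0, 1) can dominate small true variances for many steps otherwise
      if (self$nUpdates == 0L) {
        self$runningMean <- mu
        self$runningVar <- v * n / max(n - 1, 1)
      } else {
        self$runningMean <- (1 - momentum) * self$runningMean + momentum * mu
        self$runningVar <- (1 - momentum) * self$runningVar +
          momentum * v * n / max(n - 1, 1)
      }
      self$nUpdates <- self$nUpdates + 1L
    } else {
      mu <- self$runningMean
      v <- self$runningVar
    }
    invstd <- 1 / sqrt(v + eps)
    xhat <- (xm - mu) * invstd
    pushCache(self, list(xhat = xhat, invstd = invstd, d = d,
                         training = training))
    array(self$params$gamma * xhat + self$params$beta, d)
  }
  self$backward <- function(gy) {
    cc <- popCache(self)
    gym <- matrix(gy, C)
    accumGrad(self, "gamma", rowSums(gym * cc$xhat))
    accumGrad(self, "beta", rowSums(gym))
    gxhat <- gym * self$params$gamma
    if (cc$training) {
      n <- ncol(gym)
      gx <- cc$invstd / n *
        (n * gxhat - rowSums(gxhat) - cc$xhat * rowSums(gxhat * cc$xhat))
    } else {
      gx <- gxhat * cc$invstd
    }
    array(gx, cc$d)
  }
  self
}

## ---- 1-D convolution -------------------------------------------------------

convOutLen <- function(L, k, s, p) (L + 2L * p - k) %/% s + 1L

nnConv1d <- function(cin, cout, k, stride = 2L, pad = 1L, bias = TRUE) {
  self <- newModule("conv1d")
  self$cin <- cin; self$cout <- cout; self$k <- k
  self$stride <- stride; self$pad <- pad
  self$params$W <- matrix(uinit(cout * cin * k, cin * k), cout, cin * k)
  if (bias) self$params$b <- uinit(cout, cin * k)
  self$forward <- function(x, training = TRUE) {
    d <- dim(x)
    stopIfNot(length(d) == 3 && d[1] == cin,
              "conv1d expects (C=%d, L, B) input", cin)
    L <- d[2]; B <- d[3]
    Lout <- convOutLen(L, k, stride, pad)
    stopIfNot(Lout >= 1, "input length %d too short for kernel %d", L, k)
    M <- im2col1d_cpp(x, cin, L, B, k, stride, pad)  # (cin*k, Lout*B)
    y <- self$params$W %*% M
    if (!is.null(self$params$b)) y <- y + self$params$b
    pushCache(self, list(M = M, L = L, Lout = Lout, B = B))
    array(y, c(cout, Lout, B))
  }
  self$backward <- function(gy) {
    cc <- popCache(self)
    gym <- matrix(gy, cout)
    accumGrad(self, "W", tcrossprod(gym, cc$M))
    if (!is.null(self$params$b)) accumGrad(self, "b", rowSums(gym))
    dM <- crossprod(self$params$W, gym)              # (cin*k, Lout*B)
    array(col2im1d_cpp(dM, cin, cc$L, cc$B, k, stride, pad),
          c(cin, cc$L, cc$B))
  }
  self
}

## ---- 2-D convolution -------------------------------------------------------

nnConv2d <- function(cin, cout, k, stride = 1L, pad = 0L, bias = TRUE) {
  self <- newModule("conv2d")
  self$params$W <- matrix(uinit(cout * cin * k * k, cin * k * k),
                          cout, cin * k * k)
  if (bias) self$params$b <- uinit(cout, cin * k * k)
  pointwise <- k == 1L && stride == 1L && pad == 0L
  self$forward <- function(x, training = TRUE) {
    d <- dim(x)
    stopIfNot(length(d) == 4 && d[1] == cin,
              "conv2d expects (C=%d, H, W, B) input", cin)
    H <- d[2]; W <- d[3]; B <- d[4]
    if (pointwise) {
      ## 1x1 convolution: a linear map over channels at every position
      M <- matrix(x, cin)
      y <- self$params$W %*% M
      if (!is.null(self$params$b)) y <- y + self$params$b
      pushCache(self, list(M = M, d = d))
      return(array(y, c(cout, H, W, B)))
    }
    Ho <- convOutLen(H, k, stride, pad); Wo <- convOutLen(W, k, stride, pad)
    M <- im2col2d_cpp(x, cin, H, W, B, k, stride, pad) # (cin*k*k, Ho*Wo*B)
    y <- self$params$W %*% M
    if (!is.null(self$params$b)) y <- y + self$params$b
    pushCache(self, list(M = M, H = H, W = W, B = B))
    array(y, c(cout, Ho, Wo, B))
  }
  self$backward <- function(gy) {
    cc <- popCache(self)
    gym <- matrix(gy, cout)
    accumGrad(self, "W", tcrossprod(gym, cc$M))
    if (!is.null(self$params$b)) accumGrad(self, "b", rowSums(gym))
    dM <- crossprod(self$params$W, gym)
    if (pointwise) return(array(dM, cc$d))
    array(col2im2d_cpp(dM, cin, cc$H, cc$W, cc$B, k, stride, pad),
          c(cin, cc$H, cc$W, cc$B))
  }
  self
}

## Depthwise 3x3-style convolution: one filter per channel, groups == C.
nnDepthwiseConv2d <- function(C, k = 3L, stride = 1L, pad = 1L, bias = TRUE) {
  self <- newModule("dwconv2d")
  self$params$W <- array(uinit(C * k * k, k * k), c(C, k, k))
  if (bias) self$params$b <- uinit(C, k * k)
  self$forward <- function(x, training = TRUE) {
    d <- dim(x)
    stopIfNot(length(d) == 4 && d[1] == C,
              "dwconv expects (C=%d, H, W, B) input", C)
    H <- d[2]; W <- d[3]; B <- d[4]
    Ho <- convOutLen(H, k, stride, pad); Wo <- convOutLen(W, k, stride, pad)
    y <- array(dwconv_fw_cpp(x, self$params$W, C, H, W, B, k, stride, pad),
               c(C, Ho, Wo, B))
    if (!is.null(self$params$b)) y <- y + self$params$b
    pushCache(self, list(x = x, H = H, W = W, B = B))
    y
  }
  self$backward <- function(gy) {
    cc <- popCache(self)
    res <- dwconv_bw_cpp(cc$x, self$params$W, gy, C, cc$H, cc$W, cc$B,
                         k, stride, pad)
    accumGrad(self, "W", array(res$dw, c(C, k, k)))
    if (!is.null(self$params$b)) accumGrad(self, "b", rowSums(matrix(gy, C)))
    array(res$dx, c(C, cc$H, cc$W, cc$B))
  }
  self
}

## ---- pooling ---------------------------------------------------------------

nnMaxPool2d <- function(k = 3L, stride = 2L, pad = 1L) {
  self <- newModule("maxpool2d")
  self$forward <- function(x, training = TRUE) {
    d <- dim(x)
    Ho <- convOutLen(d[2], k, stride, pad)
    Wo <- convOutLen(d[3], k, stride, pad)
    res <- maxpool_fw_cpp(x, d[1], d[2], d[3], d[4], k, stride, pad)
    pushCache(self, list(amax = res$amax, d = d))
    array(res$y, c(d[1], Ho, Wo, d[4]))
  }
  self$backward <- function(gy) {
    cc <- popCache(self)
    ## amax holds 0-based flat indices into the input
    array(maxpool_bw_cpp(gy, cc$amax, prod(cc$d)), cc$d)
  }
  self
}

## Global average pool over all spatial positions: (C, ..., B) -> (B, C).
nnGlobalAvgPool <- function() {
  self <- newModule("gap")
  self$forward <- function(x, training = TRUE) {
    d <- dim(x)
    C <- d[1]; B <- d[length(d)]
    n <- prod(d) / (C * B)
    xm <- array(x, c(C, n, B))
    pushCache(self, list(d = d, n = n))
    t(colMeans(aperm(xm, c(2, 1, 3))))               # (B, C)
  }
  self$backward <- function(gy) {
    cc <- popCache(self)
    C <- cc$d[1]; B <- cc$d[length(cc$d)]
    g <- array(0, c(C, cc$n, B))
    for (b in seq_len(B)) g[, , b] <- gy[b, ] / cc$n
    array(g, cc$d)
  }
  self
}

## Flatten (C, L, B) -> (B, C*L)
nnFlatten <- function() {
  self <- newModule("flatten")
  self$forward <- function(x, training = TRUE) {
    d <- dim(x)
    pushCache(self, d)
    t(matrix(x, prod(d) / d[length(d)]))
  }
  self$backward <- function(gy) array(t(gy), popCache(self))
  self
}

## Channel shuffle with g groups on (C, H, W, B)
nnChannelShuffle <- function(C, groups = 2L) {
  self <- newModule("shuffle")
  n <- C %/% groups
  perm <- as.vector(t(matrix(seq_len(C), n, groups)))
  inv <- order(perm)
  self$forward <- function(x, training = TRUE) x[perm, , , , drop = FALSE]
  self$backward <- function(gy) gy[inv, , , , drop = FALSE]
  self
}

## ---- containers ------------------------------------------------------------

nnSequential <- function(...) {
  self <- newModule("sequential")
  self$children <- list(...)
  self$forward <- function(x, training = TRUE) {
    for (m in self$children) x <- m$forward(x, training)
    x
  }
  self$backward <- function(gy) {
    for (m in rev(self$children)) gy <- m$backward(gy)
    gy
  }
  self
}

## ---- loss ------------------------------------------------------------------

softmaxRows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

## Cross-entropy over (B, K) logits; returns loss and gradient wrt logits.
crossEntropy <- function(logits, labels) {
  p <- softmaxRows(logits)
  B <- nrow(logits)
  idx <- cbind(seq_len(B), as.integer(labels))
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  g <- p
  g[idx] <- g[idx] - 1
  list(loss = loss, grad = g / B)
}

## ---- optimizer -------------------------------------------------------------

adamOptimizer <- function(module, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                          eps = 1e-8) {
  self <- new.env(parent = globalenv())
  self$modules <- collectModules(module)
  ## flat slot table: one (module, param-name) pair per trainable tensor
  slotMod <- list(); slotName <- character(0)
  for (m in self$modules) for (nm in names(m$params)) {
    slotMod[[length(slotMod) + 1L]] <- m
    slotName <- c(slotName, nm)
  }
  nSlot <- length(slotMod)
  self$stateM <- vector("list", nSlot)
  self$stateV <- vector("list", nSlot)
  self$t <- 0L
  self$lr <- lr
  self$step <- function() {
    self$t <- self$t + 1L
    bc1 <- 1 - beta1^self$t
    bc2 <- 1 - beta2^self$t
    for (i in seq_len(nSlot)) {
      m <- slotMod[[i]]; nm <- slotName[i]
      g <- m$grads[[nm]]
      if (is.null(g)) next
      if (is.null(self$stateM[[i]])) {
        self$stateM[[i]] <- numeric(length(g))
        self$stateV[[i]] <- numeric(length(g))
      }
      ## adam_step_cpp updates the optimizer-private moment buffers in place
      m$params[[nm]] <- adam_step_cpp(m$params[[nm]], g, self$stateM[[i]],
                                      self$stateV[[i]], self$lr, beta1,
                                      beta2, eps, bc1, bc2)
    }
    invisible(NULL)
  }
  self$zeroGrads <- function() {
    for (m in self$modules) m$grads <- list()
    invisible(NULL)
  }
  self
}

## ---- weight snapshots ------------------------------------------------------

getWeights <- function(module) lapply(collectModules(module), function(m)
  list(params = m$params, runningMean = m$runningMean,
       runningVar = m$runningVar))

setWeights <- function(module, weights) {
  mods <- collectModules(module)
  stopIfNot(length(mods) == length(weights),
            "weight snapshot does not match the model architecture")
  for (i in seq_along(mods)) {
    same <- all(mapply(function(a, b) identical(dim(a), dim(b)) &&
                         length(a) == length(b),
                       mods[[i]]$params, weights[[i]]$params))
    stopIfNot(isTRUE(same), "weight shapes incompatible at module %d", i)
    mods[[i]]$params <- weights[[i]]$params
    if (!is.null(weights[[i]]$runningMean)) {
      mods[[i]]$runningMean <- weights[[i]]$runningMean
      mods[[i]]$runningVar <- weights[[i]]$runningVar
    }
  }
  invisible(module)
}
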