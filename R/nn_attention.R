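## Attention modules: CBAM-style channel attention for the 1-D spectral
## branch, squeeze-and-excitation for the 2-D image branch, and the
## cross-modal attention (CMA) fusion block.

## Channel attention over a (C, N, B) 1-D feature map:
##   w = sigmoid(MLP(avgpool(F)) + MLP(maxpool(F))), output = w (*) F
## with a shared two-layer bottleneck perceptron (reduction r).
nnChannelAttention1d <- function(C, r = 8L) {
  stopIfNot(C %% r == 0, "channels (%d) must be divisible by r (%d)", C, r)
  self <- newModule("channel_attention")
  h <- C %/% r
  self$params$W1 <- matrix(uinit(h * C, C), h, C)
  self$params$b1 <- uinit(h, C)
  self$params$W2 <- matrix(uinit(C * h, h), C, h)
  self$params$b2 <- uinit(C, h)
  mlp <- function(z) {                               # z: (C, B)
    a <- self$params$W1 %*% z + self$params$b1
    hpos <- a > 0
    list(out = self$params$W2 %*% (a * hpos) + self$params$b2, a = a,
         hpos = hpos, z = z)
  }
  mlpBack <- function(cc, gout) {
    accumGrad(self, "W2", tcrossprod(gout, cc$a * cc$hpos))
    accumGrad(self, "b2", rowSums(gout))
    ga <- crossprod(self$params$W2, gout) * cc$hpos
    accumGrad(self, "W1", tcrossprod(ga, cc$z))
    accumGrad(self, "b1", rowSums(ga))
    crossprod(self$params$W1, ga)
  }
  self$forward <- function(x, training = TRUE) {
    d <- dim(x)
    stopIfNot(length(d) == 3 && d[1] == C,
              "channel attention expects (C=%d, N, B)", C)
    N <- d[2]; B <- d[3]
    avg <- colMeans(aperm(x, c(2, 1, 3)), dims = 1)  # (C, B)
    if (!is.matrix(avg)) avg <- matrix(avg, C, B)
    ## max over positions with first-occurrence argmax, vectorised over (C, B)
    mx <- matrix(x[, 1, ], C, B)
    amaxIdx <- matrix(1L, C, B)
    if (N > 1) for (nn in 2:N) {
      sl <- matrix(x[, nn, ], C, B)
      upd <- sl > mx
      amaxIdx[upd] <- nn
      mx[upd] <- sl[upd]
    }
    fa <- mlp(avg)
    fm <- mlp(mx)
    w <- sigmoidFn(fa$out + fm$out)                  # (C, B)
    wFull <- aperm(array(w, c(C, B, N)), c(1, 3, 2))
    pushCache(self, list(x = x, w = w, wFull = wFull, fa = fa, fm = fm,
                         amaxIdx = amaxIdx, N = N, B = B))
    x * wFull
  }
  self$backward <- function(gy) {
    cc <- popCache(self)
    N <- cc$N; B <- cc$B
    gx <- gy * cc$wFull
    gw <- colSums(aperm(gy * cc$x, c(2, 1, 3)), dims = 1)  # (C, B)
    if (!is.matrix(gw)) gw <- matrix(gw, C, B)
    gpre <- gw * cc$w * (1 - cc$w)
    gavg <- mlpBack(cc$fa, gpre)
    gmax <- mlpBack(cc$fm, gpre)
    ## spread the avg-pool gradient, scatter the max-pool gradient
    gx <- gx + aperm(array(gavg / N, c(C, B, N)), c(1, 3, 2))
    sc <- cbind(rep(seq_len(C), B), as.vector(cc$amaxIdx),
                rep(seq_len(B), each = C))
    gx[sc] <- gx[sc] + as.vector(gmax)
    gx
  }
  self$attentionWeights <- function(x) {
    y <- self$forward(x, training = FALSE)
    cc <- popCache(self)
    cc$w
  }
  self
}

## Squeeze-and-excitation over a (C, H, W, B) map:
##   z = global average pool, s = sigmoid(W2 relu(W1 z)), output = s (*) u.
nnSEBlock <- function(C, r = 16L) {
  stopIfNot(C %% r == 0, "channels (%d) must be divisible by r (%d)", C, r)
  self <- newModule("se_block")
  h <- C %/% r
  self$params$W1 <- matrix(uinit(h * C, C), h, C)
  self$params$b1 <- uinit(h, C)
  self$params$W2 <- matrix(uinit(C * h, h), C, h)
  self$params$b2 <- uinit(C, h)
  self$forward <- function(x, training = TRUE) {
    d <- dim(x)
    stopIfNot(length(d) == 4 && d[1] == C, "SE block expects (C=%d, H, W, B)", C)
    n <- d[2] * d[3]; B <- d[4]
    z <- colMeans(aperm(array(x, c(C, n, B)), c(2, 1, 3)), dims = 1) # (C, B)
    if (!is.matrix(z)) z <- matrix(z, C, B)
    a <- self$params$W1 %*% z + self$params$b1
    hpos <- a > 0
    s <- sigmoidFn(self$params$W2 %*% (a * hpos) + self$params$b2)   # (C, B)
    sFull <- array(apply(s, 2, rep, times = n), d)
    pushCache(self, list(x = x, z = z, a = a, hpos = hpos, s = s,
                         sFull = sFull, n = n, B = B, d = d))
    x * sFull
  }
  self$backward <- function(gy) {
    cc <- popCache(self)
    gx <- gy * cc$sFull
    gs <- colSums(aperm(array(gy * cc$x, c(C, cc$n, cc$B)), c(2, 1, 3)),
                  dims = 1)
    if (!is.matrix(gs)) gs <- matrix(gs, C, cc$B)
    gpre <- gs * cc$s * (1 - cc$s)
    accumGrad(self, "W2", tcrossprod(gpre, cc$a * cc$hpos))
    accumGrad(self, "b2", rowSums(gpre))
    ga <- crossprod(self$params$W2, gpre) * cc$hpos
    accumGrad(self, "W1", tcrossprod(ga, cc$z))
    accumGrad(self, "b1", rowSums(ga))
    gz <- crossprod(self$params$W1, ga)               # (C, B)
    gx + array(apply(gz / cc$n, 2, rep, times = cc$n), cc$d)
  }
  self
}

## Cross-modal attention fusion of two (B, C') feature matrices.
## Each feature vector is treated as a length-C' channel sequence: the image
## features provide queries, the spectral features keys and values through
## 1x1 projections (linear maps on C' channels), the C' x C' attention matrix
## is row-softmaxed, and the output re-projection is added back to the image
## features (residual), followed optionally by batch norm + leaky ReLU.
nnCMAFusion <- function(C = 64L, scaleMode = c("sqrt", "dim"),
                        leakySlope = 0.01, postNorm = TRUE) {
  scaleMode <- match.arg(scaleMode)
  self <- newModule("cma_fusion")
  for (nm in c("Wq", "Wk", "Wv", "Wo"))
    self$params[[nm]] <- matrix(uinit(C * C, C), C, C)
  for (nm in c("bq", "bk", "bv", "bo")) self$params[[nm]] <- uinit(C, C)
  self$scale <- if (scaleMode == "sqrt") sqrt(C) else C
  self$postNorm <- postNorm
  if (postNorm) {
    self$bn <- nnBatchNorm(C)
    self$act <- nnLeakyReLU(leakySlope)
    self$children <- list(self$bn, self$act)
  }
  self$forward <- function(fimg, fspec, training = TRUE) {
    B <- nrow(fimg)
    stopIfNot(ncol(fimg) == C && ncol(fspec) == C,
              "both branch features must be %d-dimensional", C)
    Q <- sweep(fimg %*% t(self$params$Wq), 2, self$params$bq, "+")
    K <- sweep(fspec %*% t(self$params$Wk), 2, self$params$bk, "+")
    V <- sweep(fspec %*% t(self$params$Wv), 2, self$params$bv, "+")
    A <- vector("list", B)
    Z <- matrix(0, B, C)
    for (b in seq_len(B)) {
      S <- tcrossprod(Q[b, ], K[b, ]) / self$scale    # C x C
      A[[b]] <- softmaxRows(S)
      Z[b, ] <- A[[b]] %*% V[b, ]
    }
    fused <- fimg + sweep(Z %*% t(self$params$Wo), 2, self$params$bo, "+")
    pushCache(self, list(fimg = fimg, fspec = fspec, Q = Q, K = K, V = V,
                         A = A, Z = Z))
    if (self$postNorm) {
      fused <- t(self$bn$forward(t(fused), training))
      fused <- self$act$forward(fused, training)
    }
    fused
  }
  self$backward <- function(gy) {
    cc <- popCache(self)
    if (self$postNorm) {
      gy <- self$act$backward(gy)
      gy <- t(self$bn$backward(t(gy)))
    }
    B <- nrow(gy)
    accumGrad(self, "Wo", crossprod(gy, cc$Z))
    accumGrad(self, "bo", colSums(gy))
    gZ <- gy %*% self$params$Wo
    gQ <- matrix(0, B, C); gK <- matrix(0, B, C); gV <- matrix(0, B, C)
    for (b in seq_len(B)) {
      A <- cc$A[[b]]
      dA <- tcrossprod(gZ[b, ], cc$V[b, ])            # C x C
      gV[b, ] <- crossprod(A, gZ[b, ])
      dS <- A * (dA - rowSums(dA * A))                # row-softmax backward
      gQ[b, ] <- dS %*% cc$K[b, ] / self$scale
      gK[b, ] <- crossprod(dS, cc$Q[b, ]) / self$scale
    }
    accumGrad(self, "Wq", crossprod(gQ, cc$fimg))
    accumGrad(self, "bq", colSums(gQ))
    accumGrad(self, "Wk", crossprod(gK, cc$fspec))
    accumGrad(self, "bk", colSums(gK))
    accumGrad(self, "Wv", crossprod(gV, cc$fspec))
    accumGrad(self, "bv", colSums(gV))
    gimg <- gy + gQ %*% self$params$Wq
    gspec <- gK %*% self$params$Wk + gV %*% self$params$Wv
    list(gimg = gimg, gspec = gspec)
  }
  self$attentionMatrices <- function(fimg, fspec) {
    self$forward(fimg, fspec, training = FALSE)
    cc <- popCache(self)
    cc$A
  }
  self
}
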