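nsf <- asNamespace("msifusion")

test_that("spectral branch shape propagation matches the layer table", {
  plan <- spectralShapePlan(480)
  expect_equal(plan$featureSize, c(238, 117, 58, 28, 14, 7))
  expect_equal(plan$outChannels, c(16, 32, 64, 128, 256, 512))
  expect_equal(plan$kernel, c(7, 7, 5, 5, 3, 3))
  expect_equal(attr(plan, "flatten"), 3584)
  ## derived: a 100-length input propagates by the same arithmetic
  oracle <- function(L, ks) { for (k in ks) L <- (L + 2 - k) %/% 2 + 1; L }
  expect_equal(spectralShapePlan(100)$featureSize[6],
               oracle(100, c(7, 7, 5, 5, 3, 3)))
})

test_that("spectral branch forward produces 64-d features and checks length", {
  spec <- modelSpec(inputLength = 480L, fusion = "spectral")
  m <- buildModel(spec, seed = 1)
  f <- spectralFeatures(m, matrix(rnorm(3 * 480), 3))
  expect_equal(dim(f), c(3, 64))
  expect_true(all(is.finite(f)))
  ## zero input also maps to finite features
  f0 <- spectralFeatures(m, matrix(0, 2, 480))
  expect_true(all(is.finite(f0)))
  expect_error(modelForward(m, matrix(0, 2, 100)), "480")
})

test_that("channel attention weights follow the sigmoid-gate analytics", {
  ca <- nsf$nnChannelAttention1d(8, 4)
  ## zeroed MLP: every weight is sigmoid(0) = 0.5, output halves the input
  for (nm in names(ca$params)) ca$params[[nm]][] <- 0
  x <- array(rnorm(8 * 5 * 3), c(8, 5, 3))
  y <- ca$forward(x, training = FALSE)
  nsf$clearCaches(ca)
  expect_equal(y, 0.5 * x, tolerance = 1e-12)

  ## position-constant input: avg- and max-pooled descriptors coincide, so
  ## the gate reduces to sigmoid(2 * MLP(z))
  ca2 <- nsf$nnChannelAttention1d(8, 4)
  z <- matrix(rnorm(8 * 3), 8)
  xconst <- array(rep(as.vector(z), times = 5), c(8, 3, 5))
  xconst <- aperm(xconst, c(1, 3, 2))       # (C, N, B), constant over N
  w <- ca2$attentionWeights(xconst)
  h <- pmax(ca2$params$W1 %*% z + ca2$params$b1, 0)
  o <- ca2$params$W2 %*% h + ca2$params$b2
  expect_equal(w, 1 / (1 + exp(-2 * o)), tolerance = 1e-12)
  for (i in 1:25) {
    w <- ca2$attentionWeights(array(rnorm(8 * 5 * 2, sd = 5), c(8, 5, 2)))
    expect_true(all(w > 0 & w < 1))
  }
})

test_that("SE block matches zero-weight and pencil-and-paper forwards", {
  se <- nsf$nnSEBlock(8, 4)
  for (nm in names(se$params)) se$params[[nm]][] <- 0
  x <- array(rnorm(8 * 3 * 3 * 2), c(8, 3, 3, 2))
  y <- se$forward(x, training = FALSE)
  nsf$clearCaches(se)
  expect_equal(y, 0.5 * x, tolerance = 1e-12)

  ## single-channel toy with hand-set 1x1 weights
  se1 <- nsf$nnSEBlock(1, 1)
  se1$params$W1[] <- 2;  se1$params$b1[] <- 0.5
  se1$params$W2[] <- -1; se1$params$b2[] <- 0.2
  cst <- 0.3
  x1 <- array(cst, c(1, 4, 4, 1))
  sHand <- 1 / (1 + exp(-(-1 * max(2 * cst + 0.5, 0) + 0.2)))
  y1 <- se1$forward(x1, training = FALSE)
  nsf$clearCaches(se1)
  expect_equal(as.vector(y1), rep(sHand * cst, 16), tolerance = 1e-12)

  ## the gate shrinks every channel: ||x~_c|| <= ||u_c||
  se2 <- nsf$nnSEBlock(8, 4)
  x2 <- array(rnorm(8 * 3 * 3 * 2), c(8, 3, 3, 2))
  y2 <- se2$forward(x2, training = FALSE)
  nsf$clearCaches(se2)
  expect_true(all(abs(y2) <= abs(x2) + 1e-12))
  expect_error(nsf$nnSEBlock(10, 4), "divisible")
})

test_that("cross-modal attention is row-normalised with a residual identity", {
  spec <- modelSpec(inputLength = 64L, imageSize = 32L)
  m <- buildModel(spec, seed = 2)
  fi <- matrix(rnorm(3 * 64), 3); fs <- matrix(rnorm(3 * 64), 3)
  A <- m$cma$attentionMatrices(fi, fs)
  for (a in A) expect_equal(rowSums(a), rep(1, 64), tolerance = 1e-6)

  ## zero the output projection, disable post-processing: fused == F_image
  cma <- nsf$nnCMAFusion(64, "sqrt", postNorm = FALSE)
  cma$params$Wo[] <- 0; cma$params$bo[] <- 0
  fused <- cma$forward(fi, fs, training = FALSE)
  expect_identical(fused, fi)

  ## constant Q and K give uniform attention and Z = mean of V
  cma2 <- nsf$nnCMAFusion(64, "sqrt", postNorm = FALSE)
  cma2$params$Wq[] <- 0; cma2$params$bq[] <- 1
  cma2$params$Wk[] <- 0; cma2$params$bk[] <- 1
  A2 <- cma2$attentionMatrices(fi, fs)
  expect_equal(A2[[1]], matrix(1 / 64, 64, 64), tolerance = 1e-12)
  V <- sweep(fs %*% t(cma2$params$Wv), 2, cma2$params$bv, "+")
  fused2 <- cma2$forward(fi, fs, training = FALSE)
  Z <- matrix(rowMeans(V), nrow(fi), 64)
  expect_equal(fused2,
               fi + sweep(Z %*% t(cma2$params$Wo), 2, cma2$params$bo, "+"),
               tolerance = 1e-12)
})

test_that("parameter accounting matches a closed-form oracle and the size relation", {
  ## closed form for the spectral-only variant from the layer table
  plan <- spectralShapePlan(480)
  convP <- sum(plan$inChannels * plan$outChannels * plan$kernel + plan$outChannels)
  bnP <- sum(2 * plan$outChannels)
  attnP <- (512 %/% 8) * 512 + 512 %/% 8 + 512 * (512 %/% 8) + 512
  flat <- attr(plan, "flatten")
  fcP <- (flat * 256 + 256) + (256 * 128 + 128) + (128 * 64 + 64)
  clsP <- 64 * 12 + 12
  oracle <- convP + bnP + attnP + fcP + clsP
  got <- countParameters(modelSpec(inputLength = 480L, fusion = "spectral"))
  expect_equal(got$count, oracle)
  expect_equal(got$sizeMiB, round(oracle * 4 / 2^20, 2))

  ## a single 128 -> 64 linear map with bias
  expect_equal(nsf$nParams(nsf$nnLinear(128, 64)), 8256)

  ## float32 size of published parameter counts, to 2 decimals
  expect_equal(modelSizeMiB(5492844), 20.95)
  expect_equal(modelSizeMiB(23500428), 89.65)
  expect_equal(modelSizeMiB(4811232), 18.35)
  expect_equal(modelSizeMiB(7043216), 26.87)
})

test_that("the backbone registry swaps trunks without changing the interface", {
  expect_true(all(c("shufflenet_v2", "vgg16") %in% listBackbones()))
  expect_error(buildModel(modelSpec(backbone = "resnet50")), "shufflenet_v2")

  img <- array(rnorm(3 * 32 * 32 * 2), c(3, 32, 32, 2))
  counts <- sapply(c("shufflenet_v2", "vgg16"), function(bk) {
    m <- buildModel(modelSpec(inputLength = 64L, imageSize = 32L,
                              backbone = bk, fusion = "image"), seed = 1)
    f <- imageFeatures(m, img)
    expect_equal(dim(f), c(2, 64))
    expect_true(all(is.finite(f)))
    countParameters(m)$count
  })
  expect_false(counts[1] == counts[2])
})

test_that("full-size image branch accepts 224 x 224 input", {
  m <- buildModel(modelSpec(inputLength = 480L), seed = 1)
  img <- array(rnorm(3 * 224 * 224), c(3, 224, 224, 1))
  f <- imageFeatures(m, img)
  expect_equal(dim(f), c(1, 64))
  f0 <- imageFeatures(m, array(0, c(3, 224, 224, 1)))
  expect_true(all(is.finite(f0)))
})

test_that("model probabilities are a proper softmax over 12 classes", {
  spec <- modelSpec(inputLength = 64L, imageSize = 32L)
  m <- buildModel(spec, seed = 3)
  sp <- matrix(rnorm(4 * 64), 4)
  img <- array(rnorm(3 * 32 * 32 * 4), c(3, 32, 32, 4))
  p <- modelForward(m, sp, img)
  expect_equal(dim(p), c(4, 12))
  expect_equal(rowSums(p), rep(1, 4), tolerance = 1e-12)
  expect_true(all(p > 0))

  ## softmax shift invariance
  z <- matrix(rnorm(3 * 12), 3)
  expect_equal(nsf$softmaxRows(z), nsf$softmaxRows(z + 5), tolerance = 1e-12)

  ## unpaired batches are rejected
  expect_error(
    nsf$modelLogits(m, array(0, c(1, 64, 3)), array(0, c(3, 32, 32, 2))),
    "unpaired")
})

test_that("one optimizer step moves parameters in both branches", {
  spec <- modelSpec(inputLength = 64L, imageSize = 32L)
  m <- buildModel(spec, seed = 4)
  before <- list(spec = m$spectral$children[[1]]$params$W,
                 img = m$image$children[[1]]$children[[1]]$params$W,
                 cma = m$cma$params$Wq)
  xs <- array(rnorm(64 * 8), c(1, 64, 8))
  xi <- array(rnorm(3 * 32 * 32 * 8), c(3, 32, 32, 8))
  logits <- nsf$modelLogits(m, xs, xi, TRUE)
  ce <- nsf$crossEntropy(logits, rep(1:4, 2))
  nsf$modelBackward(m, ce$grad)
  opt <- nsf$adamOptimizer(m, lr = 1e-3)
  opt$step()
  expect_false(isTRUE(all.equal(before$spec,
                                m$spectral$children[[1]]$params$W)))
  expect_false(isTRUE(all.equal(before$img,
                                m$image$children[[1]]$children[[1]]$params$W)))
  expect_false(isTRUE(all.equal(before$cma, m$cma$params$Wq)))
})

test_that("ablation constructors share structure and differ only as stated", {
  L <- 64L
  full <- buildModel(modelSpec(inputLength = L, imageSize = 32L), seed = 1)
  noAttn <- buildModel(modelSpec(inputLength = L, imageSize = 32L,
                                 fusion = "concat", spectralAttention = FALSE,
                                 imageAttention = FALSE), seed = 1)
  spOnly <- buildModel(modelSpec(inputLength = L, fusion = "spectral"), seed = 1)
  imOnly <- buildModel(modelSpec(inputLength = L, imageSize = 32L,
                                 fusion = "image"), seed = 1)
  expect_null(spOnly$image); expect_null(spOnly$cma)
  expect_null(imOnly$spectral); expect_null(imOnly$cma)
  expect_null(noAttn$cma)
  expect_false(is.null(full$cma))
  ## classifier widths: 64 for all but the concat variant (128)
  expect_equal(ncol(full$classifier$params$W), 64)
  expect_equal(ncol(noAttn$classifier$params$W), 128)
})

test_that("architecture summary exports the full layer table", {
  tb <- architectureSummary(modelSpec(inputLength = 480L))
  expect_equal(nrow(tb), 11)   # 6 conv + flatten + 3 fc + softmax
  expect_equal(tb$featureSize[tb$layer == "Flatten"], 3584)
  expect_equal(tb$featureSize[tb$layer == "Share_FC"], 64)
})
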