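nsf <- asNamespace("msifusion")

test_that("stratified splitting honours the 8:2 design and partitions folds", {
  labels <- factor(rep(1:12, each = 300))   # the full 3600-grain design
  sp <- makeSplits(labels, 0.2, 5, seed = 1)
  expect_equal(length(sp$testIds), 720)
  expect_equal(length(sp$trainIds), 2880)
  expect_equal(sort(c(sp$trainIds, sp$testIds)), seq_len(3600))
  ## per-class stratification, exact at these counts
  expect_equal(as.vector(table(labels[sp$testIds])), rep(60, 12))
  ## every training sample validates exactly once; folds balanced within 1
  expect_equal(length(sp$foldId), 2880)
  perFold <- table(sp$foldId, labels[sp$trainIds])
  expect_lte(diff(range(perFold)), 1)

  ## deterministic given the seed, different otherwise
  expect_identical(sp, makeSplits(labels, 0.2, 5, seed = 1))
  expect_false(identical(sp$testIds,
                         makeSplits(labels, 0.2, 5, seed = 2)$testIds))

  expect_error(makeSplits(factor(c(1, 1, 2)), k = 5), "fewer than")
})

test_that("evaluation metrics match a pencil-and-paper 3-class oracle", {
  truth <- c(1, 1, 1, 1, 2, 2, 2, 3, 3, 3)
  pred  <- c(1, 1, 2, 3, 2, 2, 1, 3, 3, 1)
  rep3 <- nsf$buildEvalReport(truth, pred, 3)
  expect_equal(rep3@accuracy, 6 / 10)
  ## per class: P1 = 2/4, R1 = 2/4; P2 = 2/3, R2 = 2/3; P3 = 2/3, R3 = 2/3
  expect_equal(rep3@perClass$precision, c(2/4, 2/3, 2/3))
  expect_equal(rep3@perClass$recall, c(2/4, 2/3, 2/3))
  expect_equal(rep3@perClass$f1,
               2 * rep3@perClass$precision * rep3@perClass$recall /
                 (rep3@perClass$precision + rep3@perClass$recall))
  expect_equal(rep3@precision, mean(c(2/4, 2/3, 2/3)))
  ## confusion conservation
  expect_equal(rowSums(rep3@confusion), c(truth = 4, truth = 3, truth = 3),
               ignore_attr = TRUE)
  expect_equal(sum(rep3@confusion), 10)
  expect_equal(rowSums(rep3@confusionPct), rep(100, 3), ignore_attr = TRUE)

  ## macro precision is invariant under a relabeling permutation
  perm <- c(3, 1, 2)
  repP <- nsf$buildEvalReport(perm[truth], perm[pred], 3)
  expect_equal(repP@precision, rep3@precision)
  expect_equal(repP@recall, rep3@recall)

  ## perfect predictions: accuracy 1 and a diagonal confusion matrix
  repI <- nsf$buildEvalReport(truth, truth, 3)
  expect_equal(repI@accuracy, 1)
  expect_true(all(repI@confusion[upper.tri(repI@confusion)] == 0))
  expect_true(all(repI@confusion[lower.tri(repI@confusion)] == 0))
})

test_that("accuracy identity holds to machine precision on random predictions", {
  set.seed(8)
  for (i in 1:5) {
    truth <- sample(1:4, 50, replace = TRUE)
    pred <- sample(1:4, 50, replace = TRUE)
    r <- nsf$buildEvalReport(truth, pred, 4)
    expect_equal(r@accuracy, mean(truth == pred), tolerance = 1e-12)
  }
})

## small spectra-only task shared by the protocol tests below; each class
## gets one deep private absorption dip so the task is cleanly separable
protoSet <- function(seed = 1L, nPerClass = 25L) {
  depths <- matrix(0, 4, 6)
  depths[cbind(1:4, c(1, 3, 5, 6))] <- 0.5
  cfg <- spectralSimConfig(nClasses = 4L, nPerClass = nPerClass, nBands = 64L,
                           edgeHead = 2L, edgeTail = 4L, noiseSd = 0.005,
                           classPeakDepths = depths, seed = seed)
  sp <- generateSpectra(cfg)
  spectra <- sp$spectra[, 3:60]
  n <- nrow(spectra)
  new("MultiModalSet", spectra = spectra,
      images = replicate(n, array(0, c(3, 2, 2)), simplify = FALSE),
      labels = sp$labels, sampleId = sprintf("s%03d", seq_len(n)))
}

protoBuilder <- function(numClasses = 4L) function(seed)
  buildModel(modelSpec(inputLength = 58L, numClasses = numClasses,
                       fusion = "spectral"), seed = seed)

test_that("cross-validation trains one model per fold and returns the best weights", {
  set <- protoSet()
  splits <- makeSplits(sampleLabels(set), 0.2, 5, seed = 1)
  cfg <- trainConfig(lr = 3e-3, epochs = 30L, batchSize = 8L, seed = 1L)
  cv <- runCV(protoBuilder(), set, splits, cfg)
  expect_equal(nrow(cv$records), 5)
  expect_true(all(is.finite(cv$records$valAccuracy)))
  expect_equal(cv$bestFold, which.max(cv$records$valAccuracy))
  ## an easily separable task trains to high validation accuracy per fold
  expect_true(all(cv$records$valAccuracy >= 0.9))

  ## seeded end-to-end determinism
  cv2 <- runCV(protoBuilder(), set, splits, cfg)
  expect_equal(cv$records, cv2$records)
  expect_equal(cv$bestWeights, cv2$bestWeights)
})

test_that("final training initialises from fold weights and reports on held-out data", {
  set <- protoSet()
  splits <- makeSplits(sampleLabels(set), 0.2, 5, seed = 1)
  cfg <- trainConfig(lr = 3e-3, epochs = 30L, finalEpochs = 30L,
                     batchSize = 8L, seed = 1L)
  cv <- runCV(protoBuilder(), set, splits, cfg)
  fin <- finalTrain(protoBuilder(), cv$bestWeights, set[splits$trainIds],
                    set[splits$testIds], cfg)
  expect_s4_class(fin$report, "EvalReport")
  expect_equal(sum(fin$report@confusion), length(splits$testIds))
  expect_gte(fin$report@accuracy, 0.9)
  ## honest mode touches the test set once: no per-epoch accuracies
  finH <- finalTrain(protoBuilder(), cv$bestWeights, set[splits$trainIds],
                     set[splits$testIds], cfg, honest = TRUE)
  expect_true(all(is.na(finH$history$valAccuracy)))
  ## incompatible weights are rejected
  other <- buildModel(modelSpec(inputLength = 58L, numClasses = 4L,
                                imageSize = 32L, fusion = "cma"), seed = 1)
  expect_error(nsf$setWeights(other, cv$bestWeights), "architecture|shape")
})

test_that("training is deterministic given seeds and rejects foreign labels", {
  set <- protoSet()
  cfg <- trainConfig(lr = 3e-3, epochs = 2L, batchSize = 16L, seed = 5L)
  m1 <- protoBuilder()(7); trainModel(m1, set, cfg)
  m2 <- protoBuilder()(7); trainModel(m2, set, cfg)
  expect_equal(m1$history, m2$history)
  expect_equal(predictProba(m1, set), predictProba(m2, set))

  bad <- protoBuilder(numClasses = 3L)(1)
  expect_error(trainModel(bad, set, cfg), "class set")
})

test_that("decision fusion of identical models equals either model", {
  set <- protoSet()
  cfg <- trainConfig(lr = 3e-3, epochs = 2L, batchSize = 8L, seed = 1L)
  m <- protoBuilder()(3); trainModel(m, set, cfg)
  fused <- decisionFusionBaseline(m, m, set)
  expect_equal(fused@accuracy, evaluateModel(m, set)@accuracy)
  expect_equal(fused@confusion, evaluateModel(m, set)@confusion)
})

test_that("probability averaging lets a perfect model dominate a uniform one", {
  ## constructed outputs: argmax(p_perfect/2 + p_uniform/2) == argmax(p_perfect)
  n <- 30; K <- 5
  truth <- rep(1:K, 6)
  pPerfect <- matrix(1e-6, n, K); pPerfect[cbind(1:n, truth)] <- 1
  pPerfect <- pPerfect / rowSums(pPerfect)
  pUniform <- matrix(1 / K, n, K)
  avg <- (pPerfect + pUniform) / 2
  expect_equal(max.col(avg, "first"), truth)
})
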