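#' Training configuration
#'
#' The evaluation protocol trains with Adam (learning rate 1e-4) for 200
#' epochs per cross-validation fold; those are the defaults here. Short
#' schedules (as used in the scaled-down synthetic experiments) should raise
#' the learning rate accordingly (1e-3 is the package's short-schedule
#' choice).
#'
#' @param lr Adam learning rate
#' @param epochs training epochs per fold
#' @param finalEpochs epochs for the final-training stage (defaults to
#'   `epochs`)
#' @param batchSize mini-batch size
#' @param flipProb probability of horizontal image flip during training
#' @param seed integer seed governing shuffling and augmentation
#' @return config list of class `TrainConfig`
#' @export
trainConfig <- function(lr = 1e-4, epochs = 200L, finalEpochs = epochs,
                        batchSize = 32L, flipProb = 0.5, seed = 1L) {
  stopIfNot(lr > 0, "learning rate must be > 0")
  stopIfNot(epochs >= 1 && batchSize >= 1, "epochs and batchSize must be >= 1")
  structure(list(lr = lr, epochs = as.integer(epochs),
                 finalEpochs = as.integer(finalEpochs),
                 batchSize = as.integer(batchSize), flipProb = flipProb,
                 seed = as.integer(seed)),
            class = "TrainConfig")
}

#' Stratified train/test split with cross-validation folds
#'
#' Splits samples into a test set (`testFraction`, per class) and a training
#' set, then assigns the training samples of every class to `k` folds as
#' evenly as possible (class proportions preserved within one sample).
#' Deterministic given `seed`.
#'
#' @param labels factor of class labels
#' @param testFraction held-out fraction (default 0.2, the 8:2 protocol)
#' @param k number of cross-validation folds
#' @param seed integer seed
#' @return list with `trainIds`, `testIds` (integer sample indices) and
#'   `foldId` (integer 1..k, aligned with `trainIds`)
#' @export
makeSplits <- function(labels, testFraction = 0.2, k = 5L, seed = 1L) {
  labels <- as.factor(labels)
  k <- as.integer(k)
  counts <- table(labels)
  small <- names(counts)[counts < k]
  if (length(small) > 0)
    stop(sprintf("class(es) with fewer than k=%d samples: %s", k,
                 paste(small, collapse = ", ")), call. = FALSE)
  withSeed(childSeed(seed, 21), {
    trainIds <- integer(0); testIds <- integer(0); foldId <- integer(0)
    for (cl in levels(labels)) {
      ids <- sample(which(labels == cl))
      nTest <- round(length(ids) * testFraction)
      testIds <- c(testIds, ids[seq_len(nTest)])
      tr <- ids[-seq_len(nTest)]
      trainIds <- c(trainIds, tr)
      foldId <- c(foldId, rep_len(seq_len(k), length(tr)))
    }
    list(trainIds = trainIds, testIds = testIds, foldId = foldId)
  })
}

## assemble a model input batch from a MultiModalSet
assembleBatch <- function(set, idx, spec, flip = NULL) {
  xs <- NULL; xi <- NULL
  if (spec@fusion != "image") {
    sp <- set@spectra[idx, , drop = FALSE]
    xs <- aperm(array(sp, c(nrow(sp), 1L, ncol(sp))), c(2, 3, 1))
  }
  if (spec@fusion != "spectral") {
    d <- dim(set@images[[1]])
    xi <- array(0, c(d, length(idx)))
    for (j in seq_along(idx)) {
      im <- set@images[[idx[j]]]
      if (!is.null(flip) && flip[j]) im <- im[, , rev(seq_len(d[3])), drop = FALSE]
      xi[, , , j] <- im
    }
  }
  list(spectra = xs, images = xi)
}

#' Train a model on a multimodal set
#'
#' Mini-batch Adam training with cross-entropy loss, seeded shuffling and
#' (for image inputs) random horizontal flipping. Aborts with a diagnostic if
#' the loss becomes non-finite.
#'
#' @param model a model from [buildModel()]
#' @param set a [MultiModalSet-class]
#' @param cfg a [trainConfig()]
#' @param validation optional [MultiModalSet-class] scored after every epoch
#' @param epochs number of epochs (defaults to `cfg$epochs`)
#' @return the model, invisibly; the attribute `history` (also stored in
#'   `model$history`) is a data.frame with per-epoch loss and, if a
#'   validation set was given, validation accuracy
#' @export
trainModel <- function(model, set, cfg = trainConfig(), validation = NULL,
                       epochs = cfg$epochs) {
  n <- length(set)
  labs <- as.integer(set@labels)
  stopIfNot(max(labs) <= model$spec@numClasses,
            "label outside the model's class set")
  opt <- adamOptimizer(model, lr = cfg$lr)
  hist <- data.frame(epoch = seq_len(epochs), loss = NA_real_,
                     valAccuracy = NA_real_)
  for (ep in seq_len(epochs)) {
    ord <- withSeed(childSeed(cfg$seed, 1000 + ep), sample(n))
    flips <- withSeed(childSeed(cfg$seed, 2000 + ep),
                      runif(n) < cfg$flipProb)
    losses <- numeric(0)
    for (start in seq(1, n, by = cfg$batchSize)) {
      idx <- ord[start:min(start + cfg$batchSize - 1L, n)]
      batch <- assembleBatch(set, idx, model$spec, flips[seq_along(idx)])
      logits <- modelLogits(model, batch$spectra, batch$images,
                            training = TRUE)
      ce <- crossEntropy(logits, labs[idx])
      if (!is.finite(ce$loss))
        stop(sprintf("non-finite loss at epoch %d (lr=%g): aborting", ep,
                     cfg$lr), call. = FALSE)
      modelBackward(model, ce$grad)
      opt$step()
      opt$zeroGrads()
      losses <- c(losses, ce$loss)
    }
    hist$loss[ep] <- mean(losses)
    if (!is.null(validation)) {
      p <- predictProba(model, validation)
      hist$valAccuracy[ep] <-
        mean(max.col(p, "first") == as.integer(validation@labels))
    }
  }
  model$history <- hist
  attr(model, "history") <- hist
  invisible(model)
}

#' Predict class probabilities for a multimodal set
#'
#' @param model a model from [buildModel()]
#' @param set a [MultiModalSet-class]
#' @param batchSize evaluation batch size
#' @return N x numClasses probability matrix
#' @export
predictProba <- function(model, set, batchSize = 64L) {
  n <- length(set)
  out <- matrix(NA_real_, n, model$spec@numClasses)
  for (start in seq(1, n, by = batchSize)) {
    idx <- start:min(start + batchSize - 1L, n)
    batch <- assembleBatch(set, idx, model$spec)
    logits <- modelLogits(model, batch$spectra, batch$images,
                          training = FALSE)
    out[idx, ] <- softmaxRows(logits)
  }
  clearCaches(model)
  out
}

#' Run k-fold cross-validation
#'
#' Trains one freshly initialised model per fold on the fold's training
#' portion, scores it on the fold's validation portion, and returns the
#' weights of the best-scoring fold (ties resolve to the lowest fold index).
#'
#' @param builder function(seed) returning a fresh model
#' @param set a [MultiModalSet-class] (the full training set)
#' @param splits result of [makeSplits()]; folds are taken from `foldId`
#' @param cfg a [trainConfig()]
#' @return list with `records` (data.frame fold/valAccuracy), `bestFold`,
#'   and `bestWeights` (snapshot for [finalTrain()])
#' @export
runCV <- function(builder, set, splits, cfg = trainConfig()) {
  k <- max(splits$foldId)
  records <- data.frame(fold = seq_len(k), valAccuracy = NA_real_)
  best <- NULL
  for (f in seq_len(k)) {
    valIds <- splits$trainIds[splits$foldId == f]
    trIds <- splits$trainIds[splits$foldId != f]
    model <- builder(childSeed(cfg$seed, 300 + f))
    foldCfg <- cfg
    foldCfg$seed <- childSeed(cfg$seed, 400 + f)
    trainModel(model, set[trIds], foldCfg, epochs = cfg$epochs)
    p <- predictProba(model, set[valIds])
    acc <- mean(max.col(p, "first") == as.integer(set@labels[valIds]))
    records$valAccuracy[f] <- acc
    if (is.null(best) || acc > best$acc)
      best <- list(acc = acc, fold = f, weights = getWeights(model))
  }
  list(records = records, bestFold = best$fold, bestWeights = best$weights)
}

#' Final training stage
#'
#' Re-initialises a model from the best cross-validation fold's weights and
#' retrains it on the complete training set. In the default mode the test set
#' is scored after every epoch for monitoring (the final-epoch model is still
#' the one reported, so the test set never selects the model); with
#' `honest = TRUE` the test set is touched exactly once, after training.
#'
#' @param builder function(seed) returning a fresh model
#' @param bestWeights weight snapshot from [runCV()]
#' @param trainSet,testSet [MultiModalSet-class] objects
#' @param cfg a [trainConfig()]; `finalEpochs` controls this stage
#' @param honest if TRUE, no per-epoch test monitoring
#' @return list with `model`, `report` (an [EvalReport-class] on the test
#'   set) and `history`
#' @export
finalTrain <- function(builder, bestWeights, trainSet, testSet,
                       cfg = trainConfig(), honest = FALSE) {
  model <- builder(childSeed(cfg$seed, 500))
  setWeights(model, bestWeights)
  finalCfg <- cfg
  finalCfg$seed <- childSeed(cfg$seed, 600)
  trainModel(model, trainSet, finalCfg,
             validation = if (honest) NULL else testSet,
             epochs = cfg$finalEpochs)
  report <- evaluateModel(model, testSet)
  list(model = model, report = report, history = model$history)
}

#' Evaluate a model on a labelled set
#'
#' @param model a model from [buildModel()]
#' @param set a [MultiModalSet-class]
#' @return an [EvalReport-class]
#' @export
evaluateModel <- function(model, set) {
  stopIfNot(length(set) > 0, "empty evaluation set")
  stopIfNot(nlevels(set@labels) <= model$spec@numClasses,
            "labels outside the model's class set")
  p <- predictProba(model, set)
  buildEvalReport(as.integer(set@labels), max.col(p, "first"),
                  model$spec@numClasses, levels(set@labels))
}

buildEvalReport <- function(truth, pred, nClasses,
                            classNames = as.character(seq_len(nClasses))) {
  stopIfNot(length(truth) == length(pred), "truth/prediction length mismatch")
  conf <- matrix(0L, nClasses, nClasses,
                 dimnames = list(truth = classNames, pred = classNames))
  for (i in seq_along(truth)) conf[truth[i], pred[i]] <- conf[truth[i], pred[i]] + 1L
  support <- rowSums(conf)
  predTot <- colSums(conf)
  tp <- diag(conf)
  prec <- ifelse(predTot > 0, tp / predTot, 0)
  rec <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  confPct <- conf / pmax(support, 1) * 100
  new("EvalReport",
      accuracy = sum(tp) / length(truth),
      precision = mean(prec), recall = mean(rec),
      perClass = data.frame(class = classNames, precision = prec,
                            recall = rec, f1 = f1, support = support,
                            row.names = NULL),
      confusion = conf, confusionPct = confPct, embeddings = list())
}

#' Decision-level fusion baseline
#'
#' Averages the per-sample class probabilities of a spectral-only and an
#' image-only model (or takes a majority vote) and evaluates the combined
#' decision -- the late-fusion counterpart to MSI-FusionNet's feature-level
#' fusion.
#'
#' @param spectralModel,imageModel trained unimodal models
#' @param set a [MultiModalSet-class] (the common test set)
#' @param method "average" (probability averaging) or "vote"
#' @return an [EvalReport-class]
#' @export
decisionFusionBaseline <- function(spectralModel, imageModel, set,
                                   method = c("average", "vote")) {
  method <- match.arg(method)
  stopIfNot(spectralModel$spec@numClasses == imageModel$spec@numClasses,
            "models disagree on the class set")
  ps <- predictProba(spectralModel, set)
  pi <- predictProba(imageModel, set)
  pred <- if (method == "average") {
    max.col((ps + pi) / 2, "first")
  } else {
    a <- max.col(ps, "first"); b <- max.col(pi, "first")
    conf <- ifelse(ps[cbind(seq_len(nrow(ps)), a)] >=
                   pi[cbind(seq_len(nrow(pi)), b)], a, b)
    ifelse(a == b, a, conf)
  }
  buildEvalReport(as.integer(set@labels), pred,
                  spectralModel$spec@numClasses, levels(set@labels))
}
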