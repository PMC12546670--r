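#' Embed a feature matrix into 2-D
#'
#' Projects an N x P feature matrix to N x 2 coordinates for visual
#' assessment of class separability. `"pca"` is the exact linear projection
#' onto the first two principal components (deterministic); `"tsne"` is an
#' exact (O(N^2)) t-SNE with perplexity calibration, early exaggeration and
#' momentum gradient descent; `"umap"` builds a fuzzy k-nearest-neighbour
#' graph with per-point bandwidth calibration and lays it out by stochastic
#' attraction/repulsion. The nonlinear methods are seeded and intended for
#' the moderate sample counts this package works at (hundreds to a few
#' thousand).
#'
#' @param x N x P numeric feature matrix (N >= 3)
#' @param method "pca", "tsne" or "umap"
#' @param seed integer seed for the stochastic methods
#' @param perplexity t-SNE perplexity (reduced automatically for tiny N)
#' @param iterations optimisation iterations (t-SNE/UMAP)
#' @param nNeighbors UMAP neighbourhood size
#' @return N x 2 coordinate matrix
#' @export
embedFeatures <- function(x, method = c("pca", "tsne", "umap"), seed = 1L,
                          perplexity = 30, iterations = 300L,
                          nNeighbors = 15L) {
  method <- match.arg(method)
  x <- as.matrix(x)
  stopIfNot(nrow(x) >= 3, "need at least 3 samples to embed")
  switch(method,
         pca = embedPCA(x),
         tsne = embedTSNE(x, seed, perplexity, iterations),
         umap = embedUMAP(x, seed, nNeighbors, iterations))
}

embedPCA <- function(x) {
  p <- prcomp(x, center = TRUE, scale. = FALSE)
  unname(p$x[, 1:2, drop = FALSE])
}

## conditional probabilities with per-point precision calibrated to the
## target perplexity by bisection
tsneAffinities <- function(D2, perplexity) {
  n <- nrow(D2)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    lo <- 1e-20; hi <- 1e20; beta <- 1
    for (it in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp <= 0) { beta <- beta / 2; next }
      H <- log(sp) + beta * sum(di * p) / sp
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (hi < 1e19) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- (beta + lo) / 2 }
    }
    P[i, -i] <- p / sum(p)
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

embedTSNE <- function(x, seed, perplexity, iterations) {
  n <- nrow(x)
  perplexity <- min(perplexity, (n - 1) / 3)
  D2 <- as.matrix(dist(x))^2
  P <- tsneAffinities(D2, perplexity)
  withSeed(childSeed(seed, 71), {
    Y <- matrix(rnorm(n * 2, sd = 1e-4), n)
    inc <- matrix(0, n, 2)
    momentum <- 0.5
    exag <- 12
    eta <- 200
    for (it in seq_len(iterations)) {
      if (it == 51) exag <- 1
      if (it == 21) momentum <- 0.8
      sumY <- rowSums(Y^2)
      num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      M <- (exag * P - Q) * num
      grad <- 4 * (diag(rowSums(M)) - M) %*% Y
      inc <- momentum * inc - eta * grad
      Y <- Y + inc
      Y <- sweep(Y, 2, colMeans(Y))
    }
    Y
  })
}

embedUMAP <- function(x, seed, nNeighbors, iterations) {
  n <- nrow(x)
  k <- min(nNeighbors, n - 1)
  D <- as.matrix(dist(x))
  diag(D) <- Inf
  ## fuzzy neighbourhood graph: per-point bandwidth so that the effective
  ## neighbour count is ~log2(k)
  nn <- t(apply(D, 1, function(d) order(d)[seq_len(k)]))
  rho <- vapply(seq_len(n), function(i) min(D[i, nn[i, ]]), 0)
  target <- log2(k)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- pmax(D[i, nn[i, ]] - rho[i], 0)
    lo <- 1e-3; hi <- 1e3; sig <- 1
    for (it in 1:40) {
      s <- sum(exp(-di / sig))
      if (abs(s - target) < 1e-4) break
      if (s > target) { hi <- sig; sig <- (sig + lo) / 2 }
      else { lo <- sig; sig <- if (hi < 1e3) (sig + hi) / 2 else sig * 2 }
    }
    W[i, nn[i, ]] <- exp(-di / sig)
  }
  W <- W + t(W) - W * t(W)                  # fuzzy union
  edges <- which(W > 0.01, arr.ind = TRUE)
  edges <- edges[edges[, 1] < edges[, 2], , drop = FALSE]
  ew <- W[edges]
  a <- 1.577; b <- 0.895                     # min_dist ~ 0.1 curve
  withSeed(childSeed(seed, 72), {
    Y <- embedPCA(x)
    Y <- Y / max(1e-12, stats::sd(Y)) * 1e-1
    Y <- Y + matrix(rnorm(n * 2, sd = 1e-3), n)
    for (it in seq_len(iterations)) {
      alpha <- 1 - (it - 1) / iterations
      ## attraction along sampled edges
      sel <- which(runif(nrow(edges)) < ew)
      if (length(sel)) {
        i <- edges[sel, 1]; j <- edges[sel, 2]
        d <- Y[i, , drop = FALSE] - Y[j, , drop = FALSE]
        d2 <- rowSums(d^2)
        co <- (-2 * a * b * d2^(b - 1)) / (1 + a * d2^b)
        step <- pmax(pmin(co, 4), -4) * d * alpha * 0.2
        ## accumulate per-vertex displacements
        for (rr in seq_along(i)) {
          Y[i[rr], ] <- Y[i[rr], ] + step[rr, ]
          Y[j[rr], ] <- Y[j[rr], ] - step[rr, ]
        }
      }
      ## repulsion against random negative samples
      neg <- sample(n, min(n, 5 * max(1, length(sel))), replace = TRUE)
      src <- sample(n, length(neg), replace = TRUE)
      d <- Y[src, , drop = FALSE] - Y[neg, , drop = FALSE]
      d2 <- rowSums(d^2) + 1e-3
      co <- (2 * b) / (d2 * (1 + a * d2^b))
      step <- pmax(pmin(co, 4), -4) * d * alpha * 0.2
      for (rr in seq_along(src))
        Y[src[rr], ] <- Y[src[rr], ] + step[rr, ]
    }
    sweep(Y, 2, colMeans(Y))
  })
}

#' Class-separation ratio of a feature embedding
#'
#' Mean distance between class centroids divided by mean within-class
#' distance to centroid -- a scalar summary of how well features separate
#' classes in a 2-D embedding (larger is better separated).
#'
#' @param coords N x 2 coordinate matrix
#' @param labels factor of class labels
#' @return positive scalar
#' @export
separationRatio <- function(coords, labels) {
  labels <- as.factor(labels)
  cent <- rowsum(coords, labels) / as.vector(table(labels))
  within <- mean(sqrt(rowSums((coords - cent[as.integer(labels), ])^2)))
  dd <- dist(cent)
  between <- mean(dd)
  between / max(within, 1e-12)
}
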