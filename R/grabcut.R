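## GrabCut foreground extraction: iterated Gaussian-mixture colour models for
## foreground/background plus a minimum graph cut (igraph max-flow) over the
## 4-connected pixel lattice. Initialised from a rectangle: pixels outside it
## are definite background, pixels inside start as probable foreground.
## Fully deterministic: the mixture fit uses quantile-seeded k-means, so the
## result does not depend on the global RNG state.

## diagonal-covariance GMM via deterministic k-means hard assignment
fitGMM <- function(X, k = 3L, iters = 10L) {
  n <- nrow(X)
  k <- min(k, n)
  lum <- rowMeans(X)
  qs <- quantile(lum, probs = (seq_len(k) - 0.5) / k, names = FALSE)
  centers <- X[vapply(qs, function(q) which.min(abs(lum - q)), 0L), ,
               drop = FALSE]
  for (it in seq_len(iters)) {
    d2 <- outer(rowSums(X^2), rowSums(centers^2), "+") -
      2 * X %*% t(centers)
    cl <- max.col(-d2, "first")
    for (j in seq_len(k)) {
      sel <- cl == j
      if (any(sel)) centers[j, ] <- colMeans(X[sel, , drop = FALSE])
    }
  }
  comps <- lapply(seq_len(k), function(j) {
    sel <- cl == j
    if (sum(sel) < 2)
      return(list(w = max(sum(sel), 1) / n, mu = centers[j, ],
                  var = rep(1e-2, ncol(X))))
    list(w = sum(sel) / n, mu = colMeans(X[sel, , drop = FALSE]),
         var = pmax(apply(X[sel, , drop = FALSE], 2, stats::var), 1e-4))
  })
  comps
}

## negative log-likelihood of each row under the best mixture component
gmmNegLogLik <- function(X, comps) {
  ll <- vapply(comps, function(cp) {
    log(cp$w) - 0.5 * rowSums(sweep(X, 2, cp$mu)^2 / rep(cp$var, each = nrow(X))) -
      0.5 * sum(log(2 * pi * cp$var))
  }, numeric(nrow(X)))
  -apply(ll, 1, max)
}

#' GrabCut-style foreground segmentation
#'
#' Iterative foreground extraction from a single-grain image: colour mixture
#' models for foreground and background are re-fit against the current
#' labelling, and pixel labels are re-solved as a minimum s-t cut over the
#' 4-connected image graph with contrast-sensitive smoothness weights
#' `gamma * exp(-beta * ||z_i - z_j||^2)`. Pixels outside `initRect` are
#' clamped to background. Deterministic given the image and rectangle.
#'
#' @param image `(3, H, W)` array in `[0, 1]` (or H x W x 3, auto-detected)
#' @param initRect rectangle `c(y0, x0, y1, x1)` (1-based, inclusive) assumed
#'   to contain the grain; defaults to the image bounds shrunk by 5% per side
#' @param iterations number of model-refit/cut rounds
#' @param gamma smoothness weight
#' @param nComponents mixture components per colour model
#' @return logical H x W foreground mask
#' @export
grabCutForeground <- function(image, initRect = NULL, iterations = 5L,
                              gamma = 50, nComponents = 3L) {
  if (length(dim(image)) == 3 && dim(image)[1] == 3 && dim(image)[3] != 3)
    image <- aperm(image, c(2, 3, 1))
  stopIfNot(length(dim(image)) == 3 && dim(image)[3] == 3,
            "image must be an RGB array")
  H <- dim(image)[1]; W <- dim(image)[2]
  if (is.null(initRect)) {
    my <- max(1L, round(0.05 * H)); mx <- max(1L, round(0.05 * W))
    initRect <- c(1L + my, 1L + mx, H - my, W - mx)
  }
  stopIfNot(initRect[3] > initRect[1] && initRect[4] > initRect[2],
            "degenerate initRect (zero area)")
  stopIfNot(initRect[1] >= 1 && initRect[2] >= 1 &&
            initRect[3] <= H && initRect[4] <= W,
            "initRect must lie inside the image")

  X <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
             as.vector(image[, , 3]))
  yy <- rep(seq_len(H), W); xx <- rep(seq_len(W), each = H)
  inRect <- yy >= initRect[1] & yy <= initRect[3] &
    xx >= initRect[2] & xx <= initRect[4]
  fg <- inRect

  ## contrast term: 4-neighbour edges
  idx <- matrix(seq_len(H * W), H, W)
  eR <- cbind(as.vector(idx[, -W]), as.vector(idx[, -1]))   # right
  eD <- cbind(as.vector(idx[-H, ]), as.vector(idx[-1, ]))   # down
  edges <- rbind(eR, eD)
  dz2 <- rowSums((X[edges[, 1], ] - X[edges[, 2], ])^2)
  beta <- 1 / max(2 * mean(dz2), 1e-8)
  wEdge <- gamma * exp(-beta * dz2)
  hardW <- 1e8

  for (it in seq_len(iterations)) {
    if (!any(fg) || all(fg[inRect])) {
      ## degenerate labelling: refit from the rectangle
      if (!any(fg)) fg <- inRect
    }
    fgComps <- fitGMM(X[fg, , drop = FALSE], nComponents)
    bgComps <- fitGMM(X[!fg, , drop = FALSE], nComponents)
    dFg <- gmmNegLogLik(X, fgComps)   # cost of labelling fg
    dBg <- gmmNegLogLik(X, bgComps)
    ## terminal capacities: source = fg, sink = bg
    srcCap <- ifelse(inRect, dBg, 0)      # cut to bg costs dBg
    snkCap <- ifelse(inRect, dFg, hardW)  # outside rect clamped to bg
    n <- H * W
    s <- n + 1L; t <- n + 2L
    ed <- rbind(cbind(s, seq_len(n)), cbind(seq_len(n), t),
                edges, edges[, 2:1])
    caps <- c(srcCap, snkCap, wEdge, wEdge)
    keep <- caps > 1e-10
    g <- igraph::graph_from_edgelist(ed[keep, , drop = FALSE],
                                     directed = TRUE)
    fl <- igraph::max_flow(g, source = s, target = t,
                           capacity = caps[keep])
    newFg <- rep(FALSE, n)
    part1 <- as.integer(fl$partition1)
    newFg[part1[part1 <= n]] <- TRUE
    newFg <- newFg & inRect
    if (identical(newFg, fg) && it > 1) { fg <- newFg; break }
    fg <- newFg
  }
  if (!any(fg))
    stop("GrabCut found no foreground; enlarge or re-centre initRect",
         call. = FALSE)
  matrix(fg, H, W)
}
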