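# importance_eval module: permutation variable importance (mean decrease in
# accuracy) over bagged classification trees, ROC/AUC, paired model
# comparison, and water-table-depth response curves.

#' Fit bagged classification trees
#'
#' Grows `nTrees` classification trees, each on a bootstrap sample of the
#' data (so roughly 63% of rows train each tree and the remaining ~37%
#' out-of-bag rows are retained for evaluation). Individual trees are CART
#' trees from \pkg{rpart}; the bootstrap/out-of-bag protocol and everything
#' downstream (permutation importance, AUC) are implemented here.
#' Deterministic given `seed`.
#'
#' @param data data.frame of covariates.
#' @param y two-class response (presence/background), coercible to factor.
#' @param nTrees number of trees (default 1000).
#' @param seed integer seed.
#' @param minsplit,cp tree-growing controls passed to
#'   [rpart::rpart.control()].
#' @return An object of class `baggedForest`: list of trees with their
#'   out-of-bag row indices and accuracies.
#' @export
fitBaggedTrees <- function(data, y, nTrees = 1000L, seed = 1L,
                           minsplit = 10L, cp = 0.01) {
  y <- factor(y)
  stopIfNot(nlevels(y) == 2, "the response must have exactly two classes")
  stopIfNot(all(table(y) > 0), "both classes must be non-empty")
  n <- nrow(data)
  stopIfNot(n == length(y), "data and y must have matching lengths")
  set.seed(seed)
  df <- cbind(.y = y, data)
  control <- rpart::rpart.control(minsplit = minsplit, cp = cp, xval = 0L)
  trees <- vector("list", nTrees)
  for (t in seq_len(nTrees)) {
    idx <- sample.int(n, n, replace = TRUE)
    oob <- setdiff(seq_len(n), unique(idx))
    fit <- rpart::rpart(.y ~ ., data = df[idx, , drop = FALSE],
                        method = "class", control = control)
    oobAcc <- if (length(oob)) {
      pred <- predict(fit, df[oob, , drop = FALSE], type = "class")
      mean(pred == y[oob])
    } else NA_real_
    trees[[t]] <- list(fit = fit, oob = oob, oobAcc = oobAcc)
  }
  structure(list(trees = trees, y = y, covariates = names(data),
                 nTrees = nTrees, seed = seed),
            class = "baggedForest")
}

#' @export
print.baggedForest <- function(x, ...) {
  cat(sprintf("baggedForest: %d trees over %s; mean OOB accuracy %.3f\n",
              x$nTrees, paste(x$covariates, collapse = ", "),
              mean(vapply(x$trees, `[[`, 0, "oobAcc"), na.rm = TRUE)))
  invisible(x)
}

#' Permutation importance: mean decrease in accuracy
#'
#' For every tree, the out-of-bag accuracy is compared with the accuracy
#' after randomly permuting the covariate's values among that tree's
#' out-of-bag rows; the importance is the mean decrease over trees
#' normalised by its standard error (`mean / (sd / sqrt(nTrees))`). The
#' permutation stream is seeded, so results are reproducible.
#'
#' @param forest a `baggedForest` from [fitBaggedTrees()].
#' @param data the covariate data.frame the forest was grown on.
#' @param covariate covariate name to permute.
#' @param seed integer seed for the permutation stream.
#' @return list with `importance` (normalised), `meanDecrease`,
#'   `sdDecrease` and the per-tree `decreases`.
#' @export
meanDecreaseAccuracy <- function(forest, data, covariate, seed = 1L) {
  stopIfNot(inherits(forest, "baggedForest"), "forest must be a baggedForest")
  stopIfNot(covariate %in% forest$covariates,
            "covariate not in the fitted forest: ", covariate)
  set.seed(seed)
  y <- forest$y
  dec <- vapply(forest$trees, function(tr) {
    oob <- tr$oob
    if (!length(oob)) return(NA_real_)
    perm <- data[oob, , drop = FALSE]
    perm[[covariate]] <- perm[[covariate]][sample.int(length(oob))]
    pred <- predict(tr$fit, perm, type = "class")
    tr$oobAcc - mean(pred == y[oob])
  }, 0)
  dec <- dec[!is.na(dec)]
  mu <- mean(dec)
  sdev <- stats::sd(dec)
  imp <- if (sdev > 0) mu / (sdev / sqrt(length(dec)))
         else if (mu == 0) 0 else sign(mu) * Inf
  list(importance = imp, meanDecrease = mu, sdDecrease = sdev,
       decreases = dec)
}

#' Importance table over all covariates
#'
#' Applies [meanDecreaseAccuracy()] to every covariate of the forest.
#'
#' @param forest a `baggedForest`.
#' @param data the covariate data.frame the forest was grown on.
#' @param seed seed for the permutation streams (one derived seed per
#'   covariate, so the table is invariant to covariate order).
#' @return data.frame with `covariate`, `importance`, `meanDecrease`,
#'   `sdDecrease`, sorted by decreasing importance.
#' @export
importanceTable <- function(forest, data, seed = 1L) {
  rows <- lapply(forest$covariates, function(cv) {
    r <- meanDecreaseAccuracy(forest, data, cv,
                              seed = deriveSeed(seed, match(cv, sort(forest$covariates))))
    data.frame(covariate = cv, importance = r$importance,
               meanDecrease = r$meanDecrease, sdDecrease = r$sdDecrease,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$importance), , drop = FALSE]
}

#' Area under the ROC curve
#'
#' Mann-Whitney form: the mean over all presence/background score pairs of
#' 1 when the presence scores higher, 0.5 for a tie, 0 otherwise. Computed
#' via midranks, which reproduces the all-pairs count exactly, ties
#' included.
#'
#' @param scoresPresence,scoresBackground non-empty numeric score vectors.
#' @return AUC in `[0, 1]`.
#' @export
aucScore <- function(scoresPresence, scoresBackground) {
  stopIfNot(length(scoresPresence) >= 1 && length(scoresBackground) >= 1,
            "both score vectors must be non-empty")
  stopIfNot(!anyNA(scoresPresence) && !anyNA(scoresBackground),
            "scores must not contain NA")
  m <- length(scoresPresence); n <- length(scoresBackground)
  r <- rank(c(scoresPresence, scoresBackground), ties.method = "average")
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

#' Compare two replicated models by paired AUC
#'
#' Two-sided paired t-test on the per-replicate AUC differences of two
#' models evaluated on the same replicate seeds. `"tie"` when `p >= alpha`.
#' When the differences have zero variance the test degenerates: the result
#' is a tie at zero mean difference and otherwise the better model with
#' `p = 0`, flagged via `degenerate`.
#'
#' @param aucA,aucB equal-length per-replicate AUC vectors (paired runs).
#'   `NA` pairs (failed replicates) are dropped.
#' @param alpha significance level (default 0.05).
#' @return list with `better` (`"A"`, `"B"` or `"tie"`), `meanDiff`, `p`,
#'   `n` and `degenerate`.
#' @export
compareModels <- function(aucA, aucB, alpha = 0.05) {
  stopIfNot(length(aucA) == length(aucB),
            "paired comparison requires equal-length AUC vectors")
  keep <- !(is.na(aucA) | is.na(aucB))
  d <- aucA[keep] - aucB[keep]
  stopIfNot(length(d) >= 2, "need at least two paired replicates")
  if (stats::sd(d) == 0) {
    md <- mean(d)
    return(list(better = if (md == 0) "tie" else if (md > 0) "A" else "B",
                meanDiff = md, p = if (md == 0) 1 else 0,
                n = length(d), degenerate = TRUE))
  }
  tt <- stats::t.test(d)
  md <- mean(d)
  better <- if (tt$p.value >= alpha) "tie" else if (md > 0) "A" else "B"
  list(better = better, meanDiff = md, p = tt$p.value, n = length(d),
       degenerate = FALSE)
}

#' Water-table-depth response curve
#'
#' Samples `n` cells uniformly without replacement from the valid cells of a
#' prediction surface, bins their water-table depths into `nBins` equal-width
#' bins over the sampled range, computes the per-bin mean predicted
#' probability, and fits a cubic smoothing spline (smoothness chosen by
#' generalised cross-validation) through the non-empty bin means.
#' Deterministic given `seed`.
#'
#' @param surface prediction surface ([RasterGrid-class]).
#' @param dwt co-registered water-table depth layer ([RasterGrid-class]).
#' @param n cells to sample (default 1000; capped at the number of valid
#'   cells with a warning).
#' @param nBins equal-width bins over the sampled depth range.
#' @param seed integer seed.
#' @param nSpline points of the dense spline evaluation grid.
#' @return A [ResponseCurve-class].
#' @export
responseCurve <- function(surface, dwt, n = 1000L, nBins = 20L, seed = 1L,
                          nSpline = 200L) {
  stopIfNot(identical(dim(surface@values), dim(dwt@values)),
            "surface and dwt must be co-registered")
  p <- as.vector(surface@values)
  d <- as.vector(dwt@values)
  valid <- which(!is.na(p) & !is.na(d))
  stopIfNot(length(valid) >= 4, "too few valid cells")
  if (n > length(valid)) {
    warning(sprintf("requested %d samples but only %d valid cells; using all",
                    n, length(valid)), call. = FALSE)
    n <- length(valid)
  }
  set.seed(seed)
  idx <- valid[sample.int(length(valid), n)]
  samples <- data.frame(dwt = d[idx], probability = p[idx])

  rng <- range(samples$dwt)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)  # constant-depth degenerate case
  edges <- seq(rng[1], rng[2], length.out = nBins + 1L)
  bin <- pmin(findInterval(samples$dwt, edges, rightmost.closed = TRUE), nBins)
  means <- rep(NA_real_, nBins)
  agg <- tapply(samples$probability, bin, mean)
  means[as.integer(names(agg))] <- as.numeric(agg)
  centers <- (edges[-1] + edges[-length(edges)]) / 2

  ok <- which(!is.na(means))
  stopIfNot(length(ok) >= 4, "fewer than 4 non-empty bins; reduce nBins")
  sp <- stats::smooth.spline(centers[ok], means[ok], keep.data = FALSE)
  sx <- seq(rng[1], rng[2], length.out = nSpline)
  sy <- stats::predict(sp, sx)$y

  new("ResponseCurve", samples = samples, binEdges = edges,
      binCenters = centers, binMeans = means, splineX = sx, splineY = sy)
}

#' Half-maximum depth of a response curve
#'
#' The shallowest water-table depth at which the spline falls to half of its
#' maximum — a summary of how tightly a species is bound to shallow water
#' tables. For a response proportional to `exp(-dwt / delta)` starting at
#' the surface this is `delta * log(2)`.
#'
#' @param curve a [ResponseCurve-class].
#' @return depth in metres (`NA` when the spline never falls below half its
#'   maximum).
#' @export
halfMaximumDwt <- function(curve) {
  x <- curve@splineX; y <- curve@splineY
  half <- max(y) / 2
  iMax <- which.max(y)
  below <- which(y[iMax:length(y)] <= half)
  if (!length(below)) return(NA_real_)
  i2 <- iMax + below[1] - 1L
  if (i2 == iMax) return(x[iMax])
  i1 <- i2 - 1L
  x[i1] + (half - y[i1]) * (x[i2] - x[i1]) / (y[i2] - y[i1])
}
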