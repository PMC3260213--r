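# maxent_sdm module: presence-background maximum-entropy distribution model.
# Feature expansion (linear/quadratic/product/hinge), L1-regularised
# coordinate-descent fitting of the Gibbs weights, raw and logistic
# prediction, and the 100-replicate 70-30 evaluation protocol.

FEATURE_CLASSES <- c("linear", "quadratic", "product", "hinge")

# class-specific default regularization rates, interpolated by the number of
# presence samples (in the style of the MaxEnt auto-feature defaults); hinge
# features use a constant rate
.betaRateTables <- list(
  linear    = list(m = c(10, 30, 100), rate = c(1.0, 0.2, 0.05)),
  quadratic = list(m = c(10, 17, 30, 100), rate = c(1.3, 0.8, 0.5, 0.25)),
  product   = list(m = c(10, 17, 30, 100), rate = c(2.6, 1.6, 1.0, 0.5)),
  hinge     = list(m = c(10, 100), rate = c(0.5, 0.5))
)

betaRate <- function(class, m) {
  tb <- .betaRateTables[[class]]
  stats::approx(tb$m, tb$rate, xout = m, rule = 2)$y
}

#' Build a feature expansion
#'
#' Covariates are affinely scaled to `[0, 1]` using their min/max over the
#' fitting cells *before* expansion, so every derived feature lies in
#' `[0, 1]` and the fitted objective is invariant to affine rescaling of the
#' raw covariates. With `classes = "auto"` the active classes follow the
#' usual sample-size rule: linear only below 10 presences, plus quadratic
#' from 10, plus hinge from 15, plus product from 80. Hinge features use 10
#' evenly spaced knots strictly inside the scaled range, in both
#' orientations. Constant covariates are dropped with a warning.
#'
#' @param covMat numeric matrix of covariate values over the fitting cells
#'   (background plus presences), named columns.
#' @param classes `"auto"` or a subset of
#'   `c("linear", "quadratic", "product", "hinge")`.
#' @param nPresences presence sample size `m` driving class auto-selection.
#' @param nKnots hinge knots per covariate and orientation.
#' @return A feature-set list: covariate `bounds`, active `classes`,
#'   `knots`, a `descriptors` data.frame (one row per feature) and
#'   `nFeatures`.
#' @export
buildFeatures <- function(covMat, classes = "auto", nPresences,
                          nKnots = 10L) {
  stopIfNot(nrow(covMat) >= 2, "at least 2 fitting cells required")
  stopIfNot(all(is.finite(covMat)), "covariates must be finite over fitting cells")
  covNames <- colnames(covMat)
  stopIfNot(!is.null(covNames) && all(nzchar(covNames)),
            "covariate matrix must have named columns")

  bounds <- apply(covMat, 2, range)
  constant <- bounds[1, ] == bounds[2, ]
  if (any(constant)) {
    warning("dropping constant covariate(s): ",
            paste(covNames[constant], collapse = ", "), call. = FALSE)
    covNames <- covNames[!constant]
    bounds <- bounds[, !constant, drop = FALSE]
    stopIfNot(length(covNames) >= 1, "all covariates are constant")
  }

  if (identical(classes, "auto")) {
    m <- nPresences
    classes <- "linear"
    if (m >= 10) classes <- c(classes, "quadratic")
    if (m >= 15) classes <- c(classes, "hinge")
    if (m >= 80) classes <- c(classes, "product")
  } else {
    stopIfNot(all(classes %in% FEATURE_CLASSES),
              "classes must be a subset of ",
              paste(FEATURE_CLASSES, collapse = ", "))
  }

  knots <- seq_len(nKnots) / (nKnots + 1)  # strictly inside (0, 1)
  desc <- list()
  add <- function(type, cov, cov2 = NA_character_, knot = NA_real_) {
    desc[[length(desc) + 1L]] <<- data.frame(
      type = type, cov = cov, cov2 = cov2, knot = knot,
      stringsAsFactors = FALSE)
  }
  for (cv in covNames) add("linear", cv)
  if ("quadratic" %in% classes) for (cv in covNames) add("quadratic", cv)
  if ("product" %in% classes && length(covNames) >= 2) {
    for (i in seq_len(length(covNames) - 1))
      for (j in (i + 1):length(covNames))
        add("product", covNames[i], covNames[j])
  }
  if ("hinge" %in% classes) {
    for (cv in covNames) for (k in knots) {
      add("hingeF", cv, knot = k)
      add("hingeR", cv, knot = k)
    }
  }
  desc <- do.call(rbind, desc)
  list(covNames = covNames, bounds = bounds, classes = classes,
       knots = knots, descriptors = desc, nFeatures = nrow(desc))
}

#' Evaluate a feature expansion at cells
#'
#' Raw covariates are clamped to the training bounds (no extrapolation) and
#' scaled to `[0, 1]` before expansion.
#'
#' @param featureSet output of [buildFeatures()].
#' @param covMat covariate matrix with (at least) the feature set's columns.
#' @return numeric cells-by-features matrix.
#' @export
featureMatrix <- function(featureSet, covMat) {
  fs <- featureSet
  missing <- setdiff(fs$covNames, colnames(covMat))
  stopIfNot(length(missing) == 0,
            "covariates absent from input: ", paste(missing, collapse = ", "))
  scaled <- vapply(fs$covNames, function(cv) {
    b <- fs$bounds[, cv]
    x <- pmin(pmax(covMat[, cv], b[1]), b[2])
    (x - b[1]) / (b[2] - b[1])
  }, numeric(nrow(covMat)))
  scaled <- matrix(scaled, nrow = nrow(covMat),
                   dimnames = list(NULL, fs$covNames))
  d <- fs$descriptors
  out <- matrix(0, nrow(covMat), nrow(d))
  for (j in seq_len(nrow(d))) {
    x <- scaled[, d$cov[j]]
    out[, j] <- switch(d$type[j],
      linear = x,
      quadratic = x^2,
      product = x * scaled[, d$cov2[j]],
      hingeF = pmax(0, (x - d$knot[j]) / (1 - d$knot[j])),
      hingeR = pmax(0, (d$knot[j] - x) / d$knot[j]))
  }
  colnames(out) <- featureNames(fs)
  out
}

featureNames <- function(fs) {
  d <- fs$descriptors
  ifelse(d$type == "product", paste0("P:", d$cov, "*", d$cov2),
    ifelse(d$type %in% c("hingeF", "hingeR"),
           sprintf("%s:%s:%.3f", ifelse(d$type == "hingeF", "HF", "HR"),
                   d$cov, d$knot),
           paste0(toupper(substr(d$type, 1, 1)), ":", d$cov)))
}

featureClassForBeta <- function(type) {
  ifelse(type %in% c("hingeF", "hingeR"), "hinge",
         ifelse(type == "quadratic", "quadratic",
                ifelse(type == "product", "product", "linear")))
}

softThreshold <- function(z, t) sign(z) * pmax(abs(z) - t, 0)

#' Fit a maximum-entropy distribution model
#'
#' Maximises the L1-penalised log likelihood
#' `mean(lambda . f(x_i)) - log Z(lambda) - sum(beta_j |lambda_j|)` over the
#' fitting cells (the background with the presence cells added for
#' normalisation) by cyclic coordinate descent with a soft-threshold Newton
#' step per feature and backtracking, so the objective is non-decreasing
#' across iterations. The default penalties are
#' `beta_j = betaMultiplier * rate(class, m) * sd(f_j over presences) /
#' sqrt(m)`; pass `beta` to override them feature-wise. Deterministic given
#' its inputs.
#'
#' @param presCov covariate matrix of the presence cells (one row per
#'   presence sample).
#' @param bgCov covariate matrix of the background cells (>= 2 rows).
#' @param features a prebuilt feature set ([buildFeatures()]) or `NULL` to
#'   build one from the fitting cells.
#' @param classes,nKnots passed to [buildFeatures()] when `features` is
#'   `NULL`.
#' @param betaMultiplier scales the default per-class penalties.
#' @param beta explicit per-feature penalty vector (recycled), overriding
#'   the defaults.
#' @param addPresences add the presence cells to the normalisation set
#'   (standard samples-with-data handling; default `TRUE`). Set `FALSE` when
#'   the background already contains the presence locations.
#' @param tol stop when a full cycle improves the objective by less than
#'   this.
#' @param maxIter maximum coordinate-descent cycles.
#' @return A [MaxentModel-class].
#' @export
fitMaxent <- function(presCov, bgCov, features = NULL, classes = "auto",
                      nKnots = 10L, betaMultiplier = 1.0, beta = NULL,
                      addPresences = TRUE, tol = 1e-5, maxIter = 2000L) {
  presCov <- as.matrix(presCov); bgCov <- as.matrix(bgCov)
  m <- nrow(presCov)
  stopIfNot(m >= 1, "at least one presence is required")
  stopIfNot(nrow(bgCov) >= 2, "at least two background cells are required")
  stopIfNot(identical(colnames(presCov), colnames(bgCov)),
            "presence and background covariates must share columns")
  all <- if (addPresences) rbind(presCov, bgCov) else bgCov
  fs <- features %||% buildFeatures(rbind(presCov, bgCov), classes = classes,
                                    nPresences = m, nKnots = nKnots)
  Fmat <- featureMatrix(fs, all)
  Fpres <- featureMatrix(fs, presCov)
  n <- nrow(Fmat); nF <- ncol(Fmat)
  pbar <- colMeans(Fpres)

  if (is.null(beta)) {
    cls <- featureClassForBeta(fs$descriptors$type)
    rate <- vapply(cls, betaRate, 0, m = m)
    s <- apply(Fpres, 2, stats::sd)
    sAll <- apply(Fmat, 2, stats::sd)
    s[!is.finite(s) | s == 0] <- sAll[!is.finite(s) | s == 0]
    beta <- betaMultiplier * rate * s / sqrt(m)
  } else {
    beta <- rep_len(beta, nF)
  }
  beta <- pmax(beta, 0)

  lambda <- numeric(nF)
  eta <- numeric(n)
  logZ <- log(n)
  q <- rep(1 / n, n)
  objective <- function() sum(pbar * lambda) - logZ - sum(beta * abs(lambda))
  objTrace <- objective()

  iter <- 0L
  converged <- FALSE
  while (iter < maxIter) {
    iter <- iter + 1L
    for (j in seq_len(nF)) {
      Fj <- Fmat[, j]
      Ej <- sum(q * Fj)
      Vj <- sum(q * Fj^2) - Ej^2
      if (Vj < 1e-12) next
      z <- lambda[j] + (pbar[j] - Ej) / Vj
      lamNew <- softThreshold(z, beta[j] / Vj)
      delta <- lamNew - lambda[j]
      if (abs(delta) < 1e-12) next
      # backtrack on the exact objective so it never decreases
      for (bt in 1:12) {
        etaNew <- eta + delta * Fj
        logZNew <- logSumExp(etaNew)
        dObj <- pbar[j] * delta - (logZNew - logZ) -
          beta[j] * (abs(lambda[j] + delta) - abs(lambda[j]))
        if (dObj >= -1e-12) break
        delta <- delta / 2
      }
      if (dObj < -1e-12) next
      lambda[j] <- lambda[j] + delta
      eta <- etaNew; logZ <- logZNew
      q <- exp(eta - logZ)
    }
    objNew <- objective()
    objTrace <- c(objTrace, objNew)
    if (objNew - objTrace[length(objTrace) - 1L] < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    stop(sprintf(
      "maxent fit did not converge in %d cycles; objective trace tail: %s",
      maxIter,
      paste(sprintf("%.8g", utils::tail(objTrace, 5)), collapse = ", ")),
      call. = FALSE)

  H <- -sum(ifelse(q > 0, q * log(q), 0))
  new("MaxentModel", featureSet = fs, lambda = as.numeric(lambda),
      beta = as.numeric(beta), logZ = logZ, entropy = H,
      diagnostics = list(iterations = iter, objective = objTrace,
                         converged = converged, nPresence = m, nCells = n))
}

#' Predict from a fitted maxent model
#'
#' Raw output is the Gibbs density `q(x) = exp(lambda . f(x)) / Z` with the
#' normaliser from the fitting cells; logistic output is
#' `e^H q / (1 + e^H q)` with `H` the entropy of the fitted distribution
#' (default prevalence 0.5). Covariates outside the training bounds are
#' clamped.
#'
#' @param object a [MaxentModel-class].
#' @param covMat covariate matrix at the cells to predict.
#' @param type `"logistic"` (default) or `"raw"`.
#' @return numeric vector of predictions; `NA` rows propagate.
#' @export
setMethod("predict", "MaxentModel", function(object, covMat,
                                             type = c("logistic", "raw")) {
  type <- match.arg(type)
  covMat <- as.matrix(covMat)
  ok <- stats::complete.cases(covMat[, object@featureSet$covNames, drop = FALSE])
  out <- rep(NA_real_, nrow(covMat))
  if (any(ok)) {
    Fmat <- featureMatrix(object@featureSet, covMat[ok, , drop = FALSE])
    raw <- exp(as.vector(Fmat %*% object@lambda) - object@logZ)
    out[ok] <- if (type == "raw") raw else {
      eHq <- exp(object@entropy) * raw
      eHq / (1 + eHq)
    }
  }
  out
})

#' Predict a probability-of-occurrence surface
#'
#' Evaluates a fitted model over every cell of a covariate stack.
#'
#' @param model a [MaxentModel-class].
#' @param stack a [CovariateStack-class] containing the model's covariates.
#' @param type `"logistic"` or `"raw"`.
#' @return A [RasterGrid-class]; cells with any missing covariate are `NA`.
#' @export
predictSurface <- function(model, stack, type = "logistic") {
  g <- stack@grid
  cm <- covMatrix(stack, model@featureSet$covNames)
  p <- predict(model, cm, type = type)
  rasterGrid(matrix(p, g@nRows, g@nCols), g,
             name = paste0("prediction_", type))
}

#' Replicated 70-30 fit/evaluation protocol
#'
#' Runs `nRuns` replicates, each with a fresh randomised split of the
#' presence cells into training and test portions and a fresh background
#' sample from the candidate cells; fits on the training portion and scores
#' the held-out presences against the replicate's background by AUC.
#' Replicates that fail to fit are recorded and skipped; an error is raised
#' if fewer than 90% succeed. Deterministic given the master `seed`; calling
#' this with the same seed and different covariate sets yields paired
#' replicates (identical splits and backgrounds).
#'
#' @param presences data.frame of 0-based `row`, `col` presence cells
#'   (>= 10 distinct cells).
#' @param candidates data.frame of background candidate cells (e.g. from
#'   [targetGroupBackground()]).
#' @param stack a [CovariateStack-class].
#' @param covariates character; stack layers used as model covariates.
#' @param nRuns number of replicates (default 100).
#' @param trainFrac training fraction of presences (default 0.7).
#' @param nBackground background cells per replicate (default
#'   `min(10000, nrow(candidates))`).
#' @param seed master seed.
#' @param classes,betaMultiplier,tol,maxIter passed to [fitMaxent()].
#' @return data.frame with one row per replicate: `run`, `auc` (NA for
#'   failed runs) and `nTrain`/`nTest`.
#' @export
replicateFit <- function(presences, candidates, stack, covariates,
                         nRuns = 100L, trainFrac = 0.7,
                         nBackground = min(10000L, nrow(candidates)),
                         seed = 1L, classes = "auto", betaMultiplier = 1.0,
                         tol = 1e-5, maxIter = 2000L) {
  m <- nrow(presences)
  stopIfNot(m >= 10, "at least 10 presence cells are required")
  nTrain <- max(1L, round(trainFrac * m))
  nTest <- m - nTrain
  stopIfNot(nTest >= 1, "the test split is empty; lower trainFrac")

  auc <- rep(NA_real_, nRuns)
  for (r in seq_len(nRuns)) {
    set.seed(deriveSeed(seed, r))
    perm <- sample.int(m)
    trainIdx <- perm[seq_len(nTrain)]
    testIdx <- perm[(nTrain + 1L):m]
    bg <- sampleBackground(candidates, nBackground, seed = deriveSeed(seed, 100000L + r))
    trainCov <- covMatrix(stack, covariates, presences[trainIdx, , drop = FALSE])
    testCov <- covMatrix(stack, covariates, presences[testIdx, , drop = FALSE])
    bgCov <- covMatrix(stack, covariates, bg)
    fit <- tryCatch(
      fitMaxent(trainCov, bgCov, classes = classes,
                betaMultiplier = betaMultiplier, tol = tol, maxIter = maxIter),
      error = function(e) NULL)
    if (is.null(fit)) next
    auc[r] <- aucScore(predict(fit, testCov, type = "raw"),
                       predict(fit, bgCov, type = "raw"))
  }
  nFail <- sum(is.na(auc))
  if (nFail > 0.1 * nRuns)
    stop(sprintf("replicate protocol failed: %d of %d runs did not fit",
                 nFail, nRuns), call. = FALSE)
  data.frame(run = seq_len(nRuns), auc = auc, nTrain = nTrain, nTest = nTest)
}

#' Serialise / restore a fitted model as JSON
#'
#' Stores the feature definitions, bounds, weights, penalties, normaliser
#' and entropy; `readMaxentModel` reconstructs an equivalent
#' [MaxentModel-class].
#'
#' @param model a [MaxentModel-class].
#' @param path JSON path.
#' @return `writeMaxentModel` returns `path` invisibly; `readMaxentModel`
#'   the restored model.
#' @export
writeMaxentModel <- function(model, path) {
  fs <- model@featureSet
  jsonlite::write_json(list(
    covNames = fs$covNames,
    bounds = as.data.frame(fs$bounds),
    classes = fs$classes,
    knots = fs$knots,
    descriptors = fs$descriptors,
    lambda = model@lambda,
    beta = model@beta,
    logZ = model@logZ,
    entropy = model@entropy
  ), path, digits = NA)
  invisible(path)
}

#' @rdname writeMaxentModel
#' @export
readMaxentModel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  bounds <- as.matrix(x$bounds)
  rownames(bounds) <- NULL
  fs <- list(covNames = x$covNames, bounds = bounds, classes = x$classes,
             knots = x$knots, descriptors = x$descriptors,
             nFeatures = nrow(x$descriptors))
  new("MaxentModel", featureSet = fs, lambda = x$lambda, beta = x$beta,
      logZ = x$logZ, entropy = x$entropy,
      diagnostics = list(iterations = NA_integer_, converged = TRUE,
                         restored = TRUE))
}
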