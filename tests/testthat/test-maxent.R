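# Maximum-entropy model: feature expansion, L1 fitting, prediction and the
# replicate protocol.

# independent objective evaluation used by the oracle checks
maxentObjective <- function(lambda, fs, presCov, fitCov, beta) {
  Fall <- featureMatrix(fs, fitCov)
  Fp <- featureMatrix(fs, presCov)
  eta <- as.vector(Fall %*% lambda)
  mx <- max(eta)
  mean(Fp %*% lambda) - (mx + log(sum(exp(eta - mx)))) - sum(beta * abs(lambda))
}

test_that("auto feature classes follow the sample-size rule", {
  cm <- cbind(a = runif(100), b = runif(100))
  f12 <- buildFeatures(cm, "auto", nPresences = 12)
  expect_setequal(f12$classes, c("linear", "quadratic"))
  expect_equal(f12$nFeatures, 4)

  f100 <- buildFeatures(cm, "auto", nPresences = 100)
  expect_setequal(f100$classes, c("linear", "quadratic", "hinge", "product"))
  # 2 linear + 2 quadratic + 1 product + 2 covs x 2 orientations x 10 knots
  expect_equal(f100$nFeatures, 45)

  f5 <- buildFeatures(cm, "auto", nPresences = 5)
  expect_equal(f5$classes, "linear")

  expect_warning(
    fc <- buildFeatures(cbind(a = runif(20), b = 1), "auto", nPresences = 50),
    "constant covariate")
  expect_equal(fc$covNames, "a")
})

test_that("features are scaled to [0,1] with clamping outside bounds", {
  cm <- cbind(a = c(2, 4, 6))
  fs <- buildFeatures(cm, "linear", nPresences = 3)
  Fm <- featureMatrix(fs, cbind(a = c(0, 2, 4, 6, 10)))
  expect_equal(as.vector(Fm), c(0, 0, 0.5, 1, 1))
})

test_that("the two-cell binary-feature L1 example matches the KKT oracle", {
  pres <- matrix(1, 1, 1, dimnames = list(NULL, "x"))
  bg <- matrix(c(0, 1), 2, 1, dimnames = list(NULL, "x"))
  fit <- fitMaxent(pres, bg, classes = "linear", beta = 0.1,
                   addPresences = FALSE, tol = 1e-12)
  # L1 shrinks the constraint E_q f = 1 to 1 - beta = 0.9, so lambda = ln 9
  expect_equal(fit@lambda, log(9), tolerance = 1e-6)
  q <- predict(fit, bg, type = "raw")
  expect_equal(q, c(0.1, 0.9), tolerance = 1e-6)
})

test_that("the fitted objective matches exhaustive grid search", {
  set.seed(9)
  bg <- cbind(a = c(0.1, 0.4, 0.9, 0.6, 0.2, 0.75))
  pres <- bg[c(3, 4, 6), , drop = FALSE]
  fit <- fitMaxent(pres, bg, classes = c("linear", "quadratic"),
                   addPresences = FALSE, tol = 1e-12, maxIter = 10000)
  obj <- function(l) maxentObjective(l, fit@featureSet, pres, bg, fit@beta)

  grid <- seq(-10, 10, by = 0.1)
  best <- -Inf; bestL <- c(0, 0)
  for (l1 in grid) for (l2 in grid) {
    o <- obj(c(l1, l2))
    if (o > best) { best <- o; bestL <- c(l1, l2) }
  }
  for (zoom in 1:3) {
    local <- seq(-0.15, 0.15, by = 0.005)
    for (l1 in bestL[1] + local) for (l2 in bestL[2] + local) {
      o <- obj(c(l1, l2))
      if (o > best) { best <- o; bestL <- c(l1, l2) }
    }
  }
  fitted <- utils::tail(fit@diagnostics$objective, 1)
  expect_lt(abs(fitted - best), 1e-6)
})

test_that("with beta = 0 the fitted expectations equal the presence means", {
  set.seed(3)
  bg <- cbind(a = runif(30), b = runif(30))
  pres <- bg[sample(30, 12, prob = exp(2 * bg[, 1])), ]
  fit <- fitMaxent(pres, bg, classes = c("linear", "quadratic"), beta = 0,
                   addPresences = FALSE, tol = 1e-10, maxIter = 5000)
  Fall <- featureMatrix(fit@featureSet, bg)
  q <- predict(fit, bg, type = "raw")
  expect_lt(max(abs(colSums(q * Fall) - colMeans(featureMatrix(fit@featureSet, pres)))),
            1e-4)
})

test_that("an overwhelming penalty returns the uniform distribution", {
  set.seed(4)
  bg <- cbind(a = runif(40), b = runif(40))
  pres <- bg[1:10, ]
  fit <- fitMaxent(pres, bg, classes = "linear", beta = 1e6,
                   addPresences = FALSE)
  expect_true(all(fit@lambda == 0))
  expect_equal(predict(fit, bg, type = "raw"), rep(1 / 40, 40))
  expect_equal(predict(fit, bg, type = "logistic"), rep(0.5, 40))
})

test_that("the fitted distribution is normalised and the objective ascends", {
  occ <- sharedOccurrence()
  stack <- sharedStack()
  covs <- c("temperature", "elevation", "dwt")
  pres <- covMatrix(stack, covs, occ$presences[1:60, ])
  bg <- covMatrix(stack, covs, occ$candidates[1:300, ])
  fit <- fitMaxent(pres, bg)
  q <- predict(fit, rbind(pres, bg), type = "raw")
  expect_equal(sum(q), 1, tolerance = 1e-8)
  expect_true(all(diff(fit@diagnostics$objective) >= -1e-12))
})

test_that("the objective is invariant to affine covariate rescaling", {
  set.seed(12)
  bg <- cbind(a = runif(50, 10, 30), b = runif(50, -5, 5))
  pres <- bg[sample(50, 20, prob = exp(bg[, 2])), ]
  f1 <- fitMaxent(pres, bg, classes = c("linear", "quadratic", "hinge"),
                  addPresences = FALSE, tol = 1e-9)
  rescale <- function(m) cbind(a = 100 * m[, "a"] - 7, b = m[, "b"] / 3 + 2)
  f2 <- fitMaxent(rescale(pres), rescale(bg),
                  classes = c("linear", "quadratic", "hinge"),
                  addPresences = FALSE, tol = 1e-9)
  expect_equal(utils::tail(f1@diagnostics$objective, 1),
               utils::tail(f2@diagnostics$objective, 1), tolerance = 1e-6)
})

test_that("predictions are self-consistent and logistic is monotone in raw", {
  set.seed(5)
  bg <- cbind(a = runif(40), b = runif(40))
  pres <- bg[sample(40, 15, prob = exp(bg[, 1])), ]
  fit <- fitMaxent(pres, bg, addPresences = FALSE)
  Fall <- featureMatrix(fit@featureSet, bg)
  qManual <- exp(as.vector(Fall %*% fit@lambda) - fit@logZ)
  expect_equal(predict(fit, bg, type = "raw"), qManual, tolerance = 1e-10)

  raw <- predict(fit, bg, type = "raw")
  logi <- predict(fit, bg, type = "logistic")
  expect_equal(order(raw), order(logi))
  expect_true(all(logi > 0 & logi < 1))

  # missing covariates propagate as NA
  bgNA <- bg; bgNA[3, 1] <- NA
  expect_true(is.na(predict(fit, bgNA)[3]))
})

test_that("models round-trip through JSON serialisation", {
  set.seed(15)
  bg <- cbind(a = runif(40), b = runif(40))
  pres <- bg[sample(40, 20, prob = exp(bg[, 1])), ]
  fit <- fitMaxent(pres, bg, addPresences = FALSE)
  path <- withr::local_tempfile(fileext = ".json")
  writeMaxentModel(fit, path)
  back <- readMaxentModel(path)
  expect_equal(back@lambda, fit@lambda)
  expect_equal(back@logZ, fit@logZ)
  expect_equal(predict(back, bg, type = "logistic"),
               predict(fit, bg, type = "logistic"), tolerance = 1e-12)
})

test_that("the replicate protocol is deterministic and reduces to one run", {
  occ <- sharedOccurrence()
  stack <- sharedStack()
  covs <- c("temperature", "precipitation", "elevation", "dwt")
  a1 <- replicateFit(occ$presences, occ$candidates, stack, covs, nRuns = 5,
                     seed = 77)
  a2 <- replicateFit(occ$presences, occ$candidates, stack, covs, nRuns = 5,
                     seed = 77)
  expect_identical(a1$auc, a2$auc)
  expect_false(anyNA(a1$auc))
  expect_true(all(a1$auc > 0 & a1$auc < 1))

  one <- replicateFit(occ$presences, occ$candidates, stack, covs, nRuns = 1,
                      seed = 3)
  expect_equal(nrow(one), 1)
  expect_error(replicateFit(occ$presences[1:5, ], occ$candidates, stack, covs,
                            nRuns = 2, seed = 1),
               "at least 10")
})
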