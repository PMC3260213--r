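# Permutation importance, AUC, model comparison and response curves.

test_that("bootstrap out-of-bag fractions concentrate near 1/e", {
  set.seed(2)
  n <- 1000
  dat <- data.frame(x1 = runif(n), x2 = runif(n))
  y <- as.integer(dat$x1 > 0.5)
  forest <- fitBaggedTrees(dat, y, nTrees = 60, seed = 4)
  oobFrac <- vapply(forest$trees, function(t) length(t$oob) / n, 0)
  expect_true(all(oobFrac > 0.30 & oobFrac < 0.44))
  expect_lt(abs(mean(oobFrac) - exp(-1)), 0.01)
})

test_that("a separable problem reaches high out-of-bag accuracy", {
  set.seed(3)
  dat <- data.frame(x1 = runif(400))
  y <- as.integer(dat$x1 > 0.5)
  forest <- fitBaggedTrees(dat, y, nTrees = 60, seed = 9)
  acc <- mean(vapply(forest$trees, `[[`, 0, "oobAcc"), na.rm = TRUE)
  expect_gt(acc, 0.95)

  again <- fitBaggedTrees(dat, y, nTrees = 60, seed = 9)
  expect_identical(vapply(forest$trees, `[[`, 0, "oobAcc"),
                   vapply(again$trees, `[[`, 0, "oobAcc"))
  expect_error(fitBaggedTrees(dat, rep(1, 400), nTrees = 5, seed = 1),
               "two classes")
})

test_that("permuting an unused covariate decreases accuracy by exactly zero", {
  set.seed(5)
  dat <- data.frame(x1 = runif(300), dead = rep(c(0.4, 0.6), 150))
  # response depends only on x1; 'dead' is constant within each class pattern
  y <- as.integer(dat$x1 > 0.5)
  dat$dead <- 0.5  # constant: no tree can split on it
  forest <- fitBaggedTrees(dat, y, nTrees = 40, seed = 2)
  mda <- meanDecreaseAccuracy(forest, dat, "dead", seed = 1)
  expect_true(all(mda$decreases == 0))
  expect_equal(mda$importance, 0)
  expect_error(meanDecreaseAccuracy(forest, dat, "nope", seed = 1),
               "not in the fitted forest")
})

test_that("signal covariates outrank noise and noise importance is near zero", {
  set.seed(6)
  n <- 400
  dat <- data.frame(x1 = runif(n), x2 = runif(n))
  y <- as.integer(dat$x1 > 0.5)
  flip <- sample(n, round(0.05 * n))
  y[flip] <- 1L - y[flip]
  forest <- fitBaggedTrees(dat, y, nTrees = 150, seed = 8)
  i1 <- meanDecreaseAccuracy(forest, dat, "x1", seed = 3)
  i2 <- meanDecreaseAccuracy(forest, dat, "x2", seed = 3)
  expect_gt(i1$importance, i2$importance)
  expect_lt(abs(i2$importance), 2)

  # the importance table is invariant to covariate column order
  datSwap <- dat[, c("x2", "x1")]
  forestSwap <- fitBaggedTrees(datSwap, y, nTrees = 150, seed = 8)
  t1 <- importanceTable(forest, dat, seed = 5)
  t2 <- importanceTable(forestSwap, datSwap, seed = 5)
  expect_equal(t1[order(t1$covariate), "meanDecrease"],
               t2[order(t2$covariate), "meanDecrease"], tolerance = 0.05)
  expect_equal(t1$covariate[1], "x1")
  expect_equal(t2$covariate[1], "x1")
})

test_that("AUC matches direct pair counting, including ties", {
  expect_equal(aucScore(c(0.9, 0.4), c(0.5, 0.1)), 0.75)
  expect_equal(aucScore(c(1, 1), c(0, 0)), 1)
  expect_equal(aucScore(rep(0.5, 5), rep(0.5, 7)), 0.5)
  expect_error(aucScore(numeric(0), 1), "non-empty")

  bruteAuc <- function(sp, sb) {
    tot <- 0
    for (p in sp) for (b in sb)
      tot <- tot + if (p > b) 1 else if (p == b) 0.5 else 0
    tot / (length(sp) * length(sb))
  }
  set.seed(11)
  for (i in 1:10) {
    # discrete scores force plenty of ties
    sp <- sample(seq(0, 1, by = 0.1), 100, replace = TRUE)
    sb <- sample(seq(0, 1, by = 0.1), 100, replace = TRUE)
    expect_equal(aucScore(sp, sb), bruteAuc(sp, sb), tolerance = 1e-12)
    expect_equal(aucScore(sp, sb) + aucScore(sb, sp), 1, tolerance = 1e-12)
  }
})

test_that("paired AUC comparison flags ties, shifts and simulated gaps", {
  x <- seq(0.7, 0.9, length.out = 100)
  same <- compareModels(x, x)
  expect_equal(same$better, "tie")
  expect_equal(same$meanDiff, 0)

  shifted <- compareModels(x + 0.05, x)
  expect_equal(shifted$better, "A")
  expect_true(shifted$degenerate)

  expect_error(compareModels(x, x[1:50]), "equal-length")

  # power: N(0.80, 0.02) vs N(0.78, 0.02), n = 100 paired
  wins <- 0
  for (s in 1:40) {
    set.seed(s)
    a <- rnorm(100, 0.80, 0.02)
    b <- rnorm(100, 0.78, 0.02)
    r <- compareModels(a, b)
    wins <- wins + (r$better == "A" && r$p < 0.05)
  }
  expect_gte(wins / 40, 0.95)
})

test_that("response curves recover a constructed exponential dwt response", {
  stack <- sharedStack()
  dwt <- covLayer(stack, "dwt")
  surf <- rasterGrid(exp(-layerValues(dwt) / 0.5), stack@grid, "p")
  rc <- responseCurve(surf, dwt, n = 1000, seed = 4)

  # identical seed gives identical samples
  rc2 <- responseCurve(surf, dwt, n = 1000, seed = 4)
  expect_identical(rc@samples, rc2@samples)

  # monotone non-increasing up to numerical spline overshoot (1% of range)
  tolInc <- 0.01 * diff(range(rc@splineY))
  expect_true(all(diff(rc@splineY) <= tolInc))

  # shallow bins outscore deep bins
  shallow <- rc@binMeans[rc@binCenters >= 0 & rc@binCenters < 1]
  deep <- rc@binMeans[rc@binCenters >= 3 & rc@binCenters < 4]
  expect_gt(mean(shallow, na.rm = TRUE), mean(deep, na.rm = TRUE))

  # half-maximum depth within a factor 2 of the generating delta * ln 2
  hm <- halfMaximumDwt(rc)
  expect_gt(hm, 0.5 * log(2) / 2)
  expect_lt(hm, 0.5 * log(2) * 2)
})

test_that("a constant surface yields flat bins and a flat spline", {
  stack <- sharedStack()
  dwt <- covLayer(stack, "dwt")
  surf <- rasterGrid(matrix(0.4, stack@grid@nRows, stack@grid@nCols),
                     stack@grid, "p")
  rc <- responseCurve(surf, dwt, n = 500, seed = 2)
  expect_true(all(abs(rc@binMeans - 0.4) < 1e-12, na.rm = TRUE))
  expect_true(all(abs(rc@splineY - 0.4) < 1e-6))

  # requesting more samples than valid cells takes them all, with a warning
  small <- rasterGrid(matrix(0.4, 4, 4), gridSpec(30, -100, 1/6, 4, 4))
  sdwt <- rasterGrid(matrix(seq(0, 3, length.out = 16), 4, 4),
                     gridSpec(30, -100, 1/6, 4, 4))
  expect_warning(responseCurve(small, sdwt, n = 99, nBins = 4, seed = 1),
                 "valid cells")
})
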