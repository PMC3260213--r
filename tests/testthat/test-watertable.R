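# Equilibrium water-table solver.

flatGrid <- function(nr = 8, nc = 8) gridSpec(40, -100, 1/6, nr, nc)

test_that("lateral flux follows the depth-decayed transmissivity form", {
  g <- flatGrid(1, 2)
  land <- landscape(g, elevation = matrix(c(11, 10), 1, 2), recharge = 0,
                    T0 = 1000, f = 2)
  state <- new("WaterTableState",
               dwt = matrix(0, 1, 2),
               head = matrix(c(11, 10), 1, 2),
               iterations = 0L, maxDelta = 0)
  # head difference 1 m at zero depth: Q = T0 (with w = dx)
  expect_equal(lateralFlux(state, c(0, 0), c(0, 1), land), 1000)
  # antisymmetry
  expect_equal(lateralFlux(state, c(0, 1), c(0, 0), land), -1000)
  # equal heads: no flux
  state@head <- matrix(10, 1, 2)
  expect_equal(lateralFlux(state, c(0, 0), c(0, 1), land), 0)
  # raising the mean depth from 0 to f multiplies the flux by exp(-1)
  state@head <- matrix(c(11, 10), 1, 2)
  state@dwt <- matrix(2, 1, 2)
  expect_equal(lateralFlux(state, c(0, 0), c(0, 1), land), 1000 * exp(-1))
  expect_error(lateralFlux(state, c(0, 0), c(0, 2), land), "4-neighbours")
})

test_that("a flat closed basin with positive recharge ponds everywhere", {
  land <- landscape(flatGrid(), elevation = 50, recharge = 0.5)
  state <- solveEquilibrium(land)
  expect_true(all(state@dwt == 0))
  expect_true(all(state@head == 50))
})

test_that("zero recharge equilibrates to the fixed boundary depth", {
  bm <- matrix(FALSE, 8, 8); bm[1, 1] <- TRUE
  land <- landscape(flatGrid(), elevation = 50, recharge = 0,
                    boundaryMask = bm, boundaryDepth = 2)
  state <- solveEquilibrium(land, tol = 1e-6)
  expect_lt(max(abs(state@dwt - 2)), 1e-3)  # within 1 mm everywhere
  expect_equal(state@dwt[1, 1], 2)          # fixed cell held exactly
})

test_that("a single active cell matches the scalar root-finding oracle", {
  g <- flatGrid(1, 2)
  bm <- matrix(c(TRUE, FALSE), 1, 2)
  land <- landscape(g, elevation = 50, recharge = 0.05,
                    boundaryMask = bm, boundaryDepth = 2)
  state <- solveEquilibrium(land, tol = 1e-8)
  # equilibrium: R * A = T((d + 2) / 2) * (h - h_b), h = z - d, h_b = z - 2
  A <- land@cellLength^2
  balance <- function(d)
    0.05 * A - land@T0 * exp(-((d + 2) / 2) / land@f) * (2 - d)
  oracle <- uniroot(balance, c(0, 2), tol = 1e-12)$root
  expect_lt(abs(state@dwt[1, 2] - oracle), 1e-3)
})

test_that("unbounded drawdown without a boundary raises an error", {
  land <- landscape(flatGrid(4, 4), elevation = 50, recharge = -0.5)
  expect_error(solveEquilibrium(land, maxDepth = 50), "unbounded drawdown")
})

test_that("wetland mask thresholds at 1 m inclusively and propagates nodata", {
  m <- matrix(c(0.5, 1.0, 1.5, NA), 2, 2)
  r <- rasterGrid(m, flatGrid(2, 2), "dwt")
  w <- wetlandMask(r)
  expect_equal(layerValues(w)[1, 1], 1)   # 0.5 m is wetland
  expect_equal(layerValues(w)[2, 1], 1)   # exactly 1.0 m is wetland
  expect_equal(layerValues(w)[1, 2], 0)
  expect_true(is.na(layerValues(w)[2, 2]))
  expect_true(all(wetlandMask(matrix(10, 3, 3)) == FALSE))
  expect_error(wetlandMask(m, threshold = -1), "non-negative")
})

test_that("mass balance closes at equilibrium and tightens with tol", {
  set.seed(2)
  g <- flatGrid(10, 10)
  elev <- 40 + matrix(cumsum(rnorm(100, sd = 0.3)), 10, 10)
  bm <- matrix(FALSE, 10, 10); bm[5, 5] <- TRUE
  land <- landscape(g, elev, recharge = 0.3, boundaryMask = bm,
                    boundaryDepth = 0.5)
  state <- solveEquilibrium(land, tol = 1e-5)
  expect_lt(massBalanceResidual(state, land), 0.01)

  # zero-recharge flat case: residual is (numerically) zero
  bm2 <- matrix(FALSE, 8, 8); bm2[1, 1] <- TRUE
  flat <- landscape(flatGrid(), elevation = 50, recharge = 0,
                    boundaryMask = bm2, boundaryDepth = 2)
  expect_lt(massBalanceResidual(solveEquilibrium(flat, tol = 1e-8), flat), 1e-5)

  # refinement: residual decreases monotonically with tighter tolerance
  res <- vapply(c(1e-2, 1e-4, 1e-6), function(tol)
    massBalanceResidual(solveEquilibrium(land, tol = tol), land), 0)
  expect_true(all(diff(res) <= 1e-12))
})

test_that("equilibrium is invariant to a constant elevation shift", {
  set.seed(6)
  g <- flatGrid(6, 6)
  elev <- 30 + matrix(rnorm(36, sd = 2), 6, 6)
  bm <- matrix(FALSE, 6, 6); bm[2, 3] <- TRUE
  land1 <- landscape(g, elev, recharge = 0.2, boundaryMask = bm,
                     boundaryDepth = 1)
  land2 <- landscape(g, elev + 100, recharge = 0.2, boundaryMask = bm,
                     boundaryDepth = 1)
  s1 <- solveEquilibrium(land1, tol = 1e-6)
  s2 <- solveEquilibrium(land2, tol = 1e-6)
  expect_equal(s1@dwt, s2@dwt, tolerance = 1e-6)
})

test_that("more recharge never deepens the water table", {
  set.seed(7)
  g <- flatGrid(6, 6)
  elev <- 30 + matrix(rnorm(36, sd = 3), 6, 6)
  bm <- matrix(FALSE, 6, 6); bm[6, 6] <- TRUE
  low <- landscape(g, elev, recharge = 0.1, boundaryMask = bm,
                   boundaryDepth = 3)
  high <- landscape(g, elev, recharge = 0.3, boundaryMask = bm,
                    boundaryDepth = 3)
  sLow <- solveEquilibrium(low, tol = 1e-6)
  sHigh <- solveEquilibrium(high, tol = 1e-6)
  expect_true(all(sHigh@dwt <= sLow@dwt + 1e-4))
})

test_that("valleys are wetter than ridges on a V-shaped transect", {
  g <- flatGrid(1, 21)
  elev <- matrix(30 + 3 * abs(seq(-10, 10)), 1, 21)  # ridge at both ends
  bm <- matrix(FALSE, 1, 21); bm[1, 11] <- TRUE      # river at the valley axis
  land <- landscape(g, elev, recharge = 0.2, boundaryMask = bm,
                    boundaryDepth = 0)
  state <- solveEquilibrium(land, tol = 1e-6)
  expect_lte(state@dwt[1, 11], state@dwt[1, 1])
  expect_lte(state@dwt[1, 11], state@dwt[1, 21])
  expect_true(all(state@dwt >= 0))
})
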