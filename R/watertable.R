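# watertable_sim module: a simplified gridded equilibrium depth-to-water-table
# solver. Climate recharge is balanced against lateral groundwater flow with
# transmissivity decaying exponentially with water-table depth, so valleys and
# coasts end up wet and ridges dry.

#' Construct a Landscape
#'
#' @param grid a [GridSpec-class].
#' @param elevation metres, `nRows x nCols` matrix (row 1 = south).
#' @param recharge metres/year per cell (precipitation minus
#'   evapotranspiration); scalars are recycled.
#' @param boundaryMask logical matrix marking fixed-head cells (rivers,
#'   ocean); `NULL` for none.
#' @param boundaryDepth fixed water-table depth (m) at masked cells; scalar
#'   or matrix.
#' @param T0 transmissivity scale, m^2/year.
#' @param f e-folding depth of the transmissivity decay, metres.
#' @param cellLength cell edge length, metres.
#' @return A [Landscape-class].
#' @export
landscape <- function(grid, elevation, recharge, boundaryMask = NULL,
                      boundaryDepth = 0, T0 = 2e7, f = 3,
                      cellLength = 18500) {
  dims <- c(grid@nRows, grid@nCols)
  asMat <- function(x) {
    if (is.matrix(x)) x else matrix(x, dims[1], dims[2])
  }
  if (is.null(boundaryMask)) boundaryMask <- matrix(FALSE, dims[1], dims[2])
  new("Landscape", grid = grid, elevation = asMat(elevation),
      recharge = asMat(recharge), boundaryMask = boundaryMask,
      boundaryDepth = asMat(boundaryDepth), T0 = T0, f = f,
      cellLength = cellLength)
}

# transmissivity at depth d
transmissivity <- function(d, T0, f) T0 * exp(-d / f)

#' Lateral groundwater flux between neighbouring cells
#'
#' `Q_ij = T(dbar) * (h_i - h_j) / dx * w`, where `T(d) = T0 exp(-d/f)` is
#' evaluated at the arithmetic mean depth of the two cells and `w = dx =
#' cellLength`. Antisymmetric: `Q_ij = -Q_ji`. Units m^3/year.
#'
#' @param state a [WaterTableState-class].
#' @param cellI,cellJ 0-based `c(row, col)` of two 4-neighbouring cells.
#' @param landscape the [Landscape-class].
#' @return Flux from `cellI` to `cellJ` in m^3/year.
#' @export
lateralFlux <- function(state, cellI, cellJ, landscape) {
  stopIfNot(sum(abs(cellI - cellJ)) == 1L, "cells must be 4-neighbours")
  i <- cbind(cellI[1] + 1L, cellI[2] + 1L)
  j <- cbind(cellJ[1] + 1L, cellJ[2] + 1L)
  dbar <- (state@dwt[i] + state@dwt[j]) / 2
  Tij <- transmissivity(dbar, landscape@T0, landscape@f)
  # w / dx = 1 for square cells
  Tij * (state@head[i] - state@head[j])
}

# shift helpers: neighbour values with NA outside the grid
shiftRowUp <- function(m) rbind(m[-1, , drop = FALSE], NA)           # row + 1
shiftRowDown <- function(m) rbind(NA, m[-nrow(m), , drop = FALSE])   # row - 1
shiftColRight <- function(m) cbind(m[, -1, drop = FALSE], NA)        # col + 1
shiftColLeft <- function(m) cbind(NA, m[, -ncol(m), drop = FALSE])   # col - 1

# per-cell net lateral outflow (m^3/yr) for a given depth/head field
netOutflow <- function(d, h, T0, f) {
  flux <- function(dN, hN) {
    Tn <- transmissivity((d + dN) / 2, T0, f)
    q <- Tn * (h - hN)
    q[is.na(q)] <- 0
    q
  }
  flux(shiftRowUp(d), shiftRowUp(h)) + flux(shiftRowDown(d), shiftRowDown(h)) +
    flux(shiftColRight(d), shiftColRight(h)) + flux(shiftColLeft(d), shiftColLeft(h))
}

#' Solve for the equilibrium water table
#'
#' Damped Picard/Jacobi iteration on the head field: starting from the water
#' table at the surface, each cell's head is relaxed towards the value that
#' balances recharge against lateral flow at the current transmissivities,
#' ponded cells are clipped to the surface (`dwt >= 0`), and fixed-head cells
#' are held at their prescribed depth. Iteration stops when the largest
#' per-cell depth change is below `tol` (default 1 mm, i.e. 0.001 m).
#' Deterministic given its inputs.
#'
#' @param landscape a [Landscape-class].
#' @param tol convergence tolerance on the per-iteration depth change, m.
#' @param maxIter iteration cap.
#' @param relax damping factor `0 < relax <= 1`.
#' @param maxDepth depth (m) beyond which drawdown is declared unbounded
#'   when the landscape has no fixed-head cell.
#' @return A [WaterTableState-class].
#' @export
solveEquilibrium <- function(landscape, tol = 0.001, maxIter = 50000,
                             relax = 0.5, maxDepth = 1000) {
  stopIfNot(relax > 0 && relax <= 1, "relax must be in (0, 1]")
  g <- landscape@grid
  z <- landscape@elevation
  R <- landscape@recharge
  A <- landscape@cellLength^2
  T0 <- landscape@T0; f <- landscape@f
  fixed <- landscape@boundaryMask
  hFix <- z - landscape@boundaryDepth
  hasBoundary <- any(fixed)

  d <- matrix(0, g@nRows, g@nCols)  # start with the water table at the surface
  d[fixed] <- landscape@boundaryDepth[fixed]
  h <- z - d

  # red-black Gauss-Seidel: updating the two colours alternately removes the
  # checkerboard oscillation a simultaneous update suffers here
  red <- (outer(seq_len(g@nRows), seq_len(g@nCols), "+") %% 2L) == 0L

  halfSweep <- function(d, h, mask) {
    num <- R * A
    den <- matrix(0, g@nRows, g@nCols)
    for (sh in list(shiftRowUp, shiftRowDown, shiftColRight, shiftColLeft)) {
      dN <- sh(d); hN <- sh(h)
      Tn <- transmissivity((d + dN) / 2, T0, f)
      Tn[is.na(Tn)] <- 0
      hN[is.na(hN)] <- 0
      num <- num + Tn * hN
      den <- den + Tn
    }
    hJac <- ifelse(den > 0, num / den, h)
    # per-cell adaptive damping: the head update overshoots where the
    # equilibrium head excess R*A/sum(T) is large relative to the
    # transmissivity e-folding depth, so damp by that local stiffness
    stiff <- abs(R) * A / (2 * f * pmax(den, .Machine$double.xmin))
    omega <- relax / (1 + stiff)
    hNew <- h
    hNew[mask] <- (h + omega * (hJac - h))[mask]
    hNew[fixed] <- hFix[fixed]
    hNew <- pmin(hNew, z)           # ponded water clipped to the surface
    list(d = z - hNew, h = hNew)
  }

  iter <- 0L
  delta <- Inf
  while (iter < maxIter) {
    iter <- iter + 1L
    s <- halfSweep(d, h, red)
    s <- halfSweep(s$d, s$h, !red)
    if (!hasBoundary && max(s$d) > maxDepth)
      stop(sprintf(
        "unbounded drawdown: depth exceeded %g m with no fixed-head boundary",
        maxDepth), call. = FALSE)
    delta <- max(abs(s$d - d))
    d <- s$d; h <- s$h
    if (delta < tol) break
  }
  if (delta >= tol)
    stop(sprintf(
      "water-table solver did not converge in %d iterations (last delta %.3g m, tol %.3g m)",
      maxIter, delta, tol), call. = FALSE)
  new("WaterTableState", dwt = d, head = h, iterations = iter, maxDelta = delta)
}

#' Threshold a water-table layer into a wetland mask
#'
#' Cells are wetland where the water table is within `threshold` metres of
#' the surface (`dwt <= threshold`; the 1.0 m default is the depth at which
#' the simulated water table best matches field-mapped wetlands). Nodata
#' propagates.
#'
#' @param dwt a [RasterGrid-class] or matrix of depths (m).
#' @param threshold metres; must be non-negative.
#' @return Logical matrix (or [RasterGrid-class] when given one) with `NA`
#'   where `dwt` is `NA`.
#' @export
wetlandMask <- function(dwt, threshold = 1.0) {
  stopIfNot(threshold >= 0, "threshold must be non-negative")
  if (is(dwt, "RasterGrid")) {
    out <- dwt
    out@values <- (dwt@values <= threshold) * 1
    out@name <- "wetland"
    return(out)
  }
  dwt <= threshold
}

#' Mass-balance residual of a converged state
#'
#' For every active, non-ponded cell the equilibrium condition is
#' `recharge * area = net lateral outflow`. The residual is the summed
#' absolute imbalance over those cells, relative to the total absolute
#' recharge (or, when recharge is identically zero, to the reference flux
#' `T0`). Near zero for a converged state.
#'
#' @param state a [WaterTableState-class].
#' @param landscape the [Landscape-class] it was solved on.
#' @return Non-negative fraction.
#' @export
massBalanceResidual <- function(state, landscape) {
  A <- landscape@cellLength^2
  active <- !landscape@boundaryMask
  nonPonded <- active & state@dwt > 0
  out <- netOutflow(state@dwt, state@head, landscape@T0, landscape@f)
  imbalance <- landscape@recharge * A - out
  num <- sum(abs(imbalance[nonPonded]))
  den <- sum(abs(landscape@recharge[active] * A))
  if (den == 0) den <- landscape@T0  # reference flux for zero-recharge cases
  num / den
}
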