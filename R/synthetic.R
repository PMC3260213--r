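# synthetic_data module: covariate stacks and multi-species banding records
# with known ground truth. The generator emulates the statistical structure of
# the study inputs: banding effort clustered at survey stations, terminal
# recoveries displaced by season-dependent daily movement, and a covariate
# stack in which the water table is the equilibrium of climate recharge vs.
# topographic drainage and percent wetland is negatively correlated with it.

# ---------------------------------------------------------------------------
# niches and effort
# ---------------------------------------------------------------------------

#' Construct a SpeciesNiche
#'
#' @param species species code.
#' @param dwtScale metres; e-folding depth of water-table affinity (small =
#'   strong wetland affinity).
#' @param tempOpt,tempSd thermal optimum and breadth, degrees C.
#' @param seasonalCenter named numeric with range-centre latitude for
#'   `spring`, `summer`, `fall`, `winter`.
#' @param rangeSd latitudinal breadth, degrees.
#' @param migrationWeeks list with `spring` and `fall` `c(first, last)`
#'   0-based inclusive weeks.
#' @param baseVelocity,migrationVelocity km/day outside/inside migration
#'   (defaults 3 and 16).
#' @return A [SpeciesNiche-class].
#' @export
speciesNiche <- function(species, dwtScale, tempOpt = 12, tempSd = 6,
                         seasonalCenter = c(spring = 35, summer = 37.5,
                                            fall = 35, winter = 32.5),
                         rangeSd = 2.5,
                         migrationWeeks = list(spring = c(12L, 16L),
                                               fall = c(38L, 42L)),
                         baseVelocity = 3, migrationVelocity = 16) {
  new("SpeciesNiche", species = species, dwtScale = dwtScale,
      tempOpt = tempOpt, tempSd = tempSd, seasonalCenter = seasonalCenter,
      rangeSd = rangeSd, migrationWeeks = migrationWeeks,
      baseVelocity = baseVelocity, migrationVelocity = migrationVelocity)
}

#' Default synthetic study species
#'
#' Two co-sampled species spanning the wetland-affinity gradient seen across
#' waterfowl: a strongly wetland-affine species (`dwtScale` 0.5 m, in the
#' teal/black-duck mould) and a generalist (`dwtScale` 3 m, goose-like) with
#' offset migration timing.
#'
#' @param dwtScales named numeric of affinity scales per species code.
#' @return named list of [SpeciesNiche-class] objects.
#' @export
defaultNiches <- function(dwtScales = c(WAFF = 0.5, GENE = 3)) {
  weeks <- list(list(spring = c(12L, 16L), fall = c(38L, 42L)),
                list(spring = c(10L, 14L), fall = c(40L, 44L)))
  out <- list()
  for (i in seq_along(dwtScales)) {
    sp <- names(dwtScales)[i]
    out[[sp]] <- speciesNiche(sp, dwtScale = dwtScales[[i]],
                              tempOpt = c(12, 10)[((i - 1) %% 2) + 1],
                              migrationWeeks = weeks[[((i - 1) %% 2) + 1]])
  }
  out
}

#' True annual-cycle windows implied by a niche
#'
#' Converts the niche's ground-truth migration weeks to day-of-year season
#' windows, the reference against which detected windows are scored.
#'
#' @param niche a [SpeciesNiche-class].
#' @return A [SeasonWindows-class] with source `"prior"`.
#' @export
trueSeasonWindows <- function(niche) {
  weekIv <- function(w) {
    start <- 7L * w[1] + 1L
    end <- if (w[2] == 51L) 1L else 7L * (w[2] + 1L) + 1L
    c(start, end)
  }
  seasonWindows(niche@species, weekIv(niche@migrationWeeks$spring),
                weekIv(niche@migrationWeeks$fall), source = "prior")
}

#' Construct survey effort
#'
#' @param stationCells data.frame of 0-based `row`, `col` station cells.
#' @param stationSd Gaussian kernel width around stations, degrees.
#' @param nBanding banding events per species and season.
#' @return A [SurveyEffort-class].
#' @export
surveyEffort <- function(stationCells, stationSd = 1, nBanding = 400) {
  new("SurveyEffort", stationCells = stationCells, stationSd = stationSd,
      nBanding = as.integer(nBanding))
}

#' Default survey effort: stations scattered over the grid
#'
#' @param grid a [GridSpec-class].
#' @param nStations number of stations.
#' @param stationSd kernel width, degrees.
#' @param nBanding banding events per species and season.
#' @param seed integer seed for station placement.
#' @return A [SurveyEffort-class].
#' @export
defaultEffort <- function(grid, nStations = 15, stationSd = 1,
                          nBanding = 400, seed = 1) {
  set.seed(seed)
  keys <- sample.int(grid@nRows * grid@nCols, nStations) - 1L
  surveyEffort(data.frame(row = keys %/% grid@nCols, col = keys %% grid@nCols),
               stationSd = stationSd, nBanding = nBanding)
}

# ---------------------------------------------------------------------------
# landscape generation
# ---------------------------------------------------------------------------

# dense row-normalised Gaussian smoothing matrix (grids are desk-scale)
smoothingMatrix <- function(n, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  W <- outer(seq_len(n), seq_len(n),
             function(i, j) ifelse(abs(i - j) <= r, stats::dnorm(j - i, sd = sigma), 0))
  W / rowSums(W)
}

gaussianSmooth <- function(m, sigma) {
  smoothingMatrix(nrow(m), sigma) %*% m %*% t(smoothingMatrix(ncol(m), sigma))
}

#' Default generator parameters
#'
#' Parameters of the synthetic covariate stack; see the methods vignette for
#' the rationale behind each default.
#'
#' @return Named list of parameters.
#' @export
landscapeParams <- function() {
  list(
    elevRelief = 200,     # regional west-high gradient, m
    elevNoiseSd = 40,     # hill/valley random-field amplitude, m
    elevSigma = 3,        # random-field correlation length, cells
    elevBase = 5,         # minimum elevation above datum, m
    tempSouth = 22,       # mean temperature at the southern edge, C
    tempLatGrad = 0.8,    # C per degree latitude
    tempLapse = 6.5,      # C per km elevation
    tempNoiseSd = 0.4,
    precipWest = 0.35,    # m/yr at the western edge
    precipEast = 1.3,     # m/yr at the eastern edge
    precipNoiseSd = 0.1,
    et0 = 0.55,           # reference evapotranspiration, m/yr
    rechargeMin = 0.02,   # recharge floor, m/yr (runoff/capillary stand-in)
    riverQuantile = 0.08, # fraction of lowest-elevation cells held at dwt 0
    T0 = 6e7,             # transmissivity scale, m^2/yr
    f = 3,                # transmissivity e-folding depth, m
    cellLength = 18500,   # cell edge, m (~10-minute cell)
    pwSlope = 2,          # logistic slope of percent wetland vs (1 - dwt)
    pwCorrTarget = -0.36, # calibrated dwt / percent-wetland correlation
    solverTol = 0.001, solverMaxIter = 50000, solverRelax = 0.5
  )
}

#' The default synthetic study grid
#'
#' 60 x 100 cells of 1/6 degree spanning 30-40 N, 105-88.3 W.
#'
#' @return A [GridSpec-class].
#' @export
defaultStudyGrid <- function() gridSpec(30, -105, 1/6, nRows = 60, nCols = 100)

# matrix of cell-centre latitudes (rows x cols)
latitudeMatrix <- function(grid) {
  lat <- grid@latOrigin + (seq_len(grid@nRows) - 0.5) * grid@cellSize
  matrix(lat, grid@nRows, grid@nCols)
}

#' Generate a synthetic covariate stack
#'
#' Builds co-registered `temperature`, `precipitation`, `elevation`, `dwt`
#' and `percent_wetland` layers. Elevation is a smoothed Gaussian random
#' field over a west-high regional gradient; temperature follows a
#' latitudinal gradient minus an elevation lapse; precipitation a
#' longitudinal gradient; the water table is the solved equilibrium of
#' recharge (precipitation minus reference evapotranspiration, floored at a
#' small positive value) against lateral drainage towards low-elevation
#' fixed-head river cells; and percent wetland is a logistic transform of
#' the water table around the 1 m wetland threshold with noise calibrated so
#' that `cor(dwt, percent_wetland)` lands at the target (default -0.36).
#' Deterministic given `seed`.
#'
#' @param seed integer seed.
#' @param grid a [GridSpec-class]; at least 4 x 4.
#' @param params list as from [landscapeParams()]; partial overrides allowed.
#' @return A [CovariateStack-class].
#' @export
generateLandscape <- function(seed, grid = defaultStudyGrid(),
                              params = landscapeParams()) {
  p <- utils::modifyList(landscapeParams(), params)
  stopIfNot(grid@nRows >= 4 && grid@nCols >= 4,
            "grid must be at least 4 x 4 cells")
  set.seed(seed)
  nr <- grid@nRows; nc <- grid@nCols
  colFrac <- matrix(rep((seq_len(nc) - 0.5) / nc, each = nr), nr, nc)
  lat <- latitudeMatrix(grid)

  noise <- gaussianSmooth(matrix(stats::rnorm(nr * nc), nr, nc), p$elevSigma)
  noise <- noise / stats::sd(noise) * p$elevNoiseSd
  elev <- p$elevRelief * (1 - colFrac) + noise
  elev <- elev - min(elev) + p$elevBase

  temp <- p$tempSouth - p$tempLatGrad * (lat - grid@latOrigin) -
    p$tempLapse * elev / 1000 + stats::rnorm(nr * nc, sd = p$tempNoiseSd)

  pnoise <- gaussianSmooth(matrix(stats::rnorm(nr * nc), nr, nc), p$elevSigma)
  pnoise <- pnoise / stats::sd(pnoise) * p$precipNoiseSd
  precip <- p$precipWest + (p$precipEast - p$precipWest) * colFrac + pnoise
  precip <- pmax(precip, 0.05)

  recharge <- pmax(precip - p$et0, p$rechargeMin)
  rivers <- elev <= stats::quantile(elev, p$riverQuantile)

  land <- landscape(grid, elev, recharge, boundaryMask = rivers,
                    boundaryDepth = 0, T0 = p$T0, f = p$f,
                    cellLength = p$cellLength)
  state <- solveEquilibrium(land, tol = p$solverTol,
                            maxIter = p$solverMaxIter, relax = p$solverRelax)
  dwt <- state@dwt

  pw0 <- stats::plogis(-p$pwSlope * (dwt - 1))
  r0 <- stats::cor(as.vector(pw0), as.vector(dwt))
  rt <- p$pwCorrTarget
  noiseSd <- if (abs(r0) > abs(rt))
    stats::sd(pw0) * sqrt((r0 / rt)^2 - 1) else 0
  pw <- pmin(pmax(pw0 + stats::rnorm(nr * nc, sd = noiseSd), 0), 1)

  mk <- function(v, nm) rasterGrid(matrix(v, nr, nc), grid, nm)
  new("CovariateStack", grid = grid,
      layers = list(
        temperature = mk(temp, "temperature"),
        precipitation = mk(precip, "precipitation"),
        elevation = mk(elev, "elevation"),
        dwt = mk(dwt, "dwt"),
        percent_wetland = mk(pw, "percent_wetland")),
      landscape = land, state = state, params = p, seed = as.integer(seed))
}

#' Access covariate layers and values
#'
#' `covLayer` returns one layer; `covMatrix` returns a cells-by-covariates
#' matrix of values at the given 0-based cells (all grid cells when
#' `cells = NULL`).
#'
#' @param stack a [CovariateStack-class].
#' @param name layer name.
#' @return `covLayer`: a [RasterGrid-class].
#' @export
covLayer <- function(stack, name) {
  stopIfNot(name %in% names(stack@layers), "unknown covariate layer: ", name)
  stack@layers[[name]]
}

#' @rdname covLayer
#' @param names layer names (default: all).
#' @param cells data.frame with 0-based `row`, `col`, or `NULL` for all cells.
#' @export
covMatrix <- function(stack, names = NULL, cells = NULL) {
  names <- names %||% base::names(stack@layers)
  if (is.null(cells)) {
    g <- stack@grid
    cells <- data.frame(row = rep(seq_len(g@nRows) - 1L, times = g@nCols),
                        col = rep(seq_len(g@nCols) - 1L, each = g@nRows))
  }
  out <- vapply(names, function(nm) valuesAtCells(covLayer(stack, nm), cells),
                numeric(nrow(cells)))
  out <- matrix(out, nrow = nrow(cells), dimnames = list(NULL, names))
  out
}

# all-cell data.frame with row/col/lat for a grid
allCells <- function(grid) {
  cells <- data.frame(row = rep(seq_len(grid@nRows) - 1L, times = grid@nCols),
                      col = rep(seq_len(grid@nCols) - 1L, each = grid@nRows))
  ctr <- cellCenter(cells$row, cells$col, grid)
  cbind(cells, ctr)
}

# ---------------------------------------------------------------------------
# presence and record simulation
# ---------------------------------------------------------------------------

# per-cell suitability of a niche in a season (vector over allCells order)
nicheSuitability <- function(niche, stack, season) {
  cells <- allCells(stack@grid)
  dwt <- valuesAtCells(covLayer(stack, "dwt"), cells)
  temp <- valuesAtCells(covLayer(stack, "temperature"), cells)
  ctrLat <- cells$lat
  s <- exp(-dwt / niche@dwtScale) *
    exp(-(temp - niche@tempOpt)^2 / (2 * niche@tempSd^2)) *
    exp(-(ctrLat - niche@seasonalCenter[[season]])^2 / (2 * niche@rangeSd^2))
  s[is.na(s)] <- 0
  list(cells = cells, s = s)
}

#' Sample presence cells from a niche
#'
#' Cells are drawn (with replacement) with probability proportional to the
#' ground-truth suitability
#' `exp(-dwt/dwtScale) * exp(-(T-tempOpt)^2/(2 tempSd^2)) *
#' exp(-(lat-center)^2/(2 rangeSd^2))`; the sampled suitability is retained
#' for evaluation.
#'
#' @param niche a [SpeciesNiche-class].
#' @param stack a [CovariateStack-class].
#' @param season one of `spring`, `summer`, `fall`, `winter`.
#' @param n number of presence draws (>= 1).
#' @param seed integer seed.
#' @return data.frame with `row`, `col`, `lat`, `lon`, `suitability`.
#' @export
simulatePresences <- function(niche, stack, season, n, seed) {
  stopIfNot(n >= 1, "n must be >= 1")
  su <- nicheSuitability(niche, stack, season)
  if (all(su$s == 0)) stop("suitability is zero everywhere", call. = FALSE)
  set.seed(seed)
  idx <- sample.int(length(su$s), n, replace = TRUE, prob = su$s)
  out <- su$cells[idx, , drop = FALSE]
  out$suitability <- su$s[idx]
  rownames(out) <- NULL
  out
}

# Gaussian station kernel over all cells (degrees distance to nearest effort)
stationKernel <- function(effort, grid) {
  cells <- allCells(grid)
  st <- cellCenter(effort@stationCells$row, effort@stationCells$col, grid)
  k <- numeric(nrow(cells))
  for (i in seq_len(nrow(st))) {
    d2 <- (cells$lat - st$lat[i])^2 + (cells$lon - st$lon[i])^2
    k <- k + exp(-d2 / (2 * effort@stationSd^2))
  }
  k
}

# sample calendar dates uniformly over a circular doy window across years
sampleSeasonDates <- function(n, window, years) {
  doys <- if (window[1] < window[2]) seq(window[1], window[2] - 1)
          else c(seq(window[1], YEAR_DAYS), seq_len(window[2] - 1))
  doy <- sample(doys, n, replace = TRUE)
  yr <- sample(years, n, replace = TRUE)
  as.Date(doy - 1, origin = as.Date(sprintf("%d-01-01", yr)))
}

# elapsed-day distribution of terminal recoveries: geometric with mean ~20
# days, truncated at 60
sampleElapsedDays <- function(n, meanDays = 20, maxDays = 60) {
  pr <- stats::dgeom(0:(maxDays - 1), prob = 1 / meanDays)
  sample.int(maxDays, n, replace = TRUE, prob = pr)
}

#' Simulate multi-species banding/recovery records
#'
#' For each species and season, banding events are drawn from the species'
#' presence distribution re-weighted by a Gaussian kernel around the survey
#' stations (the shared effort bias). Every banded bird receives one
#' terminal recovery: elapsed days are geometric (mean 20, truncated at 60)
#' and the bird is displaced by `elapsed * velocity` along the seasonal
#' movement direction (north in spring, south in fall, a random bearing
#' otherwise), where the velocity is the niche's migration velocity when the
#' movement window's midpoint week falls in the true migration weeks and the
#' base velocity otherwise. Dates are spread uniformly over the species'
#' season windows across `years`. Deterministic given `seed`.
#'
#' @param niches list of [SpeciesNiche-class] (>= 2 species, as required
#'   downstream by target-group backgrounds).
#' @param effort a [SurveyEffort-class].
#' @param stack a [CovariateStack-class].
#' @param seed integer seed.
#' @param years calendar years to spread records over.
#' @return record data.frame (see [readRecords()]) with derived cells.
#' @export
simulateBandingRecords <- function(niches, effort, stack, seed,
                                   years = 1990:1999) {
  stopIfNot(length(niches) >= 2,
            "at least two species are required (target-group backgrounds)")
  set.seed(seed)
  g <- stack@grid
  kern <- stationKernel(effort, g)
  eps <- g@cellSize / 1000  # clamp margin inside the grid bounding box
  latMax <- gridLatMax(g) - eps; lonMax <- gridLonMax(g) - eps

  out <- list()
  serial <- 0L
  for (niche in niches) {
    windows <- trueSeasonWindows(niche)
    mig <- niche@migrationWeeks
    for (season in c("spring", "summer", "fall", "winter")) {
      n <- effort@nBanding
      if (n == 0L) next
      su <- nicheSuitability(niche, stack, season)
      w <- su$s * kern
      if (all(w == 0)) w <- su$s
      idx <- sample.int(length(w), n, replace = TRUE, prob = w)
      cells <- su$cells[idx, , drop = FALSE]
      # jitter banding locations uniformly within the 10-minute cell
      bLat <- cells$lat + stats::runif(n, -0.5, 0.5) * g@cellSize
      bLon <- cells$lon + stats::runif(n, -0.5, 0.5) * g@cellSize
      bDate <- sampleSeasonDates(n, slot(windows, season), years)

      elapsed <- sampleElapsedDays(n)
      midWeek <- weekOfDoy((dayOfYear(bDate) + elapsed %/% 2L - 1L) %% YEAR_DAYS + 1L)
      inSpring <- midWeek >= mig$spring[1] & midWeek <= mig$spring[2]
      inFall <- midWeek >= mig$fall[1] & midWeek <= mig$fall[2]
      vel <- ifelse(inSpring | inFall, niche@migrationVelocity, niche@baseVelocity)
      bearing <- ifelse(inSpring, 0, ifelse(inFall, 180, stats::runif(n, 0, 360)))
      dest <- geosphere::destPoint(cbind(bLon, bLat), bearing,
                                   elapsed * vel * 1000, r = EARTH_RADIUS_KM * 1000)
      rLat <- pmin(pmax(dest[, 2], g@latOrigin + eps), latMax)
      rLon <- pmin(pmax(dest[, 1], g@lonOrigin + eps), lonMax)

      ids <- sprintf("%s-%06d", niche@species, serial + seq_len(n))
      serial <- serial + n
      out[[length(out) + 1L]] <- data.frame(
        band_id = rep(ids, 2), species = niche@species,
        event = rep(c("banding", "recovery"), each = n),
        date = c(bDate, bDate + elapsed),
        lat = c(bLat, rLat), lon = c(bLon, rLon), stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, out)
  rownames(records) <- NULL
  binRecords(records, g)
}
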