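#' @import methods
NULL

# ---------------------------------------------------------------------------
# GridSpec: the regular lat/lon analysis grid. Banding records are located at
# 10-minute (1/6 degree) resolution, so all analyses run on cells of this
# grid. Cells are half-open intervals [edge, edge + cellSize) on both axes and
# indices are 0-based with row 0 at the southern edge.
# ---------------------------------------------------------------------------

#' Regular latitude/longitude analysis grid
#'
#' Defines the rectangular grid onto which all records and covariates are
#' binned. The default cell size of 1/6 degree matches the 10-minute
#' resolution of banding-laboratory encounter locations. Cells are half-open
#' (`[edge, edge + cellSize)`) in both axes; indices are 0-based with row 0 at
#' the southern edge and column 0 at the western edge.
#'
#' @slot latOrigin southern edge, decimal degrees.
#' @slot lonOrigin western edge, decimal degrees.
#' @slot cellSize cell width/height in degrees (default 1/6).
#' @slot nRows,nCols grid extent in cells.
#'
#' @seealso [gridSpec()], [binToGrid()], [cellCenter()]
#' @export
setClass("GridSpec",
  representation(
    latOrigin = "numeric",
    lonOrigin = "numeric",
    cellSize  = "numeric",
    nRows     = "integer",
    nCols     = "integer"
  )
)

setValidity("GridSpec", function(object) {
  msg <- character()
  if (length(object@cellSize) != 1 || object@cellSize <= 0)
    msg <- c(msg, "cellSize must be a single positive number")
  if (object@nRows < 1L || object@nCols < 1L)
    msg <- c(msg, "nRows and nCols must be >= 1")
  if (object@latOrigin < -90 || object@latOrigin + object@nRows * object@cellSize > 90 + 1e-9)
    msg <- c(msg, "latitude extent must lie within [-90, 90]")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# RasterGrid: one environmental covariate on a GridSpec. Missing data are NA.
# ---------------------------------------------------------------------------

#' Gridded environmental covariate layer
#'
#' A single 2-D covariate on a [GridSpec-class] grid. `values` is an
#' `nRows x nCols` matrix whose first row is the *southern* row of the grid;
#' missing data are `NA`.
#'
#' @slot grid the [GridSpec-class] the layer is aligned to.
#' @slot values numeric matrix, `nRows x nCols`, row 1 = southern row.
#' @slot name layer name (e.g. `"dwt"`).
#'
#' @seealso [rasterGrid()], [readAsciiGrid()], [writeAsciiGrid()]
#' @export
setClass("RasterGrid",
  representation(
    grid   = "GridSpec",
    values = "matrix",
    name   = "character"
  )
)

setValidity("RasterGrid", function(object) {
  if (nrow(object@values) != object@grid@nRows ||
      ncol(object@values) != object@grid@nCols)
    return("values matrix does not match the grid dimensions")
  TRUE
})

# ---------------------------------------------------------------------------
# SeasonWindows: day-of-year intervals partitioning the circular year.
# ---------------------------------------------------------------------------

#' Species-specific annual-cycle windows
#'
#' Day-of-year intervals for spring migration, summer/breeding, fall migration
#' and winter/non-breeding. Intervals are half-open circular intervals
#' `[start, end)` on a 365-day year and the four of them always partition the
#' circular year, in the order spring, summer, fall, winter.
#'
#' @slot species species code.
#' @slot spring,summer,fall,winter numeric length-2 `(start, endExclusive)`
#'   day-of-year intervals.
#' @slot source `"detected"` when both migration windows come from the weekly
#'   velocity series, `"prior"` when both fall back to natural-history priors,
#'   `"mixed"` otherwise.
#'
#' @seealso [seasonWindows()], [detectMigrationWindows()], [assignSeason()]
#' @export
setClass("SeasonWindows",
  representation(
    species = "character",
    spring  = "numeric",
    summer  = "numeric",
    fall    = "numeric",
    winter  = "numeric",
    source  = "character"
  )
)

setValidity("SeasonWindows", function(object) {
  msg <- character()
  iv <- list(spring = object@spring, summer = object@summer,
             fall = object@fall, winter = object@winter)
  for (nm in names(iv)) {
    v <- iv[[nm]]
    if (length(v) != 2 || anyNA(v) || any(v < 1) || any(v > YEAR_DAYS))
      msg <- c(msg, sprintf("%s must be two days-of-year in 1..%d", nm, YEAR_DAYS))
  }
  if (!length(msg)) {
    # chained partition: each season starts where the previous one ends
    if (object@summer[1] != object@spring[2] ||
        object@fall[1]   != object@summer[2] ||
        object@winter[1] != object@fall[2] ||
        object@spring[1] != object@winter[2])
      msg <- c(msg, "season intervals must chain spring->summer->fall->winter around the year")
    else {
      tot <- sum(vapply(iv, function(v) circularIntervalLength(v[1], v[2]), 0))
      if (tot != YEAR_DAYS)
        msg <- c(msg, "season intervals must partition the 365-day circular year")
    }
  }
  if (!object@source %in% c("detected", "prior", "mixed"))
    msg <- c(msg, "source must be one of 'detected', 'prior', 'mixed'")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# WeeklyVelocitySeries: 52 weekly mean movement rates from recovery pairs.
# ---------------------------------------------------------------------------

#' Weekly mean movement-rate series
#'
#' Mean daily distance travelled (km/day) of band-recovery pairs, averaged by
#' the 0-based week of the pair's midpoint date. Weeks with no observations
#' are `NA` (missing), never zero.
#'
#' @slot species species code.
#' @slot values numeric length 52; `NA` where `counts == 0`.
#' @slot counts integer length 52; observations per week.
#'
#' @seealso [weeklyMeanSeries()], [detectMigrationWindows()]
#' @export
setClass("WeeklyVelocitySeries",
  representation(
    species = "character",
    values  = "numeric",
    counts  = "integer"
  )
)

setValidity("WeeklyVelocitySeries", function(object) {
  msg <- character()
  if (length(object@values) != 52L || length(object@counts) != 52L)
    msg <- c(msg, "values and counts must have length 52")
  else if (any(is.na(object@values) != (object@counts == 0L)))
    msg <- c(msg, "weeks with zero count must be NA and vice versa")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Landscape + WaterTableState: the equilibrium water-table solver's input and
# output.
# ---------------------------------------------------------------------------

#' Gridded landscape for the water-table solver
#'
#' Inputs to [solveEquilibrium()]: surface elevation, climate recharge
#' (precipitation minus evapotranspiration) and lateral-flow parameters.
#' Transmissivity decays exponentially with water-table depth,
#' `T(d) = T0 * exp(-d / f)`.
#'
#' @slot grid the [GridSpec-class] of the landscape.
#' @slot elevation metres above datum, `nRows x nCols` (row 1 = south).
#' @slot recharge metres/year per cell; may be negative.
#' @slot boundaryMask logical matrix; `TRUE` marks fixed-head cells (rivers,
#'   ocean) whose water-table depth is held at `boundaryDepth`.
#' @slot boundaryDepth metres below surface held at fixed-head cells
#'   (matrix, read only where `boundaryMask` is `TRUE`).
#' @slot T0 transmissivity scale, m^2/year.
#' @slot f e-folding depth of transmissivity decay, metres.
#' @slot cellLength cell edge length, metres.
#'
#' @seealso [landscape()], [solveEquilibrium()], [lateralFlux()]
#' @export
setClass("Landscape",
  representation(
    grid          = "GridSpec",
    elevation     = "matrix",
    recharge      = "matrix",
    boundaryMask  = "matrix",
    boundaryDepth = "matrix",
    T0            = "numeric",
    f             = "numeric",
    cellLength    = "numeric"
  )
)

setValidity("Landscape", function(object) {
  msg <- character()
  dims <- c(object@grid@nRows, object@grid@nCols)
  for (nm in c("elevation", "recharge", "boundaryMask", "boundaryDepth")) {
    m <- slot(object, nm)
    if (!identical(dim(m), as.integer(dims)))
      msg <- c(msg, sprintf("%s must be an nRows x nCols matrix", nm))
  }
  if (object@T0 <= 0) msg <- c(msg, "T0 must be positive")
  if (object@f <= 0) msg <- c(msg, "f must be positive")
  if (object@cellLength <= 0) msg <- c(msg, "cellLength must be positive")
  if (any(object@boundaryDepth[object@boundaryMask] < 0))
    msg <- c(msg, "boundaryDepth must be >= 0 at fixed-head cells")
  if (length(msg)) msg else TRUE
})

#' Equilibrium water-table state
#'
#' Output of [solveEquilibrium()]: depth to water table per cell and solver
#' diagnostics. `dwt >= 0` everywhere (ponded water is clipped to the
#' surface); fixed-head cells hold their prescribed depth exactly.
#'
#' @slot dwt metres below surface, `nRows x nCols`.
#' @slot head hydraulic head = elevation - dwt, metres.
#' @slot iterations iterations used.
#' @slot maxDelta largest per-cell depth change on the final iteration, m.
#'
#' @seealso [solveEquilibrium()], [massBalanceResidual()], [wetlandMask()]
#' @export
setClass("WaterTableState",
  representation(
    dwt        = "matrix",
    head       = "matrix",
    iterations = "integer",
    maxDelta   = "numeric"
  )
)

setValidity("WaterTableState", function(object) {
  if (any(object@dwt < 0, na.rm = TRUE)) return("dwt must be >= 0 everywhere")
  TRUE
})

# ---------------------------------------------------------------------------
# CovariateStack: the generated (or assembled) set of co-registered layers.
# ---------------------------------------------------------------------------

#' Co-registered covariate stack
#'
#' A named set of [RasterGrid-class] layers on one grid, as produced by
#' [generateLandscape()]: `temperature`, `precipitation`, `elevation`, `dwt`
#' and `percent_wetland`, plus the [Landscape-class] and solver state that
#' produced the water-table layer.
#'
#' @slot grid shared [GridSpec-class].
#' @slot layers named list of [RasterGrid-class] objects.
#' @slot landscape the [Landscape-class] used for the water-table solve.
#' @slot state the converged [WaterTableState-class].
#' @slot params generator parameters actually used.
#' @slot seed integer seed the stack was generated from.
#'
#' @seealso [generateLandscape()], [covLayer()], [covMatrix()]
#' @export
setClass("CovariateStack",
  representation(
    grid      = "GridSpec",
    layers    = "list",
    landscape = "Landscape",
    state     = "WaterTableState",
    params    = "list",
    seed      = "integer"
  )
)

setValidity("CovariateStack", function(object) {
  if (!length(object@layers) || is.null(names(object@layers)) ||
      any(!nzchar(names(object@layers))))
    return("layers must be a non-empty named list")
  if (!all(vapply(object@layers, is, TRUE, class2 = "RasterGrid")))
    return("all layers must be RasterGrid objects")
  TRUE
})

# ---------------------------------------------------------------------------
# SpeciesNiche + SurveyEffort: ground truth of the synthetic generator.
# ---------------------------------------------------------------------------

#' Ground-truth niche of a synthetic species
#'
#' Defines the suitability surface presences are sampled from:
#' `s = exp(-dwt/dwtScale) * exp(-(T-tempOpt)^2/(2 tempSd^2)) *
#' exp(-(lat-center)^2/(2 rangeSd^2))`. Small `dwtScale` means strong wetland
#' affinity. Migration weeks and velocities define the movement model used
#' when displacing recoveries.
#'
#' @slot species species code.
#' @slot dwtScale metres; e-folding depth of the water-table affinity.
#' @slot tempOpt,tempSd thermal optimum and breadth, degrees C.
#' @slot seasonalCenter named numeric, range-centre latitude per season
#'   (`spring`, `summer`, `fall`, `winter`).
#' @slot rangeSd latitudinal range breadth, degrees.
#' @slot migrationWeeks list with `spring` and `fall`, each `c(firstWeek,
#'   lastWeek)` 0-based inclusive true migration weeks.
#' @slot baseVelocity,migrationVelocity km/day outside/inside migration.
#'
#' @seealso [speciesNiche()], [defaultNiches()], [simulatePresences()]
#' @export
setClass("SpeciesNiche",
  representation(
    species           = "character",
    dwtScale          = "numeric",
    tempOpt           = "numeric",
    tempSd            = "numeric",
    seasonalCenter    = "numeric",
    rangeSd           = "numeric",
    migrationWeeks    = "list",
    baseVelocity      = "numeric",
    migrationVelocity = "numeric"
  )
)

setValidity("SpeciesNiche", function(object) {
  msg <- character()
  if (object@dwtScale <= 0) msg <- c(msg, "dwtScale must be positive")
  if (object@tempSd <= 0) msg <- c(msg, "tempSd must be positive")
  if (object@rangeSd <= 0) msg <- c(msg, "rangeSd must be positive")
  if (!all(c("spring", "summer", "fall", "winter") %in% names(object@seasonalCenter)))
    msg <- c(msg, "seasonalCenter must name all four seasons")
  if (!all(c("spring", "fall") %in% names(object@migrationWeeks)))
    msg <- c(msg, "migrationWeeks must contain spring and fall")
  if (object@migrationVelocity <= object@baseVelocity)
    msg <- c(msg, "migrationVelocity must exceed baseVelocity")
  if (length(msg)) msg else TRUE
})

#' Survey (banding-station) effort model
#'
#' Banding effort is concentrated at survey stations: banding locations are
#' drawn from the species' suitability surface re-weighted by a Gaussian
#' kernel around the stations. This is the sampling bias that target-group
#' backgrounds are designed to absorb.
#'
#' @slot stationCells data.frame with 0-based `row`, `col` of station cells.
#' @slot stationSd kernel width, degrees.
#' @slot nBanding banding events per species and season.
#'
#' @seealso [surveyEffort()], [defaultEffort()], [simulateBandingRecords()]
#' @export
setClass("SurveyEffort",
  representation(
    stationCells = "data.frame",
    stationSd    = "numeric",
    nBanding     = "integer"
  )
)

setValidity("SurveyEffort", function(object) {
  msg <- character()
  if (nrow(object@stationCells) < 1) msg <- c(msg, "at least one station required")
  if (!all(c("row", "col") %in% names(object@stationCells)))
    msg <- c(msg, "stationCells must have columns 'row' and 'col'")
  if (object@stationSd <= 0) msg <- c(msg, "stationSd must be positive")
  if (object@nBanding < 0L) msg <- c(msg, "nBanding must be >= 0")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# MaxentModel: fitted maximum-entropy distribution model.
# ---------------------------------------------------------------------------

#' Fitted maximum-entropy distribution model
#'
#' Feature weights of the Gibbs distribution
#' `q(x) = exp(lambda . f(x)) / Z` over the fitting cells, with the entropy
#' `H` of `q` retained so predictions can be expressed on the logistic scale
#' `p = e^H q / (1 + e^H q)` (default prevalence 0.5).
#'
#' @slot featureSet feature expansion definition (see [buildFeatures()]).
#' @slot lambda fitted feature weights.
#' @slot beta per-feature L1 penalties used in the fit.
#' @slot logZ log normaliser over the fitting cells.
#' @slot entropy entropy `H` of the fitted distribution.
#' @slot diagnostics list: iterations, objective trace, converged flag,
#'   number of presences/fitting cells.
#'
#' @seealso [fitMaxent()], [predict()][predict,MaxentModel-method],
#'   [replicateFit()]
#' @export
setClass("MaxentModel",
  representation(
    featureSet  = "list",
    lambda      = "numeric",
    beta        = "numeric",
    logZ        = "numeric",
    entropy     = "numeric",
    diagnostics = "list"
  )
)

setValidity("MaxentModel", function(object) {
  msg <- character()
  if (length(object@lambda) != length(object@beta))
    msg <- c(msg, "lambda and beta must have the same length")
  if (any(object@beta < 0)) msg <- c(msg, "beta must be non-negative")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# ResponseCurve: binned covariate-response trend with spline smoother.
# ---------------------------------------------------------------------------

#' Covariate response curve
#'
#' Random cells sampled from a prediction surface, binned by water-table
#' depth, with per-bin mean predicted probability and a cubic smoothing
#' spline through the bin means.
#'
#' @slot samples data.frame with `dwt` and `probability` for each sampled cell.
#' @slot binEdges,binCenters,binMeans equal-width bins over the sampled dwt
#'   range; `binMeans` is `NA` for empty bins.
#' @slot splineX,splineY smoothing-spline evaluations on a dense dwt grid.
#'
#' @seealso [responseCurve()], [halfMaximumDwt()]
#' @export
setClass("ResponseCurve",
  representation(
    samples    = "data.frame",
    binEdges   = "numeric",
    binCenters = "numeric",
    binMeans   = "numeric",
    splineX    = "numeric",
    splineY    = "numeric"
  )
)

# ---------------------------------------------------------------------------
# show methods
# ---------------------------------------------------------------------------

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %d x %d cells of %.6g deg, origin (%.4g, %.4g)\n",
              object@nRows, object@nCols, object@cellSize,
              object@latOrigin, object@lonOrigin))
})

setMethod("show", "RasterGrid", function(object) {
  v <- object@values
  cat(sprintf("RasterGrid '%s': %d x %d cells, range [%.4g, %.4g], %d NA\n",
              ifelse(nzchar(object@name), object@name, "<unnamed>"),
              nrow(v), ncol(v), suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
})

setMethod("show", "SeasonWindows", function(object) {
  cat(sprintf("SeasonWindows for %s (source: %s)\n", object@species, object@source))
  for (nm in c("spring", "summer", "fall", "winter"))
    cat(sprintf("  %-6s doy [%3d, %3d)\n", nm, slot(object, nm)[1], slot(object, nm)[2]))
})

setMethod("show", "WeeklyVelocitySeries", function(object) {
  cat(sprintf("WeeklyVelocitySeries for %s: %d informative weeks, mean %.2f km/day\n",
              object@species, sum(object@counts > 0),
              mean(object@values, na.rm = TRUE)))
})

setMethod("show", "Landscape", function(object) {
  cat(sprintf(
    "Landscape: %d x %d cells, T0 = %.3g m2/yr, f = %.3g m, %d fixed-head cells\n",
    object@grid@nRows, object@grid@nCols, object@T0, object@f,
    sum(object@boundaryMask)))
})

setMethod("show", "WaterTableState", function(object) {
  cat(sprintf(
    "WaterTableState: dwt range [%.3g, %.3g] m, %d iterations, final delta %.3g m\n",
    min(object@dwt), max(object@dwt), object@iterations, object@maxDelta))
})

setMethod("show", "CovariateStack", function(object) {
  cat(sprintf("CovariateStack (seed %d): layers %s on %d x %d grid\n",
              object@seed, paste(names(object@layers), collapse = ", "),
              object@grid@nRows, object@grid@nCols))
})

setMethod("show", "SpeciesNiche", function(object) {
  cat(sprintf(
    "SpeciesNiche %s: dwtScale %.2g m, tempOpt %.3g C, migration weeks S %d-%d / F %d-%d\n",
    object@species, object@dwtScale, object@tempOpt,
    object@migrationWeeks$spring[1], object@migrationWeeks$spring[2],
    object@migrationWeeks$fall[1], object@migrationWeeks$fall[2]))
})

setMethod("show", "SurveyEffort", function(object) {
  cat(sprintf("SurveyEffort: %d stations, kernel sd %.2g deg, %d bandings/species/season\n",
              nrow(object@stationCells), object@stationSd, object@nBanding))
})

setMethod("show", "MaxentModel", function(object) {
  d <- object@diagnostics
  cat(sprintf(
    "MaxentModel: %d features (%d active), logZ %.4f, H %.4f, %d iterations%s\n",
    length(object@lambda), sum(object@lambda != 0), object@logZ, object@entropy,
    d$iterations %||% NA_integer_,
    if (isTRUE(d$converged)) "" else " (not converged)"))
})

setMethod("show", "ResponseCurve", function(object) {
  cat(sprintf("ResponseCurve: %d samples, %d bins over dwt [%.3g, %.3g] m\n",
              nrow(object@samples), length(object@binCenters),
              min(object@binEdges), max(object@binEdges)))
})
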