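# banding_records module, part 1: the analysis grid and great-circle geometry.

# IUGG mean Earth radius; all great-circle distances use this sphere.
EARTH_RADIUS_KM <- 6371.0088

#' Construct a GridSpec
#'
#' @param latOrigin,lonOrigin southern and western edges, decimal degrees.
#' @param cellSize cell size in degrees; the default `1/6` is the 10-minute
#'   resolution of banding-record locations.
#' @param nRows,nCols grid extent in cells.
#' @return A [GridSpec-class] object.
#' @examples
#' g <- gridSpec(24, -125, 1/6, 156, 354)
#' binToGrid(30.05, -97.99, g)
#' @export
gridSpec <- function(latOrigin, lonOrigin, cellSize = 1/6, nRows, nCols) {
  new("GridSpec", latOrigin = as.numeric(latOrigin),
      lonOrigin = as.numeric(lonOrigin), cellSize = as.numeric(cellSize),
      nRows = as.integer(nRows), nCols = as.integer(nCols))
}

#' The contiguous-US 10-minute analysis grid
#'
#' A 1/6-degree grid covering 24-50 N, 125-66 W, aligned to integer degrees.
#' This is the default grid records are binned to.
#'
#' @return A [GridSpec-class].
#' @export
conusGrid <- function() {
  gridSpec(24, -125, 1/6, nRows = 26 * 6, nCols = 59 * 6)
}

#' Number of rows/columns of a grid
#' @param grid a [GridSpec-class].
#' @return Integer count.
#' @export
nGridRows <- function(grid) grid@nRows

#' @rdname nGridRows
#' @export
nGridCols <- function(grid) grid@nCols

gridLatMax <- function(grid) grid@latOrigin + grid@nRows * grid@cellSize
gridLonMax <- function(grid) grid@lonOrigin + grid@nCols * grid@cellSize

#' Bin points to grid cells
#'
#' Maps coordinates to the half-open cell containing them:
#' `row = floor((lat - latOrigin) / cellSize)` and analogously for columns.
#' A point exactly on an interior cell edge belongs to the higher-index cell.
#'
#' @param lat,lon coordinates in decimal degrees (vectorised).
#' @param grid a [GridSpec-class].
#' @return data.frame with 0-based integer columns `row` and `col`.
#' @export
binToGrid <- function(lat, lon, grid) {
  stopIfNot(length(lat) == length(lon), "lat and lon must have equal length")
  badLat <- which(lat < grid@latOrigin | lat >= gridLatMax(grid))
  if (length(badLat))
    stop(sprintf("latitude %.6g outside grid range [%g, %g)",
                 lat[badLat[1]], grid@latOrigin, gridLatMax(grid)), call. = FALSE)
  badLon <- which(lon < grid@lonOrigin | lon >= gridLonMax(grid))
  if (length(badLon))
    stop(sprintf("longitude %.6g outside grid range [%g, %g)",
                 lon[badLon[1]], grid@lonOrigin, gridLonMax(grid)), call. = FALSE)
  data.frame(
    row = pmin(as.integer(floor((lat - grid@latOrigin) / grid@cellSize)), grid@nRows - 1L),
    col = pmin(as.integer(floor((lon - grid@lonOrigin) / grid@cellSize)), grid@nCols - 1L)
  )
}

#' Cell centre coordinates
#'
#' Since records are binned, all distance computations use cell centres:
#' `centre = origin + (index + 0.5) * cellSize` per axis.
#'
#' @param row,col 0-based cell indices (vectorised).
#' @param grid a [GridSpec-class].
#' @return data.frame with columns `lat` and `lon`.
#' @export
cellCenter <- function(row, col, grid) {
  row <- as.integer(row); col <- as.integer(col)
  if (any(row < 0L | row >= grid@nRows))
    stop("cell row index out of range", call. = FALSE)
  if (any(col < 0L | col >= grid@nCols))
    stop("cell col index out of range", call. = FALSE)
  data.frame(
    lat = grid@latOrigin + (row + 0.5) * grid@cellSize,
    lon = grid@lonOrigin + (col + 0.5) * grid@cellSize
  )
}

# single integer key per cell, used for set operations on cell sets
cellKey <- function(row, col, grid) as.integer(row) * grid@nCols + as.integer(col)

keyToCell <- function(key, grid) {
  data.frame(row = key %/% grid@nCols, col = key %% grid@nCols)
}

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0088 km (IUGG mean radius).
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (vectorised).
#' @return Distance(s) in km.
#' @examples
#' greatCircleKm(0, 0, 0, 180)  # half the circumference, ~20015 km
#' @export
greatCircleKm <- function(lat1, lon1, lat2, lon2) {
  ok <- function(lat, lon) all(abs(lat) <= 90) && all(abs(lon) <= 180)
  stopIfNot(ok(lat1, lon1) && ok(lat2, lon2),
            "coordinates must satisfy |lat| <= 90 and |lon| <= 180")
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_KM)
}

#' Read/write a grid definition as JSON
#'
#' The grid definition `{lat_origin, lon_origin, cell_size, n_rows, n_cols}`
#' is shared by the record reader and all raster I/O.
#'
#' @param path file path.
#' @return `readGridSpec` returns a [GridSpec-class]; `writeGridSpec` returns
#'   `path` invisibly.
#' @export
readGridSpec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("lat_origin", "lon_origin", "cell_size", "n_rows", "n_cols")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("grid definition is missing fields: ", paste(missing, collapse = ", "),
         call. = FALSE)
  gridSpec(x$lat_origin, x$lon_origin, x$cell_size, x$n_rows, x$n_cols)
}

#' @rdname readGridSpec
#' @param grid a [GridSpec-class] to serialise.
#' @export
writeGridSpec <- function(grid, path) {
  jsonlite::write_json(
    list(lat_origin = grid@latOrigin, lon_origin = grid@lonOrigin,
         cell_size = grid@cellSize, n_rows = grid@nRows, n_cols = grid@nCols),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
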