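# Raster container, ESRI ASCII grid I/O and block resampling.

#' Construct a RasterGrid
#'
#' @param values numeric `nRows x nCols` matrix, row 1 = southern row; `NA`
#'   marks nodata.
#' @param grid a [GridSpec-class].
#' @param name layer name.
#' @return A [RasterGrid-class].
#' @export
rasterGrid <- function(values, grid, name = "") {
  new("RasterGrid", grid = grid, values = values, name = name)
}

#' Layer values / grid accessors
#' @param x a [RasterGrid-class].
#' @return `layerValues` the value matrix; `layerGrid` the [GridSpec-class];
#'   `layerName` the name.
#' @export
layerValues <- function(x) x@values

#' @rdname layerValues
#' @export
layerGrid <- function(x) x@grid

#' @rdname layerValues
#' @export
layerName <- function(x) x@name

# value lookup at 0-based cells; cells is a data.frame(row, col)
valuesAtCells <- function(x, cells) {
  x@values[cbind(cells$row + 1L, cells$col + 1L)]
}

#' Read an ESRI ASCII grid
#'
#' Understands `xllcorner`/`yllcorner` or `xllcenter`/`yllcenter` headers and
#' an optional `NODATA_value`. Rows in the file run north to south; they are
#' flipped so that row 1 of the value matrix is the southern row.
#'
#' @param path file path.
#' @param name layer name to attach.
#' @return A [RasterGrid-class].
#' @export
readAsciiGrid <- function(path, name = "") {
  lines <- readLines(path, n = 6L)
  header <- list()
  nHeader <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2 && is.na(suppressWarnings(as.numeric(parts[1])))) {
      header[[tolower(parts[1])]] <- as.numeric(parts[2])
      nHeader <- nHeader + 1L
    } else break
  }
  need <- c("ncols", "nrows", "cellsize")
  missing <- setdiff(need, names(header))
  if (length(missing))
    stop("ASCII grid header missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  cs <- header$cellsize
  xll <- header$xllcorner %||% (header$xllcenter - cs / 2)
  yll <- header$yllcorner %||% (header$yllcenter - cs / 2)
  if (is.null(xll) || is.null(yll))
    stop("ASCII grid header missing corner/center coordinates", call. = FALSE)
  nodata <- header$nodata_value

  vals <- scan(path, what = numeric(), skip = nHeader, quiet = TRUE)
  nr <- as.integer(header$nrows); nc <- as.integer(header$ncols)
  if (length(vals) != nr * nc)
    stop(sprintf("ASCII grid has %d values, expected %d", length(vals), nr * nc),
         call. = FALSE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(nodata)) m[m == nodata] <- NA
  m <- m[nr:1, , drop = FALSE]  # file is north-first; store south-first
  rasterGrid(m, gridSpec(yll, xll, cs, nr, nc), name = name)
}

#' Write an ESRI ASCII grid
#'
#' @param x a [RasterGrid-class].
#' @param path output path.
#' @param nodata value written for `NA` cells.
#' @return `path` invisibly.
#' @export
writeAsciiGrid <- function(x, path, nodata = -9999) {
  g <- x@grid
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", g@nCols),
    sprintf("nrows %d", g@nRows),
    sprintf("xllcorner %.10g", g@lonOrigin),
    sprintf("yllcorner %.10g", g@latOrigin),
    sprintf("cellsize %.10g", g@cellSize),
    sprintf("NODATA_value %.10g", nodata)
  ), con)
  m <- x@values[g@nRows:1, , drop = FALSE]  # write north-first
  m[is.na(m)] <- nodata
  for (i in seq_len(nrow(m)))
    writeLines(paste(sprintf("%.10g", m[i, ]), collapse = " "), con)
  invisible(path)
}

#' Resample a raster onto an analysis grid
#'
#' Block-mean aggregation assigns each source cell (by its centre) to the
#' target cell containing it and averages, ignoring nodata; applied to a 0/1
#' wetland mask this yields percent wetland per target cell. `nearest`
#' samples the source cell containing each target cell centre.
#'
#' @param x source [RasterGrid-class].
#' @param grid target [GridSpec-class].
#' @param method `"mean"` (block aggregation) or `"nearest"`.
#' @return A [RasterGrid-class] on `grid`.
#' @export
resampleToGrid <- function(x, grid, method = c("mean", "nearest")) {
  method <- match.arg(method)
  sg <- x@grid
  out <- matrix(NA_real_, grid@nRows, grid@nCols)

  if (method == "mean") {
    # source cell centres
    rows <- rep(seq_len(sg@nRows) - 1L, times = sg@nCols)
    cols <- rep(seq_len(sg@nCols) - 1L, each = sg@nRows)
    ctr <- cellCenter(rows, cols, sg)
    inside <- ctr$lat >= grid@latOrigin & ctr$lat < gridLatMax(grid) &
              ctr$lon >= grid@lonOrigin & ctr$lon < gridLonMax(grid)
    if (!any(inside))
      stop("source raster does not overlap the target grid", call. = FALSE)
    tcell <- binToGrid(ctr$lat[inside], ctr$lon[inside], grid)
    v <- as.vector(x@values)[inside]
    key <- cellKey(tcell$row, tcell$col, grid)
    keep <- !is.na(v)
    if (any(keep)) {
      sums <- rowsum(v[keep], key[keep])
      cnts <- rowsum(rep(1, sum(keep)), key[keep])
      k <- as.integer(rownames(sums))
      out[cbind(k %/% grid@nCols + 1L, k %% grid@nCols + 1L)] <- sums / cnts
    }
  } else {
    rows <- rep(seq_len(grid@nRows) - 1L, times = grid@nCols)
    cols <- rep(seq_len(grid@nCols) - 1L, each = grid@nRows)
    ctr <- cellCenter(rows, cols, grid)
    inside <- ctr$lat >= sg@latOrigin & ctr$lat < gridLatMax(sg) &
              ctr$lon >= sg@lonOrigin & ctr$lon < gridLonMax(sg)
    if (!any(inside))
      stop("target grid does not overlap the source raster", call. = FALSE)
    scell <- binToGrid(ctr$lat[inside], ctr$lon[inside], sg)
    out[cbind(rows[inside] + 1L, cols[inside] + 1L)] <-
      x@values[cbind(scell$row + 1L, scell$col + 1L)]
  }
  rasterGrid(out, grid, name = x@name)
}
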