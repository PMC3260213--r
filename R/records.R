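# banding_records module, part 2: encounter-record I/O and filtering.
#
# Records are kept as a plain data.frame with columns
#   band_id, species, event ("banding"|"recovery"), date (Date), lat, lon
# plus derived 0-based cell indices row, col when a grid is attached.

RECORD_COLUMNS <- c("band_id", "species", "event", "date", "lat", "lon")

validateRecords <- function(records) {
  missing <- setdiff(RECORD_COLUMNS, names(records))
  stopIfNot(length(missing) == 0,
            "records are missing columns: ", paste(missing, collapse = ", "))
  stopIfNot(all(records$event %in% c("banding", "recovery")),
            "event must be 'banding' or 'recovery'")
  stopIfNot(all(abs(records$lat) <= 90) && all(abs(records$lon) <= 180),
            "coordinates out of range")
  invisible(records)
}

#' Read banding/encounter records from CSV
#'
#' Expects a header `band_id,species,event,date,lat,lon` with ISO-8601 dates
#' and `event` one of `banding` or `recovery`. Malformed rows raise an error
#' naming the offending line (header = line 1). When a grid is supplied the
#' derived 0-based cell indices `row`, `col` are attached.
#'
#' @param path CSV path.
#' @param grid a [GridSpec-class] used to derive cell indices, or `NULL` to
#'   skip binning.
#' @return data.frame of records.
#' @export
readRecords <- function(path, grid = conusGrid()) {
  raw <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  missing <- setdiff(RECORD_COLUMNS, names(raw))
  if (length(missing))
    stop("record file is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  line <- seq_len(nrow(raw)) + 1L  # header occupies line 1

  bad <- which(!raw$event %in% c("banding", "recovery"))
  if (length(bad))
    stop(sprintf("line %d: unknown event type '%s'", line[bad[1]],
                 raw$event[bad[1]]), call. = FALSE)

  date <- as.Date(raw$date, format = "%Y-%m-%d")
  bad <- which(is.na(date))
  if (length(bad))
    stop(sprintf("line %d: invalid date '%s'", line[bad[1]], raw$date[bad[1]]),
         call. = FALSE)

  lat <- suppressWarnings(as.numeric(raw$lat))
  lon <- suppressWarnings(as.numeric(raw$lon))
  bad <- which(is.na(lat) | is.na(lon) | abs(lat) > 90 | abs(lon) > 180)
  if (length(bad))
    stop(sprintf("line %d: invalid coordinates '%s,%s'", line[bad[1]],
                 raw$lat[bad[1]], raw$lon[bad[1]]), call. = FALSE)

  records <- data.frame(
    band_id = raw$band_id, species = raw$species, event = raw$event,
    date = date, lat = lat, lon = lon, stringsAsFactors = FALSE)
  if (!is.null(grid)) records <- binRecords(records, grid)
  records
}

#' Attach grid-cell indices to records
#'
#' @param records record data.frame.
#' @param grid a [GridSpec-class].
#' @return The records with 0-based `row`, `col` columns replaced/added.
#' @export
binRecords <- function(records, grid) {
  validateRecords(records)
  cells <- binToGrid(records$lat, records$lon, grid)
  records$row <- cells$row
  records$col <- cells$col
  records
}

#' Write records to CSV
#'
#' Writes the six canonical columns (derived cell indices are not written;
#' they are re-derived on read). Write-then-read round-trips field-by-field.
#'
#' @param records record data.frame.
#' @param path output CSV path.
#' @return `path` invisibly.
#' @export
writeRecords <- function(records, path) {
  validateRecords(records)
  out <- records[, RECORD_COLUMNS]
  out$date <- format(out$date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Restrict records to a study window
#'
#' Keeps records with `start <= date <= end`, both ends inclusive.
#'
#' @param records record data.frame.
#' @param start,end `Date` (or ISO-8601 strings) bounding the window.
#' @return Filtered records.
#' @export
filterStudyWindow <- function(records, start, end) {
  validateRecords(records)
  start <- as.Date(start); end <- as.Date(end)
  stopIfNot(!is.na(start) && !is.na(end), "start and end must be valid dates")
  stopIfNot(start <= end, "study window is inverted: start is after end")
  records[records$date >= start & records$date <= end, , drop = FALSE]
}
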