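# season_delineation module: species-specific annual-cycle windows from the
# movement rates of banded birds recovered within 30 days.

#' Construct annual-cycle windows from migration intervals
#'
#' Given the spring and fall migration intervals, summer and winter are the
#' complementary circular intervals: summer runs from the end of spring to
#' the start of fall, winter from the end of fall to the start of spring.
#'
#' @param species species code.
#' @param spring,fall numeric `c(startDoy, endDoyExclusive)` half-open
#'   circular day-of-year intervals (365-day year).
#' @param source one of `"detected"`, `"prior"`, `"mixed"`.
#' @return A [SeasonWindows-class].
#' @export
seasonWindows <- function(species, spring, fall, source = "prior") {
  new("SeasonWindows", species = species,
      spring = as.numeric(spring), fall = as.numeric(fall),
      summer = c(spring[2], fall[1]), winter = c(fall[2], spring[1]),
      source = source)
}

#' Pair recoveries with their banding event
#'
#' Matches each recovery to the banding record with the same band id and
#' keeps pairs recovered 1 to `maxDays` days after banding. Same-day
#' recoveries are excluded (their daily movement rate is undefined);
#' recoveries without a matching banding are skipped with a message.
#'
#' @param records record data.frame with derived cells (see [readRecords()]).
#' @param maxDays maximum elapsed days between banding and recovery
#'   (default 30, restricting to within-season movement).
#' @return data.frame with one row per retained pair: `band_id`, `species`,
#'   banding (`b_`) and recovery (`r_`) date/coordinates/cell, `elapsed`.
#' @export
pairedRecoveries <- function(records, maxDays = 30) {
  validateRecords(records)
  stopIfNot(all(c("row", "col") %in% names(records)),
            "records must carry derived cells; see binRecords()")
  b <- records[records$event == "banding", , drop = FALSE]
  r <- records[records$event == "recovery", , drop = FALSE]
  if (anyDuplicated(b$band_id))
    stop("inconsistent record set: duplicated banding band_id", call. = FALSE)
  idx <- match(r$band_id, b$band_id)
  unmatched <- sum(is.na(idx))
  if (unmatched > 0)
    message(unmatched, " recoveries without a matching banding were skipped")
  keep <- !is.na(idx)
  r <- r[keep, , drop = FALSE]; idx <- idx[keep]
  elapsed <- as.integer(r$date - b$date[idx])
  ok <- elapsed >= 1L & elapsed <= maxDays
  data.frame(
    band_id = r$band_id[ok], species = r$species[ok],
    b_date = b$date[idx][ok], b_lat = b$lat[idx][ok], b_lon = b$lon[idx][ok],
    b_row = b$row[idx][ok], b_col = b$col[idx][ok],
    r_date = r$date[ok], r_lat = r$lat[ok], r_lon = r$lon[ok],
    r_row = r$row[ok], r_col = r$col[ok],
    elapsed = elapsed[ok], stringsAsFactors = FALSE)
}

#' Daily movement rate of recovery pairs
#'
#' The great-circle distance between the *cell centres* of banding and
#' recovery (records are binned, so cell centres are the known locations)
#' divided by the elapsed days. Each observation is dated at the pair's
#' midpoint, `banding date + floor(elapsed / 2)`.
#'
#' @param pairs output of [pairedRecoveries()].
#' @param grid the [GridSpec-class] the records are binned to.
#' @return data.frame with `species`, `midpoint_date`, `km_per_day`,
#'   `elapsed`.
#' @export
dailyVelocity <- function(pairs, grid) {
  stopIfNot(all(pairs$elapsed >= 1L), "elapsed days must be >= 1")
  if (nrow(pairs) == 0)
    return(data.frame(species = character(), midpoint_date = as.Date(character()),
                      km_per_day = numeric(), elapsed = integer()))
  bc <- cellCenter(pairs$b_row, pairs$b_col, grid)
  rc <- cellCenter(pairs$r_row, pairs$r_col, grid)
  km <- greatCircleKm(bc$lat, bc$lon, rc$lat, rc$lon)
  data.frame(
    species = pairs$species,
    midpoint_date = pairs$b_date + pairs$elapsed %/% 2L,
    km_per_day = km / pairs$elapsed,
    elapsed = pairs$elapsed, stringsAsFactors = FALSE)
}

#' Weekly mean movement-rate series
#'
#' Averages daily movement rates by the 0-based week of the observation's
#' midpoint date (`week = min(floor((doy - 1) / 7), 51)`; week 51 absorbs the
#' year's final days). Weeks without observations are `NA`, not zero.
#'
#' @param observations output of [dailyVelocity()]; must contain one species.
#' @return A [WeeklyVelocitySeries-class].
#' @export
weeklyMeanSeries <- function(observations) {
  stopIfNot(nrow(observations) >= 1, "at least one velocity observation required")
  sp <- unique(observations$species)
  stopIfNot(length(sp) == 1,
            "observations must contain a single species; split before averaging")
  wk <- weekOfDoy(dayOfYear(observations$midpoint_date))
  counts <- integer(52)
  values <- rep(NA_real_, 52)
  agg <- tapply(observations$km_per_day, wk, mean)
  counts[as.integer(names(agg)) + 1L] <-
    as.integer(table(wk)[names(agg)])
  values[as.integer(names(agg)) + 1L] <- as.numeric(agg)
  new("WeeklyVelocitySeries", species = sp, values = values, counts = counts)
}

# circular linear interpolation of missing weeks
interpolateCircular <- function(v) {
  n <- length(v)
  obs <- which(!is.na(v))
  if (length(obs) == 0) stop("no informative weeks", call. = FALSE)
  if (length(obs) == n) return(v)
  out <- v
  for (k in which(is.na(v))) {
    dPrev <- (k - obs) %% n
    dNext <- (obs - k) %% n
    iPrev <- obs[which.min(ifelse(dPrev == 0, n, dPrev))]
    iNext <- obs[which.min(ifelse(dNext == 0, n, dNext))]
    a <- (k - iPrev) %% n
    b <- (iNext - k) %% n
    out[k] <- (b * v[iPrev] + a * v[iNext]) / (a + b)
  }
  out
}

# circular moving average, window 3
smoothCircular3 <- function(v) {
  n <- length(v)
  (v[c(n, 1:(n - 1))] + v + v[c(2:n, 1)]) / 3
}

# maximal circular runs of TRUE; returns list of integer index vectors (1-based)
circularRuns <- function(flag) {
  n <- length(flag)
  if (all(flag) || !any(flag)) return(list())
  # rotate so position 1 is FALSE, find runs, rotate back
  start <- which(!flag)[1]
  rot <- c(flag[start:n], flag[seq_len(start - 1L)])
  r <- rle(rot)
  ends <- cumsum(r$lengths)
  begins <- ends - r$lengths + 1L
  runs <- lapply(which(r$values), function(i) {
    ((begins[i]:ends[i]) + start - 2L) %% n + 1L
  })
  runs
}

#' Delineate migration windows from a weekly velocity series
#'
#' Fall and spring migration are located as peaks in the weekly movement-rate
#' series. The procedure: (i) missing weeks are filled by circular linear
#' interpolation; (ii) the series is smoothed with a circular 3-week moving
#' average; (iii) candidate migration periods are maximal runs of consecutive
#' weeks whose smoothed value exceeds `mean + 0.5 * sd` of the smoothed
#' series; (iv) the run with the highest peak whose circular midpoint falls
#' in January-June becomes spring, the highest-peak run with midpoint in
#' July-December becomes fall; (v) when either half-year has no qualifying
#' run (no clear migration signal) that window is taken from the
#' natural-history `prior`; (vi) summer and winter fill the circular
#' complement. A series with fewer than 26 informative weeks falls back to
#' the prior entirely, with a warning.
#'
#' @param series a [WeeklyVelocitySeries-class].
#' @param prior a [SeasonWindows-class] from natural history, used when no
#'   clear signal is present.
#' @return A [SeasonWindows-class] with `source` recording provenance.
#' @export
detectMigrationWindows <- function(series, prior) {
  stopIfNot(is(series, "WeeklyVelocitySeries"), "series must be a WeeklyVelocitySeries")
  stopIfNot(is(prior, "SeasonWindows"), "prior must be a SeasonWindows")
  if (sum(series@counts > 0) < 26L) {
    warning("fewer than 26 informative weeks; using prior windows", call. = FALSE)
    return(seasonWindows(series@species, prior@spring, prior@fall, source = "prior"))
  }
  v <- interpolateCircular(series@values)
  s <- smoothCircular3(v)
  thr <- mean(s) + 0.5 * stats::sd(s)
  runs <- circularRuns(s > thr)

  pickHalf <- function(firstHalf) {
    best <- NULL; bestPeak <- -Inf
    for (run in runs) {
      # circular midpoint of the run, in 0-based weeks
      w0 <- run[1] - 1L
      mid <- (w0 + (length(run) - 1) / 2) %% 52
      inFirst <- mid < 26
      if (inFirst == firstHalf && max(s[run]) > bestPeak) {
        bestPeak <- max(s[run]); best <- run
      }
    }
    best
  }
  runToInterval <- function(run) {
    ws <- run[1] - 1L            # 0-based first week
    we <- run[length(run)] - 1L  # 0-based last week
    start <- 7L * ws + 1L
    end <- if (we == 51L) 1L else 7L * (we + 1L) + 1L
    c(start, end)
  }

  springRun <- pickHalf(TRUE)
  fallRun <- pickHalf(FALSE)
  spring <- if (is.null(springRun)) prior@spring else runToInterval(springRun)
  fall <- if (is.null(fallRun)) prior@fall else runToInterval(fallRun)
  source <- if (is.null(springRun) && is.null(fallRun)) "prior"
            else if (is.null(springRun) || is.null(fallRun)) "mixed"
            else "detected"
  seasonWindows(series@species, spring, fall, source = source)
}

#' Assign dates to seasons
#'
#' Each date maps to exactly one of `spring`, `summer`, `fall`, `winter`;
#' windows are inclusive of their start day and exclusive of their end day
#' (circular). The leap day is folded into day 365.
#'
#' @param dates `Date` vector (or day-of-year integers).
#' @param windows a [SeasonWindows-class].
#' @return factor with levels `spring`, `summer`, `fall`, `winter`.
#' @export
assignSeason <- function(dates, windows) {
  doy <- if (inherits(dates, "Date")) dayOfYear(dates) else as.integer(dates)
  out <- rep(NA_character_, length(doy))
  for (nm in c("spring", "summer", "fall", "winter")) {
    iv <- slot(windows, nm)
    out[inCircularInterval(doy, iv[1], iv[2])] <- nm
  }
  factor(out, levels = c("spring", "summer", "fall", "winter"))
}

#' Read/write season windows as YAML
#'
#' Serialises `{species, spring: [s, e], fall: [s, e], source}`; summer and
#' winter are re-derived as the complementary intervals on read.
#'
#' @param path file path.
#' @param windows a [SeasonWindows-class] (write only).
#' @return `readSeasonWindows` returns a [SeasonWindows-class];
#'   `writeSeasonWindows` returns `path` invisibly.
#' @export
writeSeasonWindows <- function(windows, path) {
  yaml::write_yaml(list(
    species = windows@species,
    spring = as.integer(windows@spring),
    fall = as.integer(windows@fall),
    source = windows@source), path)
  invisible(path)
}

#' @rdname writeSeasonWindows
#' @export
readSeasonWindows <- function(path) {
  x <- yaml::read_yaml(path)
  seasonWindows(x$species, unlist(x$spring), unlist(x$fall), source = x$source)
}
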