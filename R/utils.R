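# Internal helpers shared across modules.

# Season arithmetic uses a fixed 365-day circular year; the leap day (yday 366)
# is folded into day 365 so week/season boundaries are identical across years.
YEAR_DAYS <- 365L

dayOfYear <- function(date) {
  doy <- as.POSIXlt(date)$yday + 1L
  pmin(doy, YEAR_DAYS)
}

# Weeks are 0-based; week 51 absorbs days 358-365 rather than opening a
# partial 53rd week.
weekOfDoy <- function(doy) {
  pmin((as.integer(doy) - 1L) %/% 7L, 51L)
}

# Deterministic sub-seed derivation: every stochastic stage draws its own seed
# from the master seed so stages can be re-run independently.
deriveSeed <- function(seed, offset) {
  s <- (as.numeric(seed) %% 1e6) * 2048 + 7919 * (offset %% 1e4)
  as.integer((s %% 2147483646) + 1)
}

logSumExp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# doy membership in a half-open circular interval [s, e) on the 365-day year
inCircularInterval <- function(doy, s, e) {
  if (s < e) doy >= s & doy < e else doy >= s | doy < e
}

circularIntervalLength <- function(s, e) {
  len <- (e - s) %% YEAR_DAYS
  if (len == 0) YEAR_DAYS else len
}

stopIfNot <- function(cond, ...) {
  if (!isTRUE(cond)) stop(..., call. = FALSE)
}
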