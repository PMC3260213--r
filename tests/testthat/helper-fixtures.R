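# Shared fixtures, built once per test run and memoised. All fixtures are
# generated in code from fixed seeds; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# the default synthetic covariate stack used across modules
sharedStack <- function() memo("stack", generateLandscape(42))

sharedNiches <- function() defaultNiches()

sharedEffort <- function() defaultEffort(sharedStack()@grid, seed = 5)

# multi-species banding records on the shared stack
sharedRecords <- function() {
  memo("records",
       simulateBandingRecords(sharedNiches(), sharedEffort(), sharedStack(),
                              seed = 11))
}

sharedWindows <- function() lapply(sharedNiches(), trueSeasonWindows)

# focal-species winter presences and target-group background candidates
sharedOccurrence <- function() {
  memo("occurrence", {
    rec <- sharedRecords()
    w <- sharedWindows()
    list(
      presences = presenceCells(rec, "WAFF", "winter", w$WAFF),
      candidates = targetGroupBackground(rec, "WAFF", "winter", w,
                                         sharedStack()@grid))
  })
}

# small record set with known pairing structure
toyRecords <- function(grid = gridSpec(30, -100, 1/6, 30, 30)) {
  rec <- data.frame(
    band_id = c("b1", "b1", "b2", "b2", "b3", "b3", "b4", "b4", "b5"),
    species = "SP",
    event = c("banding", "recovery", "banding", "recovery", "banding",
              "recovery", "banding", "recovery", "recovery"),
    date = as.Date(c("1995-04-10", "1995-04-30", "1995-05-01", "1995-06-15",
                     "1995-07-01", "1995-07-01", "1995-09-10", "1995-09-11",
                     "1995-10-01")),
    lat = c(31, 32, 31.5, 33, 32, 32, 31, 31.2, 34),
    lon = c(-99, -98, -99.5, -98.5, -97, -97, -96, -96, -96),
    stringsAsFactors = FALSE)
  binRecords(rec, grid)
}
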