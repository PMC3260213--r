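# Annual-cycle delineation from within-30-day recovery movement rates.

# weekly series with given values (0-based weeks), NA = missing
makeSeries <- function(values, species = "SP") {
  counts <- ifelse(is.na(values), 0L, 10L)
  new("WeeklyVelocitySeries", species = species, values = values,
      counts = counts)
}

priorWindows <- function() seasonWindows("SP", c(60, 151), c(244, 335))

test_that("recovery pairing keeps 1-30 day pairs and skips the rest", {
  rec <- toyRecords()
  expect_message(pairs <- pairedRecoveries(rec), "1 recoveries without")
  # b1: 20 days kept; b2: 45 days out of window; b3: same-day excluded;
  # b4: 1 day kept; b5: unmatched
  expect_equal(sort(pairs$band_id), c("b1", "b4"))
  expect_equal(pairs$elapsed[pairs$band_id == "b1"], 20L)
  expect_equal(pairs$elapsed[pairs$band_id == "b4"], 1L)

  # a recovery 31 days after banding is excluded, 30 days is kept
  rec31 <- data.frame(
    band_id = c("x1", "x1", "x2", "x2"), species = "SP",
    event = c("banding", "recovery", "banding", "recovery"),
    date = as.Date("1995-05-01") + c(0, 31, 0, 30),
    lat = c(31, 32, 31, 32), lon = rep(-99, 4), stringsAsFactors = FALSE)
  rec31 <- binRecords(rec31, gridSpec(30, -100, 1/6, 30, 30))
  pairs31 <- pairedRecoveries(rec31)
  expect_equal(pairs31$band_id, "x2")
})

test_that("daily velocity divides centre-to-centre distance by elapsed days", {
  g <- gridSpec(30, -100, 1/6, 30, 30)
  rec <- toyRecords(g)
  pairs <- suppressMessages(pairedRecoveries(rec))
  vel <- dailyVelocity(pairs, g)
  b1 <- pairs[pairs$band_id == "b1", ]
  ctrB <- cellCenter(b1$b_row, b1$b_col, g)
  ctrR <- cellCenter(b1$r_row, b1$r_col, g)
  expect_equal(vel$km_per_day[vel$species == "SP"][1],
               greatCircleKm(ctrB$lat, ctrB$lon, ctrR$lat, ctrR$lon) / 20)
  expect_equal(vel$midpoint_date[1], b1$b_date + 10)

  # same cell gives zero velocity; swapping endpoints leaves it unchanged
  same <- pairs[1, ]
  same$r_row <- same$b_row; same$r_col <- same$b_col
  expect_equal(dailyVelocity(same, g)$km_per_day, 0)
  swapped <- pairs[1, ]
  swapped[c("b_row", "b_col", "r_row", "r_col")] <-
    swapped[c("r_row", "r_col", "b_row", "b_col")]
  expect_equal(dailyVelocity(swapped, g)$km_per_day,
               dailyVelocity(pairs[1, ], g)$km_per_day)
})

test_that("weekly means fold day 365 into week 51 and flag missing weeks", {
  obs <- data.frame(species = "SP",
                    midpoint_date = as.Date(c("1995-01-02", "1995-01-05",
                                              "1995-12-31")),
                    km_per_day = c(10, 20, 7))
  ser <- weeklyMeanSeries(obs)
  expect_equal(ser@values[1], 15)        # week 0 mean of 10 and 20
  expect_equal(ser@values[52], 7)        # doy 365 folds into week 51
  expect_equal(sum(ser@counts), 3L)
  expect_true(all(is.na(ser@values[2:51])))

  # 520 uniform observations of 5 km/day fill all 52 weeks with mean 5
  days <- rep(seq(1, 364, by = 0.7)[1:520])
  unif <- data.frame(species = "SP",
                     midpoint_date = as.Date("1994-12-31") + floor(days),
                     km_per_day = 5)
  serU <- weeklyMeanSeries(unif)
  expect_true(all(serU@counts > 0))
  expect_equal(serU@values, rep(5, 52))

  expect_error(weeklyMeanSeries(obs[0, ]), "at least one")
})

test_that("gaussian bumps at weeks 14 and 40 are detected as migration", {
  wk <- 0:51
  vals <- 2 + 20 * exp(-(wk - 14)^2 / (2 * 2^2)) +
    20 * exp(-(wk - 40)^2 / (2 * 2^2))
  w <- detectMigrationWindows(makeSeries(vals), priorWindows())
  expect_equal(w@source, "detected")
  # recover the 0-based week range of each detected window
  springWeeks <- c(w@spring[1] - 1, w@spring[2] - 8) / 7
  fallWeeks <- c(w@fall[1] - 1, w@fall[2] - 8) / 7
  expect_true(abs(springWeeks[1] - 12) <= 1 && abs(springWeeks[2] - 16) <= 1)
  expect_true(abs(fallWeeks[1] - 38) <= 1 && abs(fallWeeks[2] - 42) <= 1)
})

test_that("flat and single-peak series fall back to the prior", {
  flat <- detectMigrationWindows(makeSeries(rep(4, 52)), priorWindows())
  expect_equal(flat@source, "prior")
  expect_equal(flat@spring, priorWindows()@spring)
  expect_equal(flat@fall, priorWindows()@fall)

  wk <- 0:51
  one <- 2 + 20 * exp(-(wk - 10)^2 / (2 * 2^2))  # March only
  mixed <- detectMigrationWindows(makeSeries(one), priorWindows())
  expect_equal(mixed@source, "mixed")
  expect_equal(mixed@fall, priorWindows()@fall)
  expect_false(identical(mixed@spring, priorWindows()@spring))
})

test_that("sparse series fall back entirely to the prior with a warning", {
  vals <- rep(NA_real_, 52)
  vals[1:20] <- 3
  expect_warning(w <- detectMigrationWindows(makeSeries(vals), priorWindows()),
                 "26 informative")
  expect_equal(w@source, "prior")
})

test_that("missing weeks are interpolated before detection", {
  wk <- 0:51
  vals <- 2 + 20 * exp(-(wk - 14)^2 / (2 * 2^2)) +
    20 * exp(-(wk - 40)^2 / (2 * 2^2))
  vals[c(5, 14, 27, 45)] <- NA  # drop weeks, including one at the spring peak
  w <- detectMigrationWindows(makeSeries(vals), priorWindows())
  expect_equal(w@source, "detected")
  springMid <- (w@spring[1] - 1 + w@spring[2] - 8) / 14
  expect_lt(abs(springMid - 14), 1.5)
})

test_that("detection co-rotates with the calendar", {
  wk <- 0:51
  vals <- 2 + 20 * exp(-(wk - 14)^2 / (2 * 2^2)) +
    20 * exp(-(wk - 40)^2 / (2 * 2^2))
  base <- detectMigrationWindows(makeSeries(vals), priorWindows())
  for (shift in c(2L, 4L)) {
    rotated <- c(vals[(52 - shift + 1):52], vals[1:(52 - shift)])
    w <- detectMigrationWindows(makeSeries(rotated), priorWindows())
    expect_equal(w@spring, (base@spring + 7 * shift - 1) %% 365 + 1,
                 info = paste("shift", shift))
    expect_equal(w@fall, (base@fall + 7 * shift - 1) %% 365 + 1)
  }
})

test_that("every day of the year maps to exactly one season", {
  set.seed(8)
  for (i in 1:20) {
    s0 <- sample(1:180, 1); s1 <- s0 + sample(14:60, 1)
    f0 <- sample(182:300, 1); f1 <- f0 + sample(14:60, 1)
    w <- seasonWindows("SP", c(s0, s1), c(f0, min(f1, 365)))
    season <- assignSeason(1:365, w)
    expect_false(anyNA(season))
    expect_equal(as.integer(table(season)["spring"]), s1 - s0)
  }
})

test_that("season boundaries are start-inclusive and winter wraps the year", {
  w <- seasonWindows("SP", c(85, 120), c(267, 302))
  expect_equal(as.character(assignSeason(85L, w)), "spring")
  expect_equal(as.character(assignSeason(119L, w)), "spring")
  expect_equal(as.character(assignSeason(120L, w)), "summer")
  # winter wraps across the year boundary
  expect_equal(as.character(assignSeason(as.Date("1995-12-31"), w)), "winter")
  expect_equal(as.character(assignSeason(as.Date("1996-01-15"), w)), "winter")
  expect_equal(as.character(assignSeason(as.Date("1996-02-29"), w)), "winter")
})

test_that("season windows round-trip through YAML", {
  w <- seasonWindows("SP", c(85, 120), c(267, 302), source = "detected")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeSeasonWindows(w, path)
  back <- readSeasonWindows(path)
  expect_equal(back@spring, w@spring)
  expect_equal(back@fall, w@fall)
  expect_equal(back@winter, w@winter)
  expect_equal(back@source, "detected")
})
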