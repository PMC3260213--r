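# hydrofowl

Distribution modelling of migratory waterfowl across the full annual cycle,
with equilibrium depth-to-water-table (DWT) as a process-driven wetland
covariate.

Distribution models for migratory, wetland-bound birds are notoriously weaker
than for other bird groups: the birds move with the seasons, and wetlands are
poorly and inconsistently mapped. `hydrofowl` implements a modelling strategy
that attacks both problems at once, aimed at quantitative ecologists working
with presence-only banding/encounter data:

* **Species-specific annual cycles.** Spring and fall migration windows are
  delineated per species from the movement rates of banded birds recovered
  within 30 days of banding (distance between 10-minute grid-cell centres
  divided by elapsed days, averaged by week); summer and winter fill the
  complementary intervals. Models are then fitted per season, not per year.
* **A process-driven wetland covariate.** Instead of a land-cover wetland
  class, the package uses depth to water table — the long-term equilibrium of
  climate recharge `R` against lateral groundwater drainage with
  depth-decaying transmissivity `T(d) = T0 e^(-d/f)`. A gridded solver finds
  the per-cell depth `d >= 0` at which `R · A = Σ_j T(d̄_ij)(h_i - h_j)`,
  with ponded cells clipped to the surface and rivers/ocean held at fixed
  head. Cells with `d <= 1 m` correspond to wetlands.
* **Target-group backgrounds.** Pseudo-absences for each species and season
  are the recorded locations of the *other* study species where the focal
  species is absent, so the background carries the same survey-effort bias as
  the presences.
* **A from-scratch maximum-entropy SDM.** Presence-background models are the
  Gibbs distribution `q(x) ∝ exp(λ·f(x))` maximising
  `mean(λ·f(x_i)) − log Z(λ) − Σ_j β_j|λ_j|` over linear, quadratic, product
  and hinge features of the covariates, fitted by monotone coordinate
  descent; predictions are reported on MaxEnt's logistic scale
  `e^H q/(1 + e^H q)` (prevalence 0.5). The protocol refits 100 replicates
  with randomised 70–30 presence splits and fresh background samples, scoring
  held-out presences by the Mann–Whitney AUC.
* **Permutation variable importance.** Bagged classification trees (bootstrap
  sampling, ~37% out-of-bag per tree) score each covariate by the mean
  decrease in OOB accuracy after permuting it, normalised by its standard
  error — plus binned DWT response curves with a GCV-smoothed cubic spline.

Because real banding-laboratory records are access-restricted, the package
ships a first-class synthetic generator (`generateLandscape()`,
`simulateBandingRecords()`) that reproduces the statistical structure of the
study inputs — co-sampled species, station-clustered banding effort, terminal
hunter-style recoveries displaced by season-dependent movement, and a
covariate stack whose DWT layer is actually solved from the recharge balance —
with every niche parameter known, so the whole pipeline is testable against
ground truth.

## Worked example

```r
library(hydrofowl)

## synthetic study conditions: covariates + two co-sampled species
stack   <- generateLandscape(seed = 42)
niches  <- defaultNiches()                      # dwtScale 0.5 m and 3 m
effort  <- defaultEffort(stack@grid, seed = 5)
records <- simulateBandingRecords(niches, effort, stack, seed = 11)

## annual-cycle delineation from within-30-day recovery velocities
pairs   <- pairedRecoveries(records[records$species == "WAFF", ])
series  <- weeklyMeanSeries(dailyVelocity(pairs, stack@grid))
windows <- detectMigrationWindows(series, trueSeasonWindows(niches$WAFF))
windows
#> SeasonWindows for WAFF (source: detected)
#>   spring doy [ 85, 120)
#>   summer doy [120, 267)
#>   fall   doy [267, 302)
#>   winter doy [302,  85)

## winter presences and target-group background
allWindows <- lapply(niches, trueSeasonWindows); allWindows$WAFF <- windows
pres <- presenceCells(records, "WAFF", "winter", windows)
cand <- targetGroupBackground(records, "WAFF", "winter", allWindows,
                              stack@grid)

## paired 100-replicate maxent protocol: does DWT add skill?
base    <- c("temperature", "precipitation", "elevation")
aucBase <- replicateFit(pres, cand, stack, base,            nRuns = 100, seed = 77)
aucDwt  <- replicateFit(pres, cand, stack, c(base, "dwt"),  nRuns = 100, seed = 77)
mean(aucBase$auc); mean(aucDwt$auc); sum(aucDwt$auc > aucBase$auc)
#> [1] 0.6257752
#> [1] 0.6931066
#> [1] 100
compareModels(aucDwt$auc, aucBase$auc)[c("better", "meanDiff", "p")]
#> $better: "A"   $meanDiff: 0.0674   $p: 7.45e-71

## permutation importance over 1000 bagged trees
bg  <- sampleBackground(cand, 500, seed = 301)
dat <- as.data.frame(covMatrix(stack, c(base, "dwt", "percent_wetland"),
                               rbind(pres, bg)))
y   <- rep(1:0, c(nrow(pres), nrow(bg)))
forest <- fitBaggedTrees(dat, y, nTrees = 1000, seed = 1)
importanceTable(forest, dat, seed = 1)
#>         covariate importance meanDecrease sdDecrease
#> 4             dwt      90.39      0.09134    0.03195
#> 1     temperature      29.91      0.01889    0.01997
#> 3       elevation      12.60      0.00639    0.01604
#> 2   precipitation       6.64      0.00359    0.01712
#> 5 percent_wetland      -5.61     -0.00144    0.00811
```

Reading the output: the detector recovers the generator's true migration
weeks (12–16 and 38–42) exactly; adding DWT to the base climate/terrain
covariates raises the mean held-out AUC from 0.626 to 0.693 and does so in
every one of the 100 paired replicates; and DWT dominates the permutation
importance ranking for this strongly wetland-affine species — the pattern the
method is designed to expose, on data where it is true by construction.

`runPipeline(defaultRunConfig(seed), "out/")` chains all of the above (plus
prediction surfaces and response curves) into one reproducible, manifested
run; `inst/scripts/hydrofowl.R` wraps it for the shell.

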