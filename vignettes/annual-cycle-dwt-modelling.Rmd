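---
title: "Annual-cycle waterfowl distribution modelling with water-table depth"
author: "hydrofowl authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annual-cycle waterfowl distribution modelling with water-table depth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydrofowl)
```

# The modelling problem

Migratory waterfowl are hard to model with standard species-distribution
methods for two compounding reasons. First, their distributions shift with
the annual cycle — a winter model and a breeding-season model of the same
species describe different geographies — so pooling records across the year
blurs both. Second, the habitat they depend on, wetlands, is mapped
inconsistently and changes faster than land-cover products are updated.

`hydrofowl` implements a pipeline that addresses both issues: it delineates
species-specific annual cycles directly from banding/recovery movement data,
and it replaces (or complements) land-cover wetland proxies with the
equilibrium depth to water table (DWT), a physically based quantity that can
be simulated anywhere and, in principle, projected under changed climate.
Because the genuine banding-laboratory data are access-restricted, the
package also ships a synthetic-data generator that reproduces the
*statistical structure* of those inputs with known ground truth; every claim
the pipeline makes is tested against that truth.

# Annual-cycle delineation

Banded birds recovered within 30 days of banding move, on average, much
faster during migration than during the stationary seasons. For each such
pair the movement rate is the great-circle distance between the banding and
recovery cell centres (records are binned to a 10-minute grid, so cell
centres are the known locations; the sphere radius is the IUGG mean
6371.0088 km) divided by the elapsed days, dated at the pair's midpoint.
Same-day recoveries are excluded — their rate is undefined — and the 30-day
cap keeps a pair's movement within one season.

Rates are averaged by 0-based week (`week = min(floor((doy - 1)/7), 51)`;
week 51 absorbs the last days of the year, and the leap day folds into day
365 so windows are identical across years). "Locating peaks" in this weekly
series is formalised deterministically:

1. missing weeks are filled by circular linear interpolation;
2. the series is smoothed by a circular 3-week moving average;
3. candidate migration periods are maximal runs of weeks above
   `mean + 0.5 sd` of the smoothed series — a scale-free threshold, so the
   detector is invariant to rescaling the velocities;
4. the highest-peak run with circular midpoint in January–June becomes
   spring, the highest in July–December becomes fall (the Northern-Hemisphere
   phenology assumed throughout);
5. a half-year with no qualifying run has "no clear migration signal" and
   falls back to the supplied natural-history prior, recorded in the
   `source` field; fewer than 26 informative weeks triggers a full fallback;
6. summer and winter are the complementary circular intervals, so the four
   windows always partition the 365-day year.

Velocity observations are assigned to the week of the pair's *midpoint*
date; with up to 30 elapsed days, dating them at the banding date would bias
detected windows about a week late. The synthetic generator uses the same
convention when assigning movement speeds, which is what makes its migration
weeks recoverable to within a week.

# The equilibrium water-table solver

DWT is modelled as the stable balance between climate-driven recharge
(precipitation minus evapotranspiration) and topographically driven lateral
groundwater flow. On a square grid with cell area $A$ and edge $\Delta x$,
the flux between 4-neighbours $i, j$ is

$$Q_{ij} = T(\bar d_{ij}) \frac{h_i - h_j}{\Delta x} w, \qquad
  T(d) = T_0 e^{-d/f},$$

with head $h = z - d$, $\bar d_{ij}$ the arithmetic mean of the two depths,
and $w = \Delta x$. Equilibrium requires $R_i A = \sum_j Q_{ij}$ at every
active cell, subject to $d \ge 0$ (ponded water is clipped to the surface
rather than routed — the downstream models only consume $d$) and to
fixed-head cells (rivers, ocean) holding a prescribed depth. The
transmissivity e-folding depth `f` (default 3 m) expresses that most lateral
flow happens near the surface; `T0` sets how efficiently the landscape
drains.

Starting from the water table at the surface, the solver relaxes each cell's
head towards the value that balances its budget at the current
transmissivities and stops when no cell's depth changes by more than the
tolerance (default 1 mm). Two numerical choices matter and are worth
stating:

* **Red-black Gauss–Seidel, not simultaneous updates.** Updating all cells
  at once admits a checkerboard mode in which neighbouring cells exchange
  overshoots indefinitely; alternating the two colours of the grid removes
  it and converges in tens to hundreds of sweeps on the default landscapes.
* **Stiffness-adaptive damping.** Where the equilibrium head excess
  $RA/\sum_j T_{ij}$ is large compared with $2f$ (dry cells whose
  transmissivity has collapsed), the bare update overshoots; the step is
  damped by $1/(1 + RA / (2f\sum_j T_{ij}))$, which bounds the per-sweep
  depth change and restores contraction. The user-facing `relax` parameter
  (default 0.5, in $(0, 1]$) scales this step.

Degenerate inputs behave predictably: a flat closed basin with positive
recharge ponds everywhere ($d \equiv 0$); zero recharge with a fixed-head
boundary equilibrates to the boundary depth exactly; net-negative recharge
with no boundary has no equilibrium (inflow cannot catch up with the
exponentially collapsing transmissivity) and raises an explicit unbounded-
drawdown error. A mass-balance diagnostic reports the summed absolute
imbalance of non-ponded cells relative to total recharge; it closes to well
under 1% at the default tolerance and tightens as the tolerance does.
The full continental hydrology this module emulates — explicit
evapotranspiration schemes, 9-second grids, validation against field wells —
is out of scope by design; what is retained is the balance *structure* that
makes valleys and coasts wet and ridges dry.

Thresholding the solved DWT at 1.0 m (inclusive) yields the wetland mask
used as the field's conventional wetland criterion.

# The synthetic study conditions

`generateLandscape()` builds a 60 × 100-cell, 1/6-degree stack spanning
30–40° N: elevation is a smoothed Gaussian random field (sd 40 m,
correlation length 3 cells) over a 200 m west-high regional gradient;
temperature follows a 0.8 °C/degree latitudinal gradient minus a
6.5 °C/km lapse; precipitation rises west to east from 0.35 to
1.3 m/yr. Recharge is precipitation minus a 0.55 m/yr reference
evapotranspiration, floored at 0.02 m/yr — the floor stands in for runoff
and capillary processes that keep dry-side cells from demanding a
non-existent equilibrium. The lowest 8% of cells are fixed-head rivers at
zero depth, and the DWT layer is the solved equilibrium on that landscape
(`T0 = 6e7` m²/yr, chosen so that roughly a third of cells sit within the
1 m wetland threshold while the dry tail spans several metres — a landscape
in which wetness is informative rather than ubiquitous or rare).

Percent wetland emulates a land-cover-derived proxy: a logistic transform of
DWT around the 1 m threshold plus noise whose variance is calibrated in
closed form so the DWT/percent-wetland correlation lands near the target
(default −0.36, the empirical correlation between simulated water tables
and land-cover wetland fractions). This gives the model comparison a
realistic, imperfectly correlated alternative wetland covariate.

Species are defined by a ground-truth suitability
$s = e^{-d/\delta}\, e^{-(T - T_{opt})^2/2\sigma_T^2}\,
e^{-(\phi - \phi_{season})^2/2\sigma_\phi^2}$: the single recoverable
wetland-affinity parameter is $\delta$ (suitability is exponential in DWT
rather than thresholded precisely so response-curve recovery has a smooth
known target). The default pair of species — $\delta$ = 0.5 m and 3 m with
offset migration weeks — spans the affinity gradient from teal-like wetland
specialists to goose-like generalists. Banding events are drawn from
suitability re-weighted by a Gaussian kernel (sd 1°) around ~15 survey
stations, giving both species the *shared* effort bias that target-group
backgrounds exist to absorb. Each banded bird gets one terminal recovery
(hunter-style): elapsed days geometric with mean 20 truncated at 60,
displacement `elapsed × velocity` north in spring, south in fall, random
bearing otherwise, with velocity 16 km/day inside the niche's true migration
weeks and 3 km/day outside — magnitudes that make delineation recoverable
but not trivial at ~1300 within-30-day pairs per species.

What the generator does *not* emulate — spatial autocorrelation of
residual suitability, multi-encounter life histories, reporting-rate
variation, population trend, managed water levels — bounds what passing
tests show: the pipeline recovers truth under the stated statistical
structure, not under every complication of real banding data.

# Backgrounds, maxent, and evaluation

Presences are the unique cells of a species' events within a season window
(cell-level deduplication matches the 10-minute binning). The target-group
background for a focal species and season is the union of the other species'
presence cells — each evaluated in *its own* window for that season, since
calendars are species-specific — minus the focal presences; absence is thus
judged at the cell-and-season level. Backgrounds are resampled uniformly
(default `min(10000, candidates)`) afresh in every replicate.

The distribution model is the Gibbs distribution over the fitting cells (the
background with the presence cells added, standard samples-with-data
handling) maximising

$$\frac{1}{m}\sum_i \lambda \cdot f(x_i) - \log Z_\lambda -
  \sum_j \beta_j |\lambda_j|.$$

Covariates are affinely scaled to $[0,1]$ from the fitting-cell bounds
*before* expansion into linear, quadratic, product and hinge features (10
evenly spaced interior knots per covariate, both orientations), which keeps
every feature in $[0,1]$ and makes the objective exactly invariant to affine
rescaling of the raw covariates. Feature classes auto-activate by presence
count (quadratic at 10, hinge at 15, product at 80); penalties follow the
class-specific rates of the usual auto-feature defaults interpolated by
sample size, times $s_j/\sqrt m$, and are exposed via `betaMultiplier` or an
explicit `beta` vector. Fitting is cyclic coordinate descent with a
soft-threshold Newton step and per-feature backtracking on the exact
objective, so the objective is non-decreasing by construction; convergence
is declared when a full cycle improves it by less than `tol` (default
1e-5). Predictions clamp covariates to the training bounds, and the logistic
output $e^H q/(1 + e^H q)$ (entropy $H$ of the fitted distribution, i.e.
prevalence 0.5) is the mapped "probability of occurrence"; the raw density
is retained for diagnostics. The replicate protocol refits 100 times with
fresh 70–30 presence splits and fresh backgrounds from a master seed, so two
covariate sets run with the same seed are exactly paired.

Evaluation is deliberately implemented in-repo rather than delegated: the
Mann–Whitney AUC via midranks (exactly the all-pairs count with ties at
half), the paired two-sided t-test on per-replicate AUC differences (chosen
over an unpaired test for power and determinism; a zero-variance difference
vector short-circuits to the sign of the mean), and permutation importance —
per tree, OOB accuracy minus OOB accuracy after permuting one covariate
among that tree's OOB rows, averaged and divided by its standard error over
trees (the classic normalisation). Only the individual CART trees come from
an established implementation (`rpart`); growing controls are modest
(`minsplit = 10`, `cp = 0.01`, no internal cross-validation) since the
ensemble, not the single tree, carries the signal.

Response curves sample 1,000 cells uniformly from a prediction surface, bin
DWT into 20 equal-width bins over the sampled range, and pass per-bin mean
probabilities to a cubic smoothing spline whose smoothness is chosen by
generalised cross-validation (bin means rather than a running mean of the
raw points — the procedure is deterministic given the seed and the bins are
the natural unit once depths are binned anyway). Two numerical notes: an
unconstrained cubic spline through steeply decaying convex means can
overshoot by a fraction of a percent in the flat tail, so monotonicity
should be judged at that tolerance; and the half-maximum depth summary is
resolved no finer than the bin width, which is why recovery of the
generating $\delta \ln 2$ is expected only within a factor of two.

# Orchestration and reproducibility

`runPipeline()` chains simulate → delineate → background → fit → evaluate
from a single configuration with one mandatory master seed; every stage
derives its own sub-seed deterministically, each output file is checksummed
into a manifest, and re-running the same configuration reproduces every
numeric output byte-for-byte. Rasters are read and written as ESRI ASCII
grids — human-readable, diffable, and sufficient for the desk-scale grids
this package targets. The default problem sizes (60 × 100 cells, two
species, 400 bandings per species-season, 100 replicates, 1000 trees) were
chosen so a full pipeline run plus its evaluation completes in minutes on a
single core; all are configurable upward.

# Known limitations

* The water-table module is a structural stand-in, not a calibrated
  hydrologic model: no evapotranspiration process model, no transient
  dynamics, no pumping or managed water levels, arithmetic (not harmonic)
  depth averaging in the transmissivity, and 4-neighbour flow only.
* The season detector reports `detected`/`prior`/`mixed` provenance but does
  not reproduce manual, judgment-based adjustment of dates against natural
  histories.
* Maxent features omit threshold/categorical classes, cumulative output and
  clamping diagnostics; the logistic output's prevalence is fixed at 0.5.
* Northern-Hemisphere calendars are assumed throughout (spring in the first
  half-year).
* AUC on presence-background data measures discrimination of presences from
  the chosen background, and target-group backgrounds deliberately share the
  presences' effort bias; absolute AUC values are therefore conservative and
  comparisons between covariate sets are the meaningful quantity.
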