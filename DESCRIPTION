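Package: hydrofowl
Title: Annual-Cycle Distribution Modelling of Migratory Waterfowl with
    Water-Table Depth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling migratory waterfowl distributions across the
    four portions of the annual cycle. Delineates species-specific migration
    seasons from the movement rates of banded birds recovered within 30 days,
    simulates equilibrium depth-to-water-table surfaces from a balance of
    climate recharge and topographically driven lateral groundwater flow,
    generates target-group background points from co-sampled species, fits
    presence-background maximum-entropy distribution models with L1-regularised
    feature weights, and evaluates covariates by permutation importance over
    bagged classification trees, ROC/AUC replicate comparisons and
    water-table-depth response curves. Includes a synthetic landscape and
    banding-record generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    geosphere,
    rpart,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'grid.R'
    'records.R'
    'raster.R'
    'seasons.R'
    'watertable.R'
    'synthetic.R'
    'background.R'
    'maxent.R'
    'importance.R'
    'pipeline.R'
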