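# pipeline_cli module: configuration, orchestration and output management
# tying the stages into one reproducible run:
# simulate -> delineate -> background -> fit -> evaluate.

#' Default run configuration
#'
#' A desk-scale synthetic end-to-end configuration: two co-sampled species
#' on a 40 x 60 cell 10-minute grid, detected season windows, paired
#' base-vs-base+dwt maxent replicates, permutation importance and a
#' water-table response curve for the focal season.
#'
#' @param seed mandatory master seed; every stage derives its own sub-seed
#'   from it.
#' @return Named configuration list (see [runPipeline()]).
#' @export
defaultRunConfig <- function(seed) {
  list(
    seed = as.integer(seed),
    grid = list(lat_origin = 30, lon_origin = -105, cell_size = 1/6,
                n_rows = 40, n_cols = 60),
    species = list(dwtScales = list(WAFF = 0.5, GENE = 3)),
    effort = list(nStations = 12, stationSd = 1, nBanding = 300),
    years = c(1990L, 1999L),
    seasonSource = "detect",
    season = "winter",
    focal = "WAFF",
    model = list(
      covariateSets = list(base = c("temperature", "precipitation", "elevation"),
                           base_dwt = c("temperature", "precipitation",
                                        "elevation", "dwt")),
      classes = "auto", betaMultiplier = 1.0, nRuns = 20,
      nBackground = 2000, trainFrac = 0.7),
    forest = list(nTrees = 300),
    response = list(n = 1000, nBins = 20)
  )
}

#' Read and validate a run configuration
#'
#' Reads a YAML configuration and validates it against the defaults
#' ([defaultRunConfig()]); unspecified fields fall back to the default.
#' A missing seed is a validation error raised before any stage runs.
#'
#' @param path YAML file path.
#' @return Validated configuration list.
#' @export
readRunConfig <- function(path) {
  user <- yaml::read_yaml(path)
  validateRunConfig(user)
  utils::modifyList(defaultRunConfig(user$seed), user)
}

validateRunConfig <- function(config) {
  stopIfNot(is.list(config), "config must be a list")
  stopIfNot(!is.null(config$seed) && is.finite(as.numeric(config$seed)),
            "config validation: a master 'seed' is mandatory")
  invisible(config)
}

configGrid <- function(config) {
  g <- config$grid
  gridSpec(g$lat_origin, g$lon_origin, g$cell_size, g$n_rows, g$n_cols)
}

#' Run the full synthetic modelling pipeline
#'
#' Executes simulate, delineate, background, fit and evaluate in order,
#' writing every stage's outputs (ASCII-grid rasters, CSV tables, YAML
#' windows, JSON models) under `outDir`, plus a `manifest.json` recording
#' the configuration, derived sub-seeds, per-stage status and an MD5
#' checksum of every output file. Re-running with the same configuration
#' reproduces all numeric outputs exactly. A stage failure aborts the run
#' with the stage name.
#'
#' @param config configuration list (see [defaultRunConfig()]) or the path
#'   to a YAML file for [readRunConfig()].
#' @param outDir output directory, created if needed.
#' @return The manifest, invisibly.
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config)) config <- readRunConfig(config)
  validateRunConfig(config)
  config <- utils::modifyList(defaultRunConfig(config$seed), config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  seeds <- list(simulate = deriveSeed(config$seed, 1),
                records = deriveSeed(config$seed, 2),
                background = deriveSeed(config$seed, 3),
                fit = deriveSeed(config$seed, 4),
                evaluate = deriveSeed(config$seed, 5))
  status <- list()
  runStage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error"))
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(res)),
           call. = FALSE)
    status[[name]] <<- "ok"
    res
  }
  grid <- configGrid(config)

  # --- simulate -----------------------------------------------------------
  sim <- runStage("simulate", function() {
    stack <- generateLandscape(seeds$simulate, grid)
    niches <- defaultNiches(unlist(config$species$dwtScales))
    effort <- defaultEffort(grid, nStations = config$effort$nStations,
                            stationSd = config$effort$stationSd,
                            nBanding = config$effort$nBanding,
                            seed = deriveSeed(config$seed, 6))
    years <- seq(config$years[1], config$years[2])
    records <- simulateBandingRecords(niches, effort, stack,
                                      seed = seeds$records, years = years)
    covDir <- file.path(outDir, "covariates")
    dir.create(covDir, showWarnings = FALSE)
    for (nm in names(stack@layers))
      writeAsciiGrid(stack@layers[[nm]], file.path(covDir, paste0(nm, ".asc")))
    writeGridSpec(grid, file.path(outDir, "grid.json"))
    writeRecords(records, file.path(outDir, "records.csv"))
    truth <- lapply(niches, function(nc) list(
      dwtScale = nc@dwtScale, tempOpt = nc@tempOpt,
      migrationWeeks = nc@migrationWeeks,
      baseVelocity = nc@baseVelocity,
      migrationVelocity = nc@migrationVelocity))
    yaml::write_yaml(truth, file.path(outDir, "truth.yaml"))
    list(stack = stack, niches = niches, records = records)
  })

  # --- delineate ----------------------------------------------------------
  windows <- runStage("delineate", function() {
    dir.create(file.path(outDir, "seasons"), showWarnings = FALSE)
    pairs <- pairedRecoveries(sim$records)
    out <- list()
    weekly <- list()
    for (sp in names(sim$niches)) {
      vel <- dailyVelocity(pairs[pairs$species == sp, , drop = FALSE], grid)
      series <- weeklyMeanSeries(vel)
      prior <- trueSeasonWindows(sim$niches[[sp]])
      w <- if (identical(config$seasonSource, "detect"))
        detectMigrationWindows(series, prior) else prior
      writeSeasonWindows(w, file.path(outDir, "seasons", paste0(sp, ".yaml")))
      weekly[[sp]] <- data.frame(species = sp, week = 0:51,
                                 km_per_day = series@values,
                                 n = series@counts)
      out[[sp]] <- w
    }
    utils::write.csv(do.call(rbind, weekly),
                     file.path(outDir, "seasons", "weekly_velocity.csv"),
                     row.names = FALSE)
    out
  })

  # --- background ---------------------------------------------------------
  occ <- runStage("background", function() {
    focal <- config$focal
    season <- config$season
    pres <- presenceCells(sim$records, focal, season, windows[[focal]])
    cand <- targetGroupBackground(sim$records, focal, season, windows, grid)
    ctrP <- cellCenter(pres$row, pres$col, grid)
    ctrB <- cellCenter(cand$row, cand$col, grid)
    tab <- rbind(
      data.frame(species = focal, season = season, role = "presence",
                 row = pres$row, col = pres$col, lat = ctrP$lat, lon = ctrP$lon),
      data.frame(species = focal, season = season, role = "background",
                 row = cand$row, col = cand$col, lat = ctrB$lat, lon = ctrB$lon))
    utils::write.csv(tab, file.path(outDir, "background.csv"), row.names = FALSE)
    list(presences = pres, candidates = cand)
  })

  # --- fit ----------------------------------------------------------------
  fits <- runStage("fit", function() {
    sets <- config$model$covariateSets
    out <- list()
    for (nm in names(sets)) {
      out[[nm]] <- replicateFit(
        occ$presences, occ$candidates, sim$stack, unlist(sets[[nm]]),
        nRuns = config$model$nRuns, trainFrac = config$model$trainFrac,
        nBackground = min(config$model$nBackground, nrow(occ$candidates)),
        seed = seeds$fit, classes = config$model$classes,
        betaMultiplier = config$model$betaMultiplier)
    }
    aucTab <- do.call(rbind, lapply(names(out), function(nm)
      cbind(model = nm, out[[nm]])))
    utils::write.csv(aucTab, file.path(outDir, "auc_replicates.csv"),
                     row.names = FALSE)
    # full-data fit of the richest covariate set for the map and response curve
    full <- names(sets)[length(sets)]
    bg <- sampleBackground(occ$candidates,
                           min(config$model$nBackground, nrow(occ$candidates)),
                           seed = deriveSeed(config$seed, 7))
    model <- fitMaxent(covMatrix(sim$stack, unlist(sets[[full]]), occ$presences),
                       covMatrix(sim$stack, unlist(sets[[full]]), bg),
                       classes = config$model$classes,
                       betaMultiplier = config$model$betaMultiplier)
    writeMaxentModel(model, file.path(outDir, "model_full.json"))
    surface <- predictSurface(model, sim$stack)
    writeAsciiGrid(surface, file.path(outDir, "prediction.asc"))
    list(auc = out, model = model, surface = surface)
  })

  # --- evaluate -----------------------------------------------------------
  runStage("evaluate", function() {
    covNames <- unlist(config$model$covariateSets[[length(config$model$covariateSets)]])
    bg <- sampleBackground(occ$candidates,
                           min(config$model$nBackground, nrow(occ$candidates)),
                           seed = deriveSeed(config$seed, 8))
    cells <- rbind(occ$presences, bg)
    dat <- as.data.frame(covMatrix(sim$stack, covNames, cells))
    y <- rep(c(1L, 0L), c(nrow(occ$presences), nrow(bg)))
    forest <- fitBaggedTrees(dat, y, nTrees = config$forest$nTrees,
                             seed = seeds$evaluate)
    imp <- importanceTable(forest, dat, seed = deriveSeed(config$seed, 9))
    imp <- cbind(species = config$focal, season = config$season, imp)
    utils::write.csv(imp, file.path(outDir, "importance.csv"), row.names = FALSE)

    curve <- responseCurve(fits$surface, covLayer(sim$stack, "dwt"),
                           n = config$response$n, nBins = config$response$nBins,
                           seed = deriveSeed(config$seed, 10))
    utils::write.csv(
      data.frame(bin_center = curve@binCenters, bin_mean = curve@binMeans),
      file.path(outDir, "response_bins.csv"), row.names = FALSE)
    utils::write.csv(
      data.frame(dwt = curve@splineX, probability = curve@splineY),
      file.path(outDir, "response_spline.csv"), row.names = FALSE)

    cmp <- if (length(fits$auc) >= 2)
      compareModels(fits$auc[[2]]$auc, fits$auc[[1]]$auc) else NULL
    jsonlite::write_json(
      list(comparison = cmp,
           meanAuc = lapply(fits$auc, function(a) mean(a$auc, na.rm = TRUE))),
      file.path(outDir, "evaluation.json"), auto_unbox = TRUE, digits = NA)
    invisible(NULL)
  })

  # --- manifest -----------------------------------------------------------
  files <- sort(setdiff(list.files(outDir, recursive = TRUE),
                        "manifest.json"))
  checksums <- as.list(tools::md5sum(file.path(outDir, files)))
  names(checksums) <- files
  manifest <- list(
    package = "hydrofowl",
    version = as.character(utils::packageVersion("hydrofowl")),
    config = config,
    subSeeds = seeds,
    stages = status,
    checksums = checksums)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
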