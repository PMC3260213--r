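# background_points module: target-group pseudo-absences — locations of the
# other study species where the focal species was not recorded, so the
# background carries the same survey-effort bias as the presences.

#' Presence cells of a species in a season
#'
#' Unique grid cells of all events (banding and recovery alike) of the
#' species whose date falls in the given season window; a cell counts once
#' regardless of how many events it holds.
#'
#' @param records record data.frame with derived cells.
#' @param species focal species code.
#' @param season one of `spring`, `summer`, `fall`, `winter`.
#' @param windows the species' [SeasonWindows-class].
#' @return data.frame of 0-based `row`, `col`, one row per distinct cell.
#' @export
presenceCells <- function(records, species, season, windows) {
  validateRecords(records)
  stopIfNot(all(c("row", "col") %in% names(records)),
            "records must carry derived cells; see binRecords()")
  sub <- records[records$species == species, , drop = FALSE]
  sub <- sub[assignSeason(sub$date, windows) == season, , drop = FALSE]
  if (nrow(sub) == 0) {
    warning(sprintf("no %s events for %s in the %s window", species, species,
                    season), call. = FALSE)
    return(data.frame(row = integer(), col = integer()))
  }
  cells <- unique(sub[, c("row", "col")])
  cells <- cells[order(cells$row, cells$col), , drop = FALSE]
  rownames(cells) <- NULL
  cells
}

#' Target-group background cells
#'
#' Known locations of the other study species — each evaluated in its *own*
#' season window for the given season label — minus the focal species'
#' presence cells in the focal window. Errors when the candidate set is
#' empty (broader data are needed).
#'
#' @param records record data.frame with derived cells.
#' @param focal focal species code.
#' @param season season label.
#' @param windowsBySpecies named list of [SeasonWindows-class], one per
#'   species present in `records` (species-specific calendars).
#' @param grid the [GridSpec-class] records are binned to.
#' @return data.frame of 0-based `row`, `col` background candidate cells.
#' @export
targetGroupBackground <- function(records, focal, season, windowsBySpecies,
                                  grid) {
  others <- setdiff(unique(records$species), focal)
  stopIfNot(length(others) >= 1,
            "target-group backgrounds need at least one non-focal species")
  otherCells <- lapply(others, function(sp) {
    presenceCells(records, sp, season, windowsBySpecies[[sp]])
  })
  cand <- unique(do.call(rbind, otherCells))
  focalCells <- presenceCells(records, focal, season, windowsBySpecies[[focal]])
  candKey <- cellKey(cand$row, cand$col, grid)
  focalKey <- cellKey(focalCells$row, focalCells$col, grid)
  keep <- !(candKey %in% focalKey)
  if (!any(keep))
    stop(paste0("no target-group background cells remain for ", focal, " in ",
                season, "; broader data (more species or seasons) are needed"),
         call. = FALSE)
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out$row, out$col), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sample background cells
#'
#' Uniform sample without replacement from the candidate set; deterministic
#' given `seed`. When `n` exceeds the candidate count the full set is
#' returned with a warning.
#'
#' @param candidates data.frame of `row`, `col` candidate cells.
#' @param n number of background cells (> 0).
#' @param seed integer seed.
#' @return data.frame of sampled `row`, `col`.
#' @export
sampleBackground <- function(candidates, n, seed) {
  stopIfNot(n > 0, "n must be positive")
  set.seed(seed)
  if (n >= nrow(candidates)) {
    if (n > nrow(candidates))
      warning(sprintf("requested %d background cells but only %d candidates; using all",
                      n, nrow(candidates)), call. = FALSE)
    return(candidates)
  }
  out <- candidates[sample.int(nrow(candidates), n), , drop = FALSE]
  rownames(out) <- NULL
  out
}
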