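#' Reference library of true emission spectra
#'
#' Builds a [SpectralLibrary-class] directly from the catalog's Gaussian
#' emission models -- the "true normalized references" used when evaluating
#' the pipeline on synthetic scenes, where the pure-dye recording step can
#' be bypassed.
#'
#' @param dyes catalog names.
#' @param grid a [WavelengthGrid-class].
#' @param background optional background [Spectrum-class].
#' @return a [SpectralLibrary-class].
#' @export
trueLibrary <- function(dyes, grid = wavelengthGrid(), background = NULL) {
  cat_ <- fluorophoreCatalog()
  unknown <- setdiff(dyes, names(cat_))
  if (length(unknown))
    sqStop("sqValidation", "unknown catalog dye(s): %s",
           paste(unknown, collapse = ", "))
  spectralLibrary(stats::setNames(
    lapply(dyes, function(d) emissionSpectrum(cat_[[d]], grid)), dyes),
    background = background)
}

#' Bead reproducibility experiment
#'
#' The full calibration protocol on one synthetic bead field: simulate
#' replicate four-bead images (independent shot noise, small stage
#' translations), push each through interferometric acquisition and
#' spectral un-mixing against the true normalized bead references, quantify
#' each bead over its ground-truth pixel set, and summarize the per-bead
#' coefficients of variation of total fluorescence across replicates.
#'
#' @param seed RNG seed.
#' @param nReplicates replicate images (default 9).
#' @param beads four catalog bead names.
#' @param peakCounts per-pixel bead signal, counts.
#' @param noise a [NoiseModel-class] applied to the rendered cubes.
#' @param schedule an [OPDSchedule-class]; `NULL` skips the acquisition
#'   step (direct-path bypass).
#' @param mode un-mixing mode.
#' @return the [replicateStats()] list, plus elements `avgCv` (mean
#'   per-bead CV of total fluorescence, percent) and `cvs` (per-bead CVs).
#' @export
beadReproducibility <- function(seed = 1L, nReplicates = 9L,
                                beads = c("bead.green", "bead.orange",
                                          "bead.red", "bead.deepred"),
                                peakCounts = 5000,
                                noise = noiseModel("shot"),
                                schedule = opdSchedule(),
                                mode = "clamp") {
  reps <- makeBeadPanel(nReplicates, noise = noise, seed = seed,
                        beads = beads, peakCounts = peakCounts)
  lib <- trueLibrary(beads)
  reports <- lapply(reps, function(rp) {
    cube <- rp$cube
    if (!is.null(schedule)) cube <- acquireCube(cube, schedule)
    am <- unmixCube(cube, lib, mode = mode)
    cellProfiles(am, truthRois(rp$truth))
  })
  st <- replicateStats(reports)
  st$avgCv <- st$cvMean
  st$cvs <- stats::setNames(st$perObject$cv_pct, st$perObject$label)
  st
}

## Map segmented cell ROIs onto ground-truth objects: each truth object is
## matched to the segmented ROI covering the largest share of its pixels.
## Returns indices into `segRois` (NA when nothing overlaps).
mapSegmentsToTruth <- function(segRois, truth, height, width) {
  segLab <- matrix(0L, height, width)
  for (i in seq_along(segRois))
    segLab[roiIndices(segRois[[i]], height, width)] <- i
  vapply(truthRois(truth), function(r) {
    hits <- segLab[roiIndices(r, height, width)]
    hits <- hits[hits > 0L]
    if (!length(hits)) NA_integer_
    else as.integer(names(which.max(table(hits))))
  }, integer(1))
}

#' Rare-cell detection experiment
#'
#' One full pipeline run on a synthetic 1-in-`nCells` rare-cell mixture:
#' simulate, acquire interferometrically, un-mix, segment cells from the
#' DAPI image, quantify per-cell dye totals and flag rare candidates with
#' [detectRare()]. Reports whether the true rare cell was flagged and how
#' many majority cells were flagged along with it.
#'
#' @param seed RNG seed.
#' @param elevation true percent elevation of the rare cells' target-dye
#'   mean.
#' @param threshold [detectRare()] elevation threshold, percent.
#' @param nCells number of cells.
#' @param rareFraction rare proportion (default 1/100).
#' @param cellCv per-cell log-normal CV (fraction).
#' @param targetDye elevated dye.
#' @param schedule an [OPDSchedule-class]; `NULL` bypasses acquisition.
#' @param noise a [NoiseModel-class] for the rendered scene.
#' @param ... further arguments to [makeCellMixture()].
#' @return list: `hit` (logical, true rare cell flagged), `falsePositives`
#'   (count), `nSegmented`, `flagged` (labels).
#' @export
rareCellRun <- function(seed, elevation = 50, threshold = 50, nCells = 100L,
                        rareFraction = 0.01, cellCv = 0.1,
                        targetDye = "FITC", schedule = opdSchedule(),
                        noise = noiseModel("shot"), ...) {
  mix <- makeCellMixture(nCells = nCells, rareFraction = rareFraction,
                         rareElevation = elevation, targetDye = targetDye,
                         cellCv = cellCv, noise = noise, seed = seed, ...)
  cube <- mix$cube
  if (!is.null(schedule)) cube <- acquireCube(cube, schedule)
  dyes <- colnames(truthTotals(mix$truth))
  lib <- trueLibrary(dyes, grid = wlGrid(cube))
  am <- unmixCube(cube, lib)
  segs <- segmentCells(mix$dapi)
  if (!length(segs))
    return(list(hit = FALSE, falsePositives = 0L, nSegmented = 0L,
                flagged = character(0)))
  d <- dim(cube@values)
  mapIdx <- mapSegmentsToTruth(segs, mix$truth, d[1L], d[2L])
  profiles <- cellProfiles(am, segs)
  flagged <- detectRare(profiles, targetDye, threshold)
  segLabels <- vapply(segs, roiLabel, character(1))
  rareTruth <- which(truthPopulations(mix$truth) == "rare")
  rareSeg <- segLabels[mapIdx[rareTruth]]
  hit <- length(rareTruth) > 0L && !anyNA(rareSeg) && all(rareSeg %in% flagged)
  list(hit = hit, falsePositives = length(setdiff(flagged, rareSeg)),
       nSegmented = length(segs), flagged = flagged)
}
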