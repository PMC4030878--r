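#' Construct a noise model
#'
#' @param kind `"none"`, `"shot"` (Poisson counting noise) or `"shot+read"`
#'   (Poisson plus zero-mean Gaussian read noise).
#' @param readSd read-noise standard deviation, counts.
#' @return a [NoiseModel-class].
#' @export
noiseModel <- function(kind = c("none", "shot", "shot+read"), readSd = 0) {
  new("NoiseModel", kind = match.arg(kind), readSd = as.numeric(readSd))
}

setMethod("show", "NoiseModel", function(object) {
  cat(sprintf("NoiseModel: %s%s\n", object@kind,
              if (object@kind == "shot+read")
                sprintf(" (read sd %g counts)", object@readSd) else ""))
})

#' Apply acquisition noise to expected intensities
#'
#' Shot noise replaces each expected value by a Poisson draw; read noise adds
#' zero-mean Gaussian counts. Results are clamped at zero (a camera reports
#' nonnegative counts). Draws come from the current RNG stream; seed control
#' belongs to the caller.
#'
#' @param x numeric vector, matrix or array of expected counts (>= 0).
#' @param model a [NoiseModel-class].
#' @return object of the same shape as `x`.
#' @export
applyNoise <- function(x, model) {
  if (model@kind == "none") return(x)
  d <- dim(x)
  y <- stats::rpois(length(x), lambda = as.numeric(x))
  if (model@kind == "shot+read" && model@readSd > 0)
    y <- y + stats::rnorm(length(x), sd = model@readSd)
  y <- pmax(y, 0)
  dim(y) <- d
  y
}

## Run code under a fixed seed, restoring the caller's RNG state after.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
  }
  expr
}

#' Scene objects: uniform bead disks and nucleus+cytoplasm cells
#'
#' `diskObject()` describes a uniformly bright disk (a calibration bead);
#' `cellObject()` a cell modeled as a cytoplasm disk carrying the transcript
#' signal with a concentric nucleus disk that appears (with `dapiCounts`
#' brightness) only in the separately recorded DAPI reference image.
#'
#' @param center numeric `(row, col)` center, pixels.
#' @param radiusPx disk (for cells: cytoplasm) radius, pixels (> 0).
#' @param brightness named numeric vector of per-fluorophore per-pixel
#'   amplitudes, counts: each in-object pixel contributes
#'   `brightness * emissionSpectrum` to the cube, so `brightness` is the
#'   pixel's total counts from that dye.
#' @param label object label used in the ground truth.
#' @param population population tag carried into the ground truth.
#' @param nucleusRadiusPx nucleus radius, pixels.
#' @param dapiCounts nucleus brightness in the DAPI image, counts per pixel.
#' @return a list understood by [renderScene()].
#' @export
diskObject <- function(center, radiusPx, brightness, label = NULL,
                       population = "majority") {
  stopifnot(length(center) == 2L, radiusPx > 0, all(brightness >= 0),
            !is.null(names(brightness)))
  list(shape = "disk", center = as.numeric(center),
       radiusPx = as.numeric(radiusPx), brightness = brightness,
       label = label, population = population)
}

#' @rdname diskObject
#' @export
cellObject <- function(center, radiusPx, nucleusRadiusPx, brightness,
                       dapiCounts = 3000, label = NULL,
                       population = "majority") {
  stopifnot(nucleusRadiusPx > 0, nucleusRadiusPx <= radiusPx,
            dapiCounts >= 0)
  obj <- diskObject(center, radiusPx, brightness, label, population)
  obj$shape <- "cell"
  obj$nucleusRadiusPx <- as.numeric(nucleusRadiusPx)
  obj$dapiCounts <- as.numeric(dapiCounts)
  obj
}

#' Construct a scene specification
#'
#' @param height,width image size, pixels.
#' @param objects list of [diskObject()] / [cellObject()] descriptions.
#' @param panel named list of [FluorophoreModel-class] covering every dye
#'   named in the objects' brightness vectors (default: the full catalog).
#' @param backgroundLevel flat background in total counts per pixel, spread
#'   evenly over bands.
#' @param autofluorescence optional broad [Spectrum-class] added at every
#'   pixel (absolute counts).
#' @param noise a [NoiseModel-class].
#' @param bleachRate per-band-step fractional photobleaching decay in
#'   `[0, 1)`; default 0 (off).
#' @param seed RNG seed used when rendering with noise.
#' @param grid a [WavelengthGrid-class].
#' @return a [SceneSpec-class].
#' @export
sceneSpec <- function(height, width, objects, panel = fluorophoreCatalog(),
                      backgroundLevel = 0, autofluorescence = NULL,
                      noise = noiseModel("none"), bleachRate = 0, seed = 1,
                      grid = wavelengthGrid()) {
  new("SceneSpec", height = as.integer(height), width = as.integer(width),
      grid = grid, panel = panel, objects = objects,
      backgroundLevel = as.numeric(backgroundLevel),
      autofluorescence = autofluorescence, noise = noise,
      bleachRate = as.numeric(bleachRate), seed = as.numeric(seed))
}

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf("SceneSpec: %dx%d px, %d objects, background %g, noise %s%s\n",
              object@height, object@width, length(object@objects),
              object@backgroundLevel, object@noise@kind,
              if (object@bleachRate > 0)
                sprintf(", bleach %g/band", object@bleachRate) else ""))
})

## Pixel linear indices (column-major) of a disk clipped to the image;
## errors if the disk lies fully outside.
diskIndices <- function(center, radius, height, width, what = "object") {
  r0 <- max(1L, floor(center[1L] - radius))
  r1 <- min(height, ceiling(center[1L] + radius))
  c0 <- max(1L, floor(center[2L] - radius))
  c1 <- min(width, ceiling(center[2L] + radius))
  if (r0 > r1 || c0 > c1)
    sqStop("sqSceneError", "%s at (%g, %g) lies outside the %dx%d image",
           what, center[1L], center[2L], height, width)
  rows <- r0:r1; cols <- c0:c1
  dr <- outer(rows - center[1L], rep(1, length(cols)))
  dc <- outer(rep(1, length(rows)), cols - center[2L])
  keep <- which(dr^2 + dc^2 <= radius^2)
  if (!length(keep))
    sqStop("sqSceneError", "%s at (%g, %g) covers no pixel of the %dx%d image",
           what, center[1L], center[2L], height, width)
  rr <- rows[(keep - 1L) %% length(rows) + 1L]
  cc <- cols[(keep - 1L) %/% length(rows) + 1L]
  cbind(row = rr, col = cc)
}

#' @rdname renderScene
setMethod("truthRois", "GroundTruth", function(x) x@rois)
#' @rdname renderScene
setMethod("truthTotals", "GroundTruth", function(x) x@totals)
#' @rdname renderScene
setMethod("truthPopulations", "GroundTruth", function(x) x@populations)

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d objects x %d fluorophores (%s)\n",
              nrow(object@totals), ncol(object@totals),
              paste(unique(object@populations), collapse = ", ")))
})

#' Render a synthetic scene into a spectral cube with ground truth
#'
#' The noiseless signal at pixel p is
#' `background + autofluorescence(p) + sum over objects and dyes of
#' brightness x emission spectrum`; photobleaching (geometric per-band decay
#' in band order, modeling signal fading over the band-sequential recording
#' of a full spectrum) and then noise are applied on top. Ground-truth totals
#' are the noiseless, pre-bleach per-object sums, recorded per object even
#' where objects overlap. Cells additionally produce a separately "recorded"
#' DAPI nucleus image (same noise model), mirroring the DAPI reference
#' channel acquired through its own filter set.
#'
#' @param spec a [SceneSpec-class].
#' @return list with elements `cube` ([SpectralCube-class]), `truth`
#'   ([GroundTruth-class]) and `dapi` (height x width matrix; all zero when
#'   the scene has no cells).
#' @examples
#' fl <- fluorophoreCatalog()
#' sc <- sceneSpec(32, 32, list(
#'   diskObject(c(16, 16), 5, c(FITC = 1000))), panel = fl["FITC"])
#' out <- renderScene(sc)
#' truthTotals(out$truth)
#' @export
renderScene <- function(spec) {
  H <- spec@height; W <- spec@width
  B <- nBands(spec@grid)
  dyes <- names(spec@panel)
  E <- vapply(spec@panel, function(m)
    emissionSpectrum(m, spec@grid)@intensity, numeric(B))  # B x nDyes
  amp <- matrix(0, H * W, length(dyes), dimnames = list(NULL, dyes))
  dapi <- matrix(0, H, W)
  nObj <- length(spec@objects)
  rois <- vector("list", nObj)
  totals <- matrix(0, nObj, length(dyes), dimnames = list(NULL, dyes))
  pops <- character(nObj)
  labs <- character(nObj)
  for (i in seq_len(nObj)) {
    ob <- spec@objects[[i]]
    co <- diskIndices(ob$center, ob$radiusPx, H, W,
                      what = if (is.null(ob$label)) sprintf("object %d", i)
                             else ob$label)
    idx <- (co[, 2L] - 1L) * H + co[, 1L]
    bn <- ob$brightness
    unknown <- setdiff(names(bn), dyes)
    if (length(unknown))
      sqStop("sqSceneError", "object %d uses fluorophores absent from the panel: %s",
             i, paste(unknown, collapse = ", "))
    for (d in names(bn)) {
      amp[idx, d] <- amp[idx, d] + bn[[d]]
      totals[i, d] <- bn[[d]] * length(idx)
    }
    if (identical(ob$shape, "cell")) {
      nco <- diskIndices(ob$center, ob$nucleusRadiusPx, H, W, "nucleus")
      dapi[(nco[, 2L] - 1L) * H + nco[, 1L]] <-
        dapi[(nco[, 2L] - 1L) * H + nco[, 1L]] + ob$dapiCounts
    }
    labs[i] <- if (is.null(ob$label)) sprintf("obj%d", i) else ob$label
    pops[i] <- ob$population
    rois[[i]] <- roi(co, labs[i])
  }
  S <- amp %*% t(E)                                  # pixels x bands
  if (spec@backgroundLevel > 0)
    S <- S + spec@backgroundLevel / B
  if (!is.null(spec@autofluorescence)) {
    stopIfGridMismatch(spec@autofluorescence@grid, spec@grid,
                       "autofluorescence and scene")
    S <- sweep(S, 2L, spec@autofluorescence@intensity, "+")
  }
  if (spec@bleachRate > 0)
    S <- sweep(S, 2L, (1 - spec@bleachRate)^(seq_len(B) - 1L), "*")
  if (spec@noise@kind != "none") {
    withSeed(spec@seed, {
      S <- applyNoise(S, spec@noise)
      dapi <- applyNoise(dapi, spec@noise)
    })
  }
  rownames(totals) <- labs
  truth <- new("GroundTruth", rois = rois, totals = totals,
               populations = pops)
  list(cube = unflattenCube(S, H, W, spec@grid), truth = truth, dapi = dapi)
}

#' Simulate replicate images of a four-bead calibration field
#'
#' Emulates the reproducibility protocol in which the same field of
#' calibration beads is re-recorded after manually repositioning the stage:
#' one fixed four-bead layout (2.5 um beads, about 8 px diameter) is rendered
#' `nReplicates` times with independent noise realizations and a small random
#' whole-field translation (at most `jitterPx` pixels per axis) per
#' replicate.
#'
#' @param nReplicates number of replicate images (>= 1; the modeled
#'   experiment analyzed nine).
#' @param noise a [NoiseModel-class].
#' @param seed RNG seed; replicate r uses `seed + r - 1`.
#' @param beads catalog names of the four bead colors.
#' @param peakCounts per-pixel total signal of each bead, counts. The
#'   default 5000 reflects a realistic peak signal for these standards.
#' @param radiusPx bead radius, pixels.
#' @param jitterPx maximum stage-repositioning translation per axis, pixels.
#' @param height,width image size.
#' @param grid a [WavelengthGrid-class].
#' @return list of `nReplicates` elements, each a `list(cube, truth, dapi)`
#'   as returned by [renderScene()].
#' @examples
#' reps <- makeBeadPanel(2, noiseModel("none"), seed = 1)
#' truthTotals(reps[[1]]$truth)
#' @export
makeBeadPanel <- function(nReplicates = 9L, noise = noiseModel("shot"),
                          seed = 1L,
                          beads = c("bead.green", "bead.orange",
                                    "bead.red", "bead.deepred"),
                          peakCounts = 5000, radiusPx = 4, jitterPx = 2,
                          height = 64L, width = 64L,
                          grid = wavelengthGrid()) {
  stopifnot(nReplicates >= 1L)
  panel <- fluorophoreCatalog()[beads]
  if (anyNA(names(panel)))
    sqStop("sqSceneError", "unknown bead name(s): %s",
           paste(setdiff(beads, names(fluorophoreCatalog())), collapse = ", "))
  base <- cbind(rep(c(0.3, 0.7), each = 2L) * height,
                rep(c(0.3, 0.7), times = 2L) * width)
  if (length(peakCounts) == 1L) peakCounts <- rep(peakCounts, length(beads))
  lapply(seq_len(nReplicates), function(r) {
    shift <- withSeed(seed + r - 1L,
                      sample(-jitterPx:jitterPx, 2L, replace = TRUE))
    objs <- lapply(seq_along(beads), function(i) {
      br <- stats::setNames(peakCounts[i], beads[i])
      diskObject(base[i, ] + shift, radiusPx, br,
                 label = sprintf("bead%d", i), population = "bead")
    })
    sc <- sceneSpec(height, width, objs, panel = panel, noise = noise,
                    seed = seed * 1000L + r, grid = grid)
    renderScene(sc)
  })
}

#' Simulate a two-population cell mixture with a rare subpopulation
#'
#' Cells are laid out on a jittered grid as cytoplasm disks with DAPI
#' nuclei. Exactly `round(nCells * rareFraction)` cells (deterministic
#' rounding) belong to the rare population, whose mean amplitude for
#' `targetDye` is the majority mean multiplied by `1 + rareElevation/100`
#' (applied on top of `rareMeans` if population baselines differ). Per-cell,
#' per-dye amplitudes are drawn log-normally around the population means with
#' coefficient of variation `cellCv`, emulating cell-cycle-dependent
#' expression variability.
#'
#' @param nCells number of cells (> 0).
#' @param rareFraction proportion of rare cells in `[0, 1]`.
#' @param rareElevation percent elevation of the rare population's
#'   `targetDye` mean above its baseline (>= 0).
#' @param panel named list of [FluorophoreModel-class] (default: the six-dye
#'   transcript panel FITC, Cy3, Cy3.5, Texas Red, Cy5, Cy5.5).
#' @param targetDye dye whose mean is elevated in rare cells.
#' @param majorityMeans named per-dye mean amplitudes (counts per pixel) of
#'   the majority population; default 800 counts per dye.
#' @param rareMeans rare-population baseline means before elevation; default
#'   equal to `majorityMeans` (populations then differ only through the
#'   elevation, and are exchangeable at `rareElevation = 0`).
#' @param cellCv per-cell log-normal coefficient of variation (fraction;
#'   default 0.2).
#' @param noise a [NoiseModel-class].
#' @param seed RNG seed (cell placement, population assignment, amplitude
#'   draws and rendering noise).
#' @param cellRadiusPx,nucleusRadiusPx cytoplasm and nucleus radii, pixels.
#' @param dapiCounts nucleus DAPI brightness, counts per pixel.
#' @param spacingPx cell-grid spacing, pixels.
#' @param jitterPx per-cell placement jitter, pixels.
#' @param grid a [WavelengthGrid-class].
#' @return `list(cube, truth, dapi)` as for [renderScene()]; population
#'   labels in the truth are `"majority"` / `"rare"`.
#' @examples
#' mix <- makeCellMixture(9, rareFraction = 1/9, rareElevation = 50,
#'                        noise = noiseModel("none"), seed = 2)
#' table(truthPopulations(mix$truth))
#' @export
makeCellMixture <- function(nCells = 100L, rareFraction = 0.01,
                            rareElevation = 50,
                            panel = fluorophoreCatalog()[c("FITC", "Cy3",
                              "Cy3.5", "TexasRed", "Cy5", "Cy5.5")],
                            targetDye = "FITC", majorityMeans = NULL,
                            rareMeans = NULL, cellCv = 0.2,
                            noise = noiseModel("shot"), seed = 1L,
                            cellRadiusPx = 5, nucleusRadiusPx = 3,
                            dapiCounts = 3000, spacingPx = 15L,
                            jitterPx = 2L, grid = wavelengthGrid()) {
  if (nCells < 1L)
    sqStop("sqEmptyScene", "a cell mixture needs at least one cell")
  stopifnot(rareFraction >= 0, rareFraction <= 1, rareElevation >= 0)
  dyes <- names(panel)
  if (!targetDye %in% dyes)
    sqStop("sqSceneError", "targetDye '%s' is not in the panel", targetDye)
  if (is.null(majorityMeans))
    majorityMeans <- stats::setNames(rep(800, length(dyes)), dyes)
  if (is.null(rareMeans)) rareMeans <- majorityMeans
  stopifnot(setequal(names(majorityMeans), dyes),
            setequal(names(rareMeans), dyes))
  rareMeans <- rareMeans[dyes]; majorityMeans <- majorityMeans[dyes]
  rareMeans[targetDye] <- rareMeans[targetDye] * (1 + rareElevation / 100)

  nRare <- round(nCells * rareFraction)
  ncols <- ceiling(sqrt(nCells))
  nrows <- ceiling(nCells / ncols)
  margin <- cellRadiusPx + jitterPx + 2L
  H <- as.integer((nrows - 1L) * spacingPx + 2L * margin)
  W <- as.integer((ncols - 1L) * spacingPx + 2L * margin)
  sdlog <- sqrt(log(1 + cellCv^2))
  objs <- withSeed(seed, {
    rare <- sample.int(nCells, nRare)
    lapply(seq_len(nCells), function(i) {
      gr <- (i - 1L) %/% ncols; gc <- (i - 1L) %% ncols
      ctr <- c(margin + gr * spacingPx, margin + gc * spacingPx) +
        if (jitterPx > 0) sample(-jitterPx:jitterPx, 2L, replace = TRUE)
        else c(0, 0)
      isRare <- i %in% rare
      mu <- if (isRare) rareMeans else majorityMeans
      amp <- if (cellCv > 0)
        stats::rlnorm(length(mu), meanlog = log(mu) - sdlog^2 / 2,
                      sdlog = sdlog)
      else as.numeric(mu)
      names(amp) <- dyes
      cellObject(ctr, cellRadiusPx, nucleusRadiusPx, amp,
                 dapiCounts = dapiCounts, label = sprintf("cell%03d", i),
                 population = if (isRare) "rare" else "majority")
    })
  })
  sc <- sceneSpec(H, W, objs, panel = panel, noise = noise,
                  seed = seed + 10000L, grid = grid)
  renderScene(sc)
}
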