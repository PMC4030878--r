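## File formats. Cubes travel as multi-page grayscale TIFF (one 32-bit
## page per band, shortest wavelength first) plus a JSON sidecar
## (<path>.json) carrying the wavelength grid and the intensity scale.
## Pages are stored divided by a power-of-two scale with headroom, so
## integer camera counts round trip bit-exactly and arbitrary reals to
## 32-bit relative precision, bit-stably after the first write.

sidecarPath <- function(path) paste0(path, ".json")

## Power-of-two intensity scale chosen so stored page values stay <= 0.5:
## the writer quantizes pages to 32-bit integers of the unit interval, and
## keeping a factor-of-two headroom means integer counts below 2^24 map to
## exact binary fractions and round trip bit-exactly.
pow2Scale <- function(mx) {
  if (!is.finite(mx) || mx <= 0) 1 else max(1, 2^(ceiling(log2(mx)) + 1))
}

## Encode a page of counts as 32-bit samples: quantize to k/2^32 (the
## reader's convention) with a half-sample offset so the result is exact
## whichever way the writer rounds its integer samples.
encodePage32 <- function(v, sc) {
  (round(v / sc * 2^32) + 0.5) / (2^32 - 1)
}

#' Read and write spectral cubes as multi-page TIFF
#'
#' `writeCube()` writes one 32-bit grayscale page per band (band 1 =
#' shortest wavelength) and a JSON sidecar `<path>.json` holding the
#' wavelength grid and the power-of-two intensity scale; `readCube()`
#' reverses it, erroring when the sidecar is missing or the page count
#' disagrees with the sidecar's band count. Integer camera counts round
#' trip bit-exactly; any cube is bit-stable from the first write on.
#'
#' @param cube a [SpectralCube-class].
#' @param path TIFF file path.
#' @return `readCube()`: a [SpectralCube-class]; `writeCube()`: the path,
#'   invisibly.
#' @export
writeCube <- function(cube, path) {
  d <- dim(cube@values)
  sc <- pow2Scale(max(cube@values))
  pages <- lapply(seq_len(d[3L]), function(b)
    encodePage32(cube@values[, , b], sc))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  jsonlite::write_json(list(start_nm = cube@grid@startNm,
                            stop_nm = cube@grid@stopNm,
                            n_bands = cube@grid@nBands,
                            scale = sc,
                            background_subtracted = cube@backgroundSubtracted),
                       sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCube
#' @export
readCube <- function(path) {
  sp <- sidecarPath(path)
  if (!file.exists(sp))
    sqStop("sqFormat", "no grid sidecar '%s' next to '%s'", sp, path)
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != meta$n_bands)
    sqStop("sqFormat", "'%s' has %d pages but the sidecar declares %d bands",
           path, length(pages), meta$n_bands)
  g <- wavelengthGrid(meta$start_nm, meta$stop_nm, meta$n_bands)
  H <- nrow(pages[[1L]]); W <- ncol(pages[[1L]])
  vals <- array(0, c(H, W, meta$n_bands))
  for (b in seq_along(pages)) vals[, , b] <- pages[[b]] * meta$scale
  new("SpectralCube", grid = g, values = vals,
      backgroundSubtracted = isTRUE(meta$background_subtracted))
}

#' Read and write single-channel reference images (DAPI)
#'
#' Single-page 32-bit TIFF with the same power-of-two scale sidecar
#' convention as [writeCube()].
#'
#' @param img numeric matrix.
#' @param path TIFF file path.
#' @export
writeImage2d <- function(img, path) {
  sc <- pow2Scale(max(img))
  tiff::writeTIFF(encodePage32(img, sc), path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  jsonlite::write_json(list(scale = sc), sidecarPath(path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeImage2d
#' @export
readImage2d <- function(path) {
  sc <- 1
  if (file.exists(sidecarPath(path)))
    sc <- jsonlite::read_json(sidecarPath(path), simplifyVector = TRUE)$scale
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img * sc
}

#' Read and write spectral libraries as JSON
#'
#' Structured text: the wavelength grid, the named entries (per-band
#' normalized values) and the optional background spectrum. Reading
#' validates the at-most-nine-entries rule.
#'
#' @param library a [SpectralLibrary-class].
#' @param path JSON file path.
#' @export
writeLibrary <- function(library, path) {
  g <- wlGrid(library)
  obj <- list(grid = list(start_nm = g@startNm, stop_nm = g@stopNm,
                          n_bands = g@nBands),
              entries = lapply(names(library@entries), function(nm)
                list(name = nm, values = library@entries[[nm]]@intensity)),
              background = if (is.null(library@background)) NULL
                           else library@background@intensity)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname writeLibrary
#' @export
readLibrary <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- wavelengthGrid(obj$grid$start_nm, obj$grid$stop_nm, obj$grid$n_bands)
  ents <- obj$entries
  if (is.data.frame(ents))
    ents <- lapply(seq_len(nrow(ents)), function(i)
      list(name = ents$name[i], values = ents$values[[i]]))
  if (length(ents) > 9L)
    sqStop("sqValidation",
           "library '%s' declares %d reference spectra; at most 9 are supported",
           path, length(ents))
  entries <- stats::setNames(
    lapply(ents, function(e) spectrum(e$values, g)),
    vapply(ents, function(e) e$name, character(1)))
  bg <- if (!is.null(obj$background) && length(obj$background))
    spectrum(obj$background, g) else NULL
  spectralLibrary(entries, background = bg)
}

#' Read and write ROI sets as JSON pixel-run lists
#'
#' Each ROI is stored as its label plus row-wise pixel runs
#' `[row, col_start, length]`, a compact plain-text representation.
#'
#' @param rois list of [ROI-class].
#' @param path JSON file path.
#' @export
writeRois <- function(rois, path) {
  enc <- lapply(rois, function(r) {
    co <- roiCoords(r)
    co <- co[order(co[, 1L], co[, 2L]), , drop = FALSE]
    runs <- list()
    i <- 1L
    while (i <= nrow(co)) {
      j <- i
      while (j < nrow(co) && co[j + 1L, 1L] == co[j, 1L] &&
             co[j + 1L, 2L] == co[j, 2L] + 1L) j <- j + 1L
      runs[[length(runs) + 1L]] <- c(co[i, 1L], co[i, 2L], j - i + 1L)
      i <- j + 1L
    }
    list(label = roiLabel(r), runs = runs)
  })
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeRois
#' @export
readRois <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(obj, function(r) {
    co <- do.call(rbind, lapply(r$runs, function(run) {
      run <- as.integer(unlist(run))
      cbind(run[1L], run[2L] + seq_len(run[3L]) - 1L)
    }))
    roi(co, label = r$label)
  })
}

#' Write ROIs as a 16-bit label image
#'
#' Pixel value 0 is background; ROI i (list order) gets label i.
#'
#' @param rois list of [ROI-class].
#' @param height,width image size.
#' @param path TIFF path.
#' @export
writeLabelImage <- function(rois, height, width, path) {
  lab <- matrix(0L, height, width)
  for (i in seq_along(rois)) {
    idx <- roiIndices(rois[[i]], height, width)
    lab[idx] <- i
  }
  ## half-offset keeps the 16-bit quantization exact whichever way the
  ## writer rounds
  tiff::writeTIFF((lab + 0.5) / 65535, path, bits.per.sample = 16L,
                  compression = "none", reduce = FALSE)
  invisible(path)
}

#' @rdname writeLabelImage
#' @export
readLabelImage <- function(path) {
  img <- tiff::readTIFF(path)
  floor(img * 65535 + 0.5)
}

#' Write an abundance map as TIFF pages plus a CSV summary
#'
#' One 32-bit float page per library entry plus a final residual page, with
#' the entry names in the JSON sidecar; the CSV holds image-wide per-dye
#' totals.
#'
#' @param abundanceMap an [AbundanceMap-class].
#' @param path TIFF path; the summary goes to `<path>.csv`.
#' @export
writeAbundance <- function(abundanceMap, path) {
  d <- dim(abundanceMap@coef)
  mx <- max(max(abundanceMap@coef), max(abundanceMap@residual), 1)
  sc <- pow2Scale(mx)
  pages <- c(lapply(seq_len(d[3L]), function(k)
    encodePage32(abundanceMap@coef[, , k], sc)),
    list(encodePage32(abundanceMap@residual, sc)))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  jsonlite::write_json(list(entries = dimnames(abundanceMap@coef)[[3L]],
                            scale = sc),
                       sidecarPath(path), auto_unbox = TRUE, digits = NA)
  tot <- apply(abundanceMap@coef, 3L, sum)
  utils::write.csv(data.frame(dye = names(tot), total = as.numeric(tot)),
                   paste0(path, ".csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname writeAbundance
#' @export
readAbundance <- function(path) {
  meta <- jsonlite::read_json(sidecarPath(path), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  k <- length(meta$entries)
  H <- nrow(pages[[1L]]); W <- ncol(pages[[1L]])
  coef <- array(0, c(H, W, k), dimnames = list(NULL, NULL, meta$entries))
  for (i in seq_len(k)) coef[, , i] <- pages[[i]] * meta$scale
  new("AbundanceMap", coef = coef,
      residual = pages[[k + 1L]] * meta$scale,
      backgroundCoef = matrix(numeric(0), 0L, 0L))
}

#' Write an RGB pseudo-color render as PNG
#'
#' @param rgb integer array (height, width, 3), values 0-255, from
#'   [renderRgb()].
#' @param path PNG path.
#' @export
writeRgb <- function(rgb, path) {
  png::writePNG(rgb / 255, path)
  invisible(path)
}

#' Write a run manifest
#'
#' Every pipeline run records the exact configuration used, the seed and
#' the package/R versions, so outputs are reproducible byte-for-byte from
#' the manifest alone.
#'
#' @param dir output directory.
#' @param config named list echoed verbatim.
#' @param seed the run seed.
#' @export
writeManifest <- function(dir, config, seed) {
  jsonlite::write_json(
    list(config = config, seed = seed,
         package = as.character(utils::packageVersion("SpectraQuant")),
         r_version = as.character(getRversion()),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(file.path(dir, "manifest.json"))
}

#' Read a scene specification from JSON
#'
#' Plain-JSON serialization of [sceneSpec()]: image size, grid, noise,
#' background/bleach parameters, a fluorophore panel (catalog names or
#' explicit `name/excitation/emission/fwhm` records) and the object list.
#'
#' @param path JSON file path.
#' @return a [SceneSpec-class].
#' @export
readSceneSpec <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  g <- if (is.null(obj$grid)) wavelengthGrid()
       else wavelengthGrid(obj$grid$start_nm, obj$grid$stop_nm,
                           obj$grid$n_bands)
  panel <- if (is.null(obj$panel)) fluorophoreCatalog()
  else {
    ps <- lapply(obj$panel, function(p) {
      if (is.character(p)) fluorophoreCatalog()[[p]]
      else fluorophore(p$name, p$excitation_nm, p$emission_nm,
                       if (is.null(p$fwhm_nm)) 30 else p$fwhm_nm)
    })
    stats::setNames(ps, vapply(ps, function(p) p@name, character(1)))
  }
  objects <- lapply(obj$objects, function(o) {
    br <- unlist(o$brightness)
    ctr <- as.numeric(unlist(o$center))
    if (identical(o$shape, "cell"))
      cellObject(ctr, o$radius_px, o$nucleus_radius_px, br,
                 dapiCounts = if (is.null(o$dapi_counts)) 3000
                              else o$dapi_counts,
                 label = o$label,
                 population = if (is.null(o$population)) "majority"
                              else o$population)
    else
      diskObject(ctr, o$radius_px, br, label = o$label,
                 population = if (is.null(o$population)) "majority"
                              else o$population)
  })
  noise <- if (is.null(obj$noise)) noiseModel("none")
           else noiseModel(obj$noise$kind,
                           if (is.null(obj$noise$read_sd)) 0
                           else obj$noise$read_sd)
  sceneSpec(obj$height, obj$width, objects, panel = panel,
            backgroundLevel = if (is.null(obj$background_level)) 0
                              else obj$background_level,
            noise = noise,
            bleachRate = if (is.null(obj$bleach_rate)) 0 else obj$bleach_rate,
            seed = if (is.null(obj$seed)) 1 else obj$seed, grid = g)
}
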