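#' Construct a wavelength grid
#'
#' Band centers are evenly spaced from `startNm` to `stopNm` inclusive. The
#' default grid covers 450-800 nm in 36 bands (10 nm spacing), matching the
#' acquisition range and spectral resolution of the modeled instrument.
#'
#' @param startNm first band center, nm.
#' @param stopNm last band center, nm.
#' @param nBands number of bands.
#' @return a [WavelengthGrid-class].
#' @examples
#' g <- wavelengthGrid()
#' head(bandCenters(g))
#' @export
wavelengthGrid <- function(startNm = 450, stopNm = 800, nBands = 36L) {
  new("WavelengthGrid", startNm = as.numeric(startNm),
      stopNm = as.numeric(stopNm), nBands = as.integer(nBands))
}

## Exact grid equality: identical start/stop/nBands. Anything else requires
## an explicit resample, preventing silent band misalignment.
gridsIdentical <- function(a, b) {
  isTRUE(a@startNm == b@startNm && a@stopNm == b@stopNm &&
         a@nBands == b@nBands)
}

stopIfGridMismatch <- function(a, b, what = "inputs") {
  if (!gridsIdentical(a, b))
    sqStop("sqGridMismatch",
           "%s are on different wavelength grids (%g-%g/%d vs %g-%g/%d); resample explicitly",
           what, a@startNm, a@stopNm, a@nBands, b@startNm, b@stopNm, b@nBands)
  invisible(TRUE)
}

#' Band centers, band count and grid accessors
#'
#' `bandCenters()` returns the wavelength (nm) of each band center,
#' `nBands()` the number of bands and `wlGrid()` the [WavelengthGrid-class]
#' carried by a spectrum, cube or library.
#'
#' @param x a [WavelengthGrid-class], [Spectrum-class], [SpectralCube-class]
#'   or [SpectralLibrary-class].
#' @return `bandCenters()`: numeric vector (nm); `nBands()`: integer;
#'   `wlGrid()`: a [WavelengthGrid-class].
#' @name bandCenters
NULL

#' @rdname bandCenters
setMethod("bandCenters", "WavelengthGrid", function(x)
  seq(x@startNm, x@stopNm, length.out = x@nBands))
#' @rdname bandCenters
setMethod("bandCenters", "Spectrum", function(x) bandCenters(x@grid))
#' @rdname bandCenters
setMethod("bandCenters", "SpectralCube", function(x) bandCenters(x@grid))
#' @rdname bandCenters
setMethod("bandCenters", "SpectralLibrary", function(x)
  bandCenters(x@entries[[1L]]@grid))

#' @rdname bandCenters
setMethod("nBands", "WavelengthGrid", function(x) x@nBands)
#' @rdname bandCenters
setMethod("nBands", "Spectrum", function(x) x@grid@nBands)
#' @rdname bandCenters
setMethod("nBands", "SpectralCube", function(x) x@grid@nBands)
#' @rdname bandCenters
setMethod("nBands", "SpectralLibrary", function(x)
  x@entries[[1L]]@grid@nBands)

#' @rdname bandCenters
setMethod("wlGrid", "WavelengthGrid", function(x) x)
#' @rdname bandCenters
setMethod("wlGrid", "Spectrum", function(x) x@grid)
#' @rdname bandCenters
setMethod("wlGrid", "SpectralCube", function(x) x@grid)
#' @rdname bandCenters
setMethod("wlGrid", "SpectralLibrary", function(x) x@entries[[1L]]@grid)

setMethod("show", "WavelengthGrid", function(object) {
  cat(sprintf("WavelengthGrid: %g-%g nm, %d bands (%.3g nm spacing)\n",
              object@startNm, object@stopNm, object@nBands,
              (object@stopNm - object@startNm) / (object@nBands - 1L)))
})

#' Construct a spectrum
#'
#' @param intensity numeric vector of nonnegative per-band intensities
#'   (counts or normalized units), one value per grid band, band 1 at the
#'   shortest wavelength.
#' @param grid a [WavelengthGrid-class] (default: the 450-800 nm grid).
#' @return a [Spectrum-class].
#' @examples
#' s <- spectrum(rep(1, 36))
#' sum(intensity(normalizeSpectrum(s)))
#' @export
spectrum <- function(intensity, grid = wavelengthGrid()) {
  new("Spectrum", grid = grid, intensity = as.numeric(intensity))
}

#' @rdname spectrum
#' @param x a [Spectrum-class].
setMethod("intensity", "Spectrum", function(x) x@intensity)

setMethod("show", "Spectrum", function(object) {
  ctr <- bandCenters(object)
  tot <- sum(object@intensity)
  pk <- if (tot > 0) sprintf(", peak at %g nm", ctr[which.max(object@intensity)])
        else ""
  cat(sprintf("Spectrum: %d bands (%g-%g nm), total %.4g%s\n",
              nBands(object), min(ctr), max(ctr), tot, pk))
})

#' Normalize a spectrum to unit area
#'
#' Divides every band by the same constant so the intensities sum to 1, the
#' convention used for reference-library entries (coefficients from the
#' un-mixing fit then carry total-signal meaning). Idempotent and invariant
#' to positive scaling of the input.
#'
#' @param x a [Spectrum-class] with positive total intensity.
#' @return the normalized [Spectrum-class].
#' @export
setMethod("normalizeSpectrum", "Spectrum", function(x) {
  tot <- sum(x@intensity)
  if (tot <= 0)
    sqStop("sqDegenerateSpectrum",
           "cannot normalize an all-zero spectrum")
  new("Spectrum", grid = x@grid, intensity = x@intensity / tot)
})

#' Resample a spectrum onto another wavelength grid
#'
#' Linear interpolation at the target band centers; target bands outside the
#' source support are set to 0. Used to align a reference library with a
#' cube recorded on a different grid.
#'
#' @param x a [Spectrum-class].
#' @param target the [WavelengthGrid-class] to resample onto; must overlap
#'   the source grid.
#' @return a [Spectrum-class] on `target`.
#' @export
setMethod("resampleSpectrum", signature("Spectrum", "WavelengthGrid"),
  function(x, target) {
    src <- bandCenters(x@grid)
    dst <- bandCenters(target)
    if (max(src) < min(dst) || min(src) > max(dst))
      sqStop("sqGridMismatch",
             "source (%g-%g nm) and target (%g-%g nm) grids are disjoint",
             min(src), max(src), min(dst), max(dst))
    v <- stats::approx(src, x@intensity, xout = dst, method = "linear",
                       rule = 1)$y
    v[is.na(v)] <- 0
    new("Spectrum", grid = target, intensity = pmax(v, 0))
  })

#' Spectral angle between two intensity vectors
#'
#' The angle (radians) between two spectra viewed as vectors, a
#' brightness-invariant similarity used by seeded region growing.
#'
#' @param a,b numeric vectors or [Spectrum-class] objects of equal length.
#' @return angle in radians, in `[0, pi]`; `NA` if either vector is all-zero.
#' @export
spectralAngle <- function(a, b) {
  if (is(a, "Spectrum")) a <- a@intensity
  if (is(b, "Spectrum")) b <- b@intensity
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  acos(min(1, max(-1, sum(a * b) / (na * nb))))
}

#' Construct a spectral cube
#'
#' @param values numeric array, dim (height, width, nBands), finite and
#'   nonnegative; band 1 is the shortest wavelength.
#' @param grid a [WavelengthGrid-class].
#' @return a [SpectralCube-class].
#' @export
spectralCube <- function(values, grid = wavelengthGrid()) {
  new("SpectralCube", grid = grid, values = values)
}

#' @rdname spectralCube
#' @param x a [SpectralCube-class].
setMethod("cubeValues", "SpectralCube", function(x) x@values)

#' @rdname spectralCube
#' @param row,col pixel coordinate (1-based).
setMethod("pixelSpectrum", "SpectralCube", function(x, row, col) {
  d <- dim(x@values)
  if (row < 1L || row > d[1L] || col < 1L || col > d[2L])
    sqStop("sqBounds", "pixel (%d, %d) outside %dx%d image", row, col,
           d[1L], d[2L])
  new("Spectrum", grid = x@grid, intensity = as.numeric(x@values[row, col, ]))
})

setMethod("dim", "SpectralCube", function(x) dim(x@values))

setMethod("show", "SpectralCube", function(object) {
  d <- dim(object@values)
  cat(sprintf("SpectralCube: %d x %d pixels, %d bands (%g-%g nm)%s\n",
              d[1L], d[2L], d[3L], object@grid@startNm, object@grid@stopNm,
              if (object@backgroundSubtracted) ", background-subtracted" else ""))
})

## Flatten a cube to a (pixels x bands) matrix, pixels in column-major
## (R array) order so matrix(v, H, W) restores the image.
flattenCube <- function(cube) {
  d <- dim(cube@values)
  matrix(cube@values, d[1L] * d[2L], d[3L])
}

unflattenCube <- function(mat, height, width, grid,
                          backgroundSubtracted = FALSE) {
  new("SpectralCube", grid = grid,
      values = array(mat, c(height, width, ncol(mat))),
      backgroundSubtracted = backgroundSubtracted)
}

#' Construct a reference-spectra library
#'
#' Entries are normalized to unit area on construction (peak- or raw-count
#' spectra may be passed). At most nine entries plus one optional background
#' spectrum, all on one grid.
#'
#' @param entries named list of [Spectrum-class] objects.
#' @param background optional [Spectrum-class] fitted (but not reported) as
#'   an extra un-mixing component.
#' @return a [SpectralLibrary-class].
#' @examples
#' g <- wavelengthGrid()
#' lib <- spectralLibrary(list(
#'   FITC = emissionSpectrum(fluorophoreCatalog()$FITC, g),
#'   Cy5  = emissionSpectrum(fluorophoreCatalog()$Cy5, g)))
#' entryNames(lib)
#' @export
spectralLibrary <- function(entries, background = NULL) {
  entries <- lapply(entries, normalizeSpectrum)
  new("SpectralLibrary", entries = entries, background = background)
}

#' @rdname spectralLibrary
#' @param x a [SpectralLibrary-class].
setMethod("entryNames", "SpectralLibrary", function(x) names(x@entries))

#' @rdname spectralLibrary
setMethod("libraryBackground", "SpectralLibrary", function(x) x@background)

setMethod("length", "SpectralLibrary", function(x) length(x@entries))

setMethod("[[", "SpectralLibrary", function(x, i) x@entries[[i]])

setMethod("show", "SpectralLibrary", function(object) {
  cat(sprintf("SpectralLibrary: %d entries (%s)%s\n", length(object@entries),
              paste(names(object@entries), collapse = ", "),
              if (is.null(object@background)) "" else " + background"))
})

## Library entries as a (bands x entries) matrix; background appended as the
## last column when present.
libraryMatrix <- function(library, withBackground = TRUE) {
  R <- vapply(library@entries, function(s) s@intensity,
              numeric(nBands(library)))
  if (withBackground && !is.null(library@background))
    R <- cbind(R, background = library@background@intensity)
  R
}

#' Construct a region of interest
#'
#' @param coords two-column integer matrix of (row, col) pixel coordinates,
#'   1-based.
#' @param label character label.
#' @return an [ROI-class].
#' @export
roi <- function(coords, label = "roi") {
  coords <- matrix(as.integer(round(coords)), ncol = 2L,
                   dimnames = list(NULL, c("row", "col")))
  new("ROI", label = label, coords = coords)
}

#' @rdname roi
#' @param x an [ROI-class].
setMethod("roiLabel", "ROI", function(x) x@label)
#' @rdname roi
setMethod("roiCoords", "ROI", function(x) x@coords)
#' @rdname roi
setMethod("roiArea", "ROI", function(x) nrow(x@coords))

setMethod("show", "ROI", function(object) {
  cat(sprintf("ROI '%s': %d pixels\n", object@label, nrow(object@coords)))
})

## Bounds check against an image and return linear indices (column-major).
roiIndices <- function(roiObj, height, width) {
  co <- roiObj@coords
  if (any(co[, 1L] > height) || any(co[, 2L] > width))
    sqStop("sqBounds", "ROI '%s' has pixels outside the %dx%d image",
           roiObj@label, height, width)
  (co[, 2L] - 1L) * height + co[, 1L]
}

## ROI centroid (row, col).
roiCentroid <- function(roiObj) colMeans(roiObj@coords)
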