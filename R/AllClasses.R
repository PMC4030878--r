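#' @import methods
NULL

## Structured condition helpers used across the package. Every contract
## violation signals a classed condition so callers (and tests) can dispatch
## on the failure kind rather than on message text.
sqStop <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "sqError")))
}

sqWarn <- function(class, fmt, ...) {
  warning(warningCondition(sprintf(fmt, ...),
                           class = c(class, "sqWarning")))
}

#' WavelengthGrid: evenly spaced emission-wavelength bands
#'
#' An ordered set of evenly spaced emission-wavelength band centers, shared by
#' spectra, spectral cubes and reference libraries. The default grid spans
#' 450-800 nm in 36 bands (10 nm spacing), the acquisition range and
#' resolution of the spectral imaging system being modeled.
#'
#' @slot startNm wavelength of the first (shortest) band center, nm.
#' @slot stopNm wavelength of the last band center, nm.
#' @slot nBands number of bands (>= 2).
#'
#' @seealso [wavelengthGrid()], [bandCenters()]
#' @exportClass WavelengthGrid
setClass("WavelengthGrid",
  representation(startNm = "numeric", stopNm = "numeric", nBands = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(object@startNm) != 1L || length(object@stopNm) != 1L ||
        length(object@nBands) != 1L)
      msg <- c(msg, "startNm, stopNm and nBands must be scalars")
    else {
      if (!is.finite(object@startNm) || !is.finite(object@stopNm))
        msg <- c(msg, "grid endpoints must be finite")
      else if (object@startNm >= object@stopNm)
        msg <- c(msg, "startNm must be < stopNm")
      if (object@nBands < 2L)
        msg <- c(msg, "nBands must be >= 2")
    }
    if (is.null(msg)) TRUE else msg
  })

#' Spectrum: per-band emission intensity on a wavelength grid
#'
#' Nonnegative intensity per wavelength band, in arbitrary count units. A
#' unit-normalized spectrum (summing to 1 over bands) is the form used as a
#' reference-library entry.
#'
#' @slot grid a [WavelengthGrid-class].
#' @slot intensity numeric vector, one nonnegative finite value per band.
#'
#' @seealso [spectrum()], [normalizeSpectrum()], [resampleSpectrum()]
#' @exportClass Spectrum
setClass("Spectrum",
  representation(grid = "WavelengthGrid", intensity = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@intensity) != object@grid@nBands)
      msg <- c(msg, sprintf("intensity has %d values but the grid has %d bands",
                            length(object@intensity), object@grid@nBands))
    if (any(!is.finite(object@intensity)))
      msg <- c(msg, "intensities must be finite")
    else if (any(object@intensity < 0))
      msg <- c(msg, "intensities must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' SpectralCube: an image with one emission spectrum per pixel
#'
#' A height x width image carrying one intensity value per pixel per
#' wavelength band, stored as a (height, width, nBands) array with band index
#' 1 at the shortest wavelength. Pixel coordinates are (row, col), row-major.
#'
#' @slot grid a [WavelengthGrid-class].
#' @slot values numeric array, dim (height, width, nBands); finite, >= 0.
#' @slot backgroundSubtracted logical scalar; `TRUE` after
#'   [subtractBackground()] has been applied, so that downstream un-mixing can
#'   flag double background handling.
#'
#' @seealso [spectralCube()], [pixelSpectrum()], [unmixCube()]
#' @exportClass SpectralCube
setClass("SpectralCube",
  representation(grid = "WavelengthGrid", values = "array",
                 backgroundSubtracted = "logical"),
  prototype(backgroundSubtracted = FALSE),
  validity = function(object) {
    d <- dim(object@values)
    msg <- NULL
    if (length(d) != 3L)
      msg <- c(msg, "values must be a 3-d array (height, width, bands)")
    else if (d[3L] != object@grid@nBands)
      msg <- c(msg, sprintf("values has %d band planes but the grid has %d bands",
                            d[3L], object@grid@nBands))
    if (any(!is.finite(object@values)))
      msg <- c(msg, "cube values must be finite")
    else if (any(object@values < 0))
      msg <- c(msg, "cube values must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' SpectralLibrary: named reference spectra plus optional background
#'
#' An ordered collection of up to nine named, unit-normalized reference dye
#' spectra sharing one wavelength grid, plus an optional background spectrum.
#' The background, when present, participates in the un-mixing fit but its
#' coefficient is never reported as a dye abundance.
#'
#' @slot entries named list of normalized [Spectrum-class] objects (1-9).
#' @slot background a [Spectrum-class] or `NULL`.
#'
#' @seealso [spectralLibrary()], [buildReference()], [unmixCube()]
#' @exportClass SpectralLibrary
setClass("SpectralLibrary",
  representation(entries = "list", background = "ANY"),
  prototype(background = NULL),
  validity = function(object) {
    msg <- NULL
    n <- length(object@entries)
    if (n < 1L || n > 9L)
      msg <- c(msg, sprintf("a library holds 1 to 9 reference spectra, got %d", n))
    nm <- names(object@entries)
    if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
      msg <- c(msg, "entries must have unique non-empty names")
    if (!all(vapply(object@entries, is, logical(1), "Spectrum")))
      msg <- c(msg, "entries must be Spectrum objects")
    else {
      g <- object@entries[[1L]]@grid
      same <- vapply(object@entries, function(s) gridsIdentical(s@grid, g),
                     logical(1))
      if (!all(same))
        msg <- c(msg, "all entries must share one wavelength grid")
      sums <- vapply(object@entries, function(s) sum(s@intensity), numeric(1))
      if (any(abs(sums - 1) > 1e-6))
        msg <- c(msg, "entries must be unit-normalized (sum to 1 over bands)")
      if (!is.null(object@background)) {
        if (!is(object@background, "Spectrum"))
          msg <- c(msg, "background must be a Spectrum or NULL")
        else if (!gridsIdentical(object@background@grid, g))
          msg <- c(msg, "background must share the entries' grid")
      }
    }
    if (is.null(msg)) TRUE else msg
  })

#' ROI: a labeled set of pixel coordinates
#'
#' A region of interest over which fluorescence is integrated: a non-empty
#' set of (row, col) pixel coordinates with a label. Coordinates are 1-based
#' matrix indices; bounds are checked against an image at the point of use.
#'
#' @slot label character scalar.
#' @slot coords integer matrix with two columns (row, col), one row per pixel.
#'
#' @seealso [roi()], [roiArea()], [roiReport()]
#' @exportClass ROI
setClass("ROI",
  representation(label = "character", coords = "matrix"),
  validity = function(object) {
    msg <- NULL
    if (length(object@label) != 1L || is.na(object@label))
      msg <- c(msg, "label must be a single string")
    if (ncol(object@coords) != 2L || nrow(object@coords) < 1L)
      msg <- c(msg, "coords must be a non-empty 2-column (row, col) matrix")
    else if (any(object@coords < 1L) || any(object@coords != round(object@coords)))
      msg <- c(msg, "coords must be positive integer pixel indices")
    if (is.null(msg)) TRUE else msg
  })

#' AbundanceMap: per-pixel fluorochrome abundances after un-mixing
#'
#' The result of spectral un-mixing: one nonnegative coefficient (in count
#' units) per pixel per library entry, plus the per-pixel residual L2 norm of
#' the unexplained spectrum. Background coefficients, when a background
#' spectrum was fitted, are stored separately and excluded from the entries.
#'
#' @slot coef numeric array, dim (height, width, nEntries), dye names on the
#'   third dimension; >= 0.
#' @slot residual numeric matrix (height, width), >= 0.
#' @slot backgroundCoef numeric matrix (height, width) of background-component
#'   coefficients, or a 0x0 matrix when no background was fitted.
#'
#' @seealso [unmixCube()], [abundance()], [roiReport()]
#' @exportClass AbundanceMap
setClass("AbundanceMap",
  representation(coef = "array", residual = "matrix",
                 backgroundCoef = "matrix"),
  validity = function(object) {
    d <- dim(object@coef)
    msg <- NULL
    if (length(d) != 3L)
      msg <- c(msg, "coef must be a 3-d array (height, width, entries)")
    else {
      if (is.null(dimnames(object@coef)[[3L]]))
        msg <- c(msg, "coef must carry entry names on dimension 3")
      if (!all(dim(object@residual) == d[1:2]))
        msg <- c(msg, "residual dimensions must match the coefficient image")
    }
    if (any(object@coef < 0) || any(object@residual < 0))
      msg <- c(msg, "coefficients and residuals must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' FluorophoreModel: emission characteristics of one dye or bead
#'
#' Peak emission wavelength and full width at half maximum of a single
#' fluorochrome or fluorescent bead, used by the synthetic-scene generator to
#' produce Gaussian emission spectra. The excitation peak is carried as
#' metadata only; excitation and filter physics are collapsed into per-object
#' brightness scalars.
#'
#' @slot name character scalar.
#' @slot excitationNm excitation peak, nm (metadata).
#' @slot emissionNm emission peak, nm.
#' @slot fwhmNm emission full width at half maximum, nm (> 0).
#'
#' @seealso [fluorophore()], [fluorophoreCatalog()], [emissionSpectrum()]
#' @exportClass FluorophoreModel
setClass("FluorophoreModel",
  representation(name = "character", excitationNm = "numeric",
                 emissionNm = "numeric", fwhmNm = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@name) != 1L) msg <- c(msg, "name must be a single string")
    if (object@fwhmNm <= 0) msg <- c(msg, "fwhmNm must be > 0")
    if (!is.finite(object@emissionNm)) msg <- c(msg, "emissionNm must be finite")
    if (is.null(msg)) TRUE else msg
  })

#' NoiseModel: acquisition noise description
#'
#' @slot kind one of `"none"`, `"shot"` (Poisson) or `"shot+read"` (Poisson
#'   plus zero-mean Gaussian read noise).
#' @slot readSd read-noise standard deviation in counts (>= 0); used only for
#'   `"shot+read"`.
#'
#' @seealso [noiseModel()], [applyNoise()]
#' @exportClass NoiseModel
setClass("NoiseModel",
  representation(kind = "character", readSd = "numeric"),
  prototype(kind = "none", readSd = 0),
  validity = function(object) {
    msg <- NULL
    if (!object@kind %in% c("none", "shot", "shot+read"))
      msg <- c(msg, "kind must be one of 'none', 'shot', 'shot+read'")
    if (object@readSd < 0) msg <- c(msg, "readSd must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' SceneSpec: a synthetic field of fluorescent objects
#'
#' Everything needed to render a synthetic spectral cube with known ground
#' truth: image size, a fluorophore panel, a list of objects (uniform disks
#' for beads, nucleus+cytoplasm disk pairs for cells), flat background level,
#' optional autofluorescence spectrum added at every pixel, a noise model, a
#' per-band photobleaching rate and the random seed.
#'
#' @slot height,width image size in pixels.
#' @slot grid a [WavelengthGrid-class].
#' @slot panel named list of [FluorophoreModel-class] objects.
#' @slot objects list of scene objects from [diskObject()] / [cellObject()].
#' @slot backgroundLevel flat background, total counts per pixel summed over
#'   bands (spread evenly across bands).
#' @slot autofluorescence a [Spectrum-class] added at every pixel, or `NULL`.
#' @slot noise a [NoiseModel-class].
#' @slot bleachRate per-band-step fractional decay in `[0, 1)`; band plane b
#'   is scaled by `(1 - bleachRate)^(b - 1)` under the band-sequential
#'   acquisition convention. Default 0 (off).
#' @slot seed integer RNG seed used when noise is on.
#'
#' @seealso [sceneSpec()], [renderScene()]
#' @exportClass SceneSpec
setClass("SceneSpec",
  representation(height = "integer", width = "integer",
                 grid = "WavelengthGrid", panel = "list", objects = "list",
                 backgroundLevel = "numeric", autofluorescence = "ANY",
                 noise = "NoiseModel", bleachRate = "numeric",
                 seed = "numeric"),
  prototype(backgroundLevel = 0, autofluorescence = NULL,
            bleachRate = 0, seed = 1),
  validity = function(object) {
    msg <- NULL
    if (object@height < 1L || object@width < 1L)
      msg <- c(msg, "image size must be positive")
    if (object@bleachRate < 0 || object@bleachRate >= 1)
      msg <- c(msg, "bleachRate must be in [0, 1)")
    if (object@backgroundLevel < 0)
      msg <- c(msg, "backgroundLevel must be >= 0")
    if (length(object@panel) &&
        (is.null(names(object@panel)) ||
         !all(vapply(object@panel, is, logical(1), "FluorophoreModel"))))
      msg <- c(msg, "panel must be a named list of FluorophoreModel objects")
    if (is.null(msg)) TRUE else msg
  })

#' GroundTruth: per-object truth for a rendered scene
#'
#' Records, for every object of a rendered synthetic scene, its true pixel
#' set, its true per-fluorophore total counts (noiseless, pre-bleach sums)
#' and its population label.
#'
#' @slot rois list of [ROI-class], one per object, in object order.
#' @slot totals numeric matrix (objects x fluorophores) of true total counts;
#'   rownames are object labels, colnames fluorophore names.
#' @slot populations character vector of population labels per object.
#'
#' @seealso [renderScene()], [truthRois()], [truthTotals()]
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(rois = "list", totals = "matrix", populations = "character"),
  validity = function(object) {
    msg <- NULL
    n <- length(object@rois)
    if (nrow(object@totals) != n || length(object@populations) != n)
      msg <- c(msg, "rois, totals rows and populations must align")
    if (any(object@totals < 0))
      msg <- c(msg, "true totals must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' OPDSchedule: stepped optical-path-difference acquisition schedule
#'
#' Evenly spaced optical path difference (OPD) values from 0 to `maxOpdNm`
#' at which interferometric frames are recorded. The step must stay below
#' half the shortest wavelength of the target grid (Nyquist) for
#' reconstruction to be valid.
#'
#' @slot nFrames number of interferometric frames (default 128; the modeled
#'   instrument records 80-130 frames per object).
#' @slot maxOpdNm largest optical path difference, nm.
#'
#' @seealso [opdSchedule()], [opdSteps()], [reconstructSpectrum()]
#' @exportClass OPDSchedule
setClass("OPDSchedule",
  representation(nFrames = "integer", maxOpdNm = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@nFrames < 2L) msg <- c(msg, "nFrames must be >= 2")
    if (!is.finite(object@maxOpdNm) || object@maxOpdNm <= 0)
      msg <- c(msg, "maxOpdNm must be positive and finite")
    if (is.null(msg)) TRUE else msg
  })

#' InterferogramStack: per-pixel interferograms at each OPD step
#'
#' @slot schedule an [OPDSchedule-class].
#' @slot frames numeric array, dim (height, width, nFrames); >= 0.
#'
#' @seealso [forwardCube()], [acquireCube()]
#' @exportClass InterferogramStack
setClass("InterferogramStack",
  representation(schedule = "OPDSchedule", frames = "array"),
  validity = function(object) {
    d <- dim(object@frames)
    msg <- NULL
    if (length(d) != 3L || d[3L] != object@schedule@nFrames)
      msg <- c(msg, "frames must be (height, width, nFrames)")
    if (any(object@frames < 0))
      msg <- c(msg, "interferogram intensities must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' GrowParams: parameters for seeded region growing
#'
#' @slot intensityTol admissible fractional deviation of a pixel's total
#'   intensity from the seed pixel's total intensity (> 0).
#' @slot spectralTol maximum spectral angle (radians) between a pixel's
#'   spectrum and the seed spectrum (> 0).
#' @slot maxArea growth budget in pixels (>= 1).
#' @slot connectivity 4 or 8.
#'
#' @seealso [growParams()], [growRoi()]
#' @exportClass GrowParams
setClass("GrowParams",
  representation(intensityTol = "numeric", spectralTol = "numeric",
                 maxArea = "numeric", connectivity = "integer"),
  prototype(intensityTol = 0.25, spectralTol = 0.15, maxArea = Inf,
            connectivity = 8L),
  validity = function(object) {
    msg <- NULL
    if (object@intensityTol <= 0) msg <- c(msg, "intensityTol must be > 0")
    if (object@spectralTol <= 0) msg <- c(msg, "spectralTol must be > 0")
    if (object@maxArea < 1) msg <- c(msg, "maxArea must be >= 1")
    if (!object@connectivity %in% c(4L, 8L))
      msg <- c(msg, "connectivity must be 4 or 8")
    if (is.null(msg)) TRUE else msg
  })
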