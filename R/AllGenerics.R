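#' @rdname bandCenters
#' @export
setGeneric("bandCenters", function(x) standardGeneric("bandCenters"))

#' @rdname bandCenters
#' @export
setGeneric("nBands", function(x) standardGeneric("nBands"))

#' @rdname bandCenters
#' @export
setGeneric("wlGrid", function(x) standardGeneric("wlGrid"))

#' @rdname spectrum
#' @export
setGeneric("intensity", function(x) standardGeneric("intensity"))

#' @rdname normalizeSpectrum
#' @export
setGeneric("normalizeSpectrum", function(x) standardGeneric("normalizeSpectrum"))

#' @rdname resampleSpectrum
#' @export
setGeneric("resampleSpectrum",
           function(x, target) standardGeneric("resampleSpectrum"))

#' @rdname spectralCube
#' @export
setGeneric("cubeValues", function(x) standardGeneric("cubeValues"))

#' @rdname spectralCube
#' @export
setGeneric("pixelSpectrum",
           function(x, row, col) standardGeneric("pixelSpectrum"))

#' @rdname spectralLibrary
#' @export
setGeneric("entryNames", function(x) standardGeneric("entryNames"))

#' @rdname spectralLibrary
#' @export
setGeneric("libraryBackground",
           function(x) standardGeneric("libraryBackground"))

#' @rdname roi
#' @export
setGeneric("roiLabel", function(x) standardGeneric("roiLabel"))

#' @rdname roi
#' @export
setGeneric("roiCoords", function(x) standardGeneric("roiCoords"))

#' @rdname roi
#' @export
setGeneric("roiArea", function(x) standardGeneric("roiArea"))

#' @rdname unmixCube
#' @export
setGeneric("abundance", function(x, name) standardGeneric("abundance"))

#' @rdname unmixCube
#' @export
setGeneric("residuals2d", function(x) standardGeneric("residuals2d"))

#' @rdname renderScene
#' @export
setGeneric("truthRois", function(x) standardGeneric("truthRois"))

#' @rdname renderScene
#' @export
setGeneric("truthTotals", function(x) standardGeneric("truthTotals"))

#' @rdname renderScene
#' @export
setGeneric("truthPopulations",
           function(x) standardGeneric("truthPopulations"))

#' @rdname opdSchedule
#' @export
setGeneric("opdSteps", function(x) standardGeneric("opdSteps"))
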