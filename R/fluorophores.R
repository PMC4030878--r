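#' Construct a fluorophore model
#'
#' @param name dye name.
#' @param excitationNm excitation peak, nm (metadata only; excitation and
#'   filter physics are collapsed into per-object brightness scalars).
#' @param emissionNm emission peak, nm.
#' @param fwhmNm emission full width at half maximum, nm. The default 30 nm
#'   gives smooth, distinct but overlapping spectra typical of organic dye
#'   panels.
#' @return a [FluorophoreModel-class].
#' @export
fluorophore <- function(name, excitationNm, emissionNm, fwhmNm = 30) {
  new("FluorophoreModel", name = name,
      excitationNm = as.numeric(excitationNm),
      emissionNm = as.numeric(emissionNm), fwhmNm = as.numeric(fwhmNm))
}

setMethod("show", "FluorophoreModel", function(object) {
  cat(sprintf("FluorophoreModel '%s': ex %g nm, em %g nm (FWHM %g nm)\n",
              object@name, object@excitationNm, object@emissionNm,
              object@fwhmNm))
})

#' Built-in fluorophore and bead catalog
#'
#' Named list of [FluorophoreModel-class] objects covering the reporter dyes
#' of the five/six-transcript FISH panels (FITC, Cy3, Cy3.5, Texas Red, Cy5,
#' Cy5.5, plus the DAPI counterstain) and the calibration-bead colors
#' (InSpeck green/orange/red/deep-red and the crimson/scarlet/ultra-red
#' far-red standards). Peaks are the manufacturer excitation/emission maxima;
#' the emission shape (Gaussian, 30 nm FWHM by default) is a model choice.
#'
#' @param fwhmNm emission FWHM applied to every catalog entry, nm.
#' @return named list of [FluorophoreModel-class].
#' @examples
#' names(fluorophoreCatalog())
#' @export
fluorophoreCatalog <- function(fwhmNm = 30) {
  spec <- list(
    ## dyes:          excitation, emission
    FITC          = c(495, 528),
    Cy3           = c(552, 565),
    Cy3.5         = c(581, 596),
    TexasRed      = c(596, 620),
    Cy5           = c(650, 667),
    Cy5.5         = c(678, 703),
    DAPI          = c(363, 461),
    ## calibration beads
    bead.green    = c(505, 515),
    bead.orange   = c(540, 560),
    bead.red      = c(580, 605),
    bead.deepred  = c(633, 660),
    bead.crimson  = c(625, 645),
    bead.scarlet  = c(645, 680),
    bead.ultrared = c(665, 695))
  out <- mapply(function(nm, v) fluorophore(nm, v[1L], v[2L], fwhmNm),
                names(spec), spec, SIMPLIFY = FALSE)
  out
}

#' Gaussian emission spectrum of a fluorophore on a grid
#'
#' Samples a Gaussian emission profile centered at the fluorophore's emission
#' peak with its stated FWHM at the grid band centers and normalizes it to
#' unit area. In the FWHM -> 0 limit all mass collapses into the band nearest
#' the peak. A peak lying more than 3 FWHM outside the grid range raises an
#' out-of-range warning (the spectrum may then be essentially zero).
#'
#' @param model a [FluorophoreModel-class].
#' @param grid a [WavelengthGrid-class].
#' @return a unit-normalized [Spectrum-class].
#' @examples
#' s <- emissionSpectrum(fluorophoreCatalog()$FITC, wavelengthGrid())
#' bandCenters(s)[which.max(intensity(s))]  # band nearest 528 nm
#' @export
emissionSpectrum <- function(model, grid = wavelengthGrid()) {
  ctr <- bandCenters(grid)
  peak <- model@emissionNm
  sd <- model@fwhmNm / (2 * sqrt(2 * log(2)))
  margin <- 3 * model@fwhmNm
  if (peak < min(ctr) - margin || peak > max(ctr) + margin)
    sqWarn("sqOutOfRange",
           "emission peak %g nm of '%s' lies more than 3 FWHM outside the %g-%g nm grid",
           peak, model@name, min(ctr), max(ctr))
  v <- exp(-(ctr - peak)^2 / (2 * sd^2))
  if (sum(v) == 0) {
    ## delta limit: underflow everywhere; put the mass in the nearest band
    ## if the peak is within the grid span.
    if (peak >= min(ctr) && peak <= max(ctr))
      v[which.min(abs(ctr - peak))] <- 1
    else
      return(new("Spectrum", grid = grid, intensity = v))
  }
  new("Spectrum", grid = grid, intensity = v / sum(v))
}
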