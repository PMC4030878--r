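#' Estimate a background spectrum from a cube region
#'
#' The per-band mean spectrum over the pixels of `roi` (not normalized),
#' the quantity subtracted as background fluorescence or stored as a
#' library background component.
#'
#' @param cube a [SpectralCube-class].
#' @param roi an [ROI-class] inside the cube.
#' @return a [Spectrum-class] in count units.
#' @export
estimateBackground <- function(cube, roi) {
  d <- dim(cube@values)
  idx <- roiIndices(roi, d[1L], d[2L])
  S <- flattenCube(cube)
  v <- if (length(idx) == 1L) S[idx, ] else colMeans(S[idx, , drop = FALSE])
  new("Spectrum", grid = cube@grid, intensity = as.numeric(v))
}

#' Subtract a background spectrum from every pixel
#'
#' Per-pixel, per-band subtraction with clamping at zero (a band where the
#' background exceeds the signal reports zero, never a negative count). The
#' returned cube is flagged background-subtracted so that un-mixing can warn
#' when a background library component is additionally fitted.
#'
#' @param cube a [SpectralCube-class].
#' @param background a [Spectrum-class] on the same grid.
#' @return the background-subtracted [SpectralCube-class].
#' @export
subtractBackground <- function(cube, background) {
  stopIfGridMismatch(cube@grid, background@grid, "cube and background")
  S <- sweep(flattenCube(cube), 2L, background@intensity, "-")
  S[S < 0] <- 0
  d <- dim(cube@values)
  unflattenCube(S, d[1L], d[2L], cube@grid, backgroundSubtracted = TRUE)
}

#' Build a reference spectrum from a single-dye image
#'
#' Reference libraries are built by recording the emission of pure dyes: the
#' mean spectrum over a signal region, minus the mean spectrum over a
#' disjoint background region, clamped at zero and normalized to unit area.
#' Scaling the specimen brightness leaves the reference unchanged.
#'
#' @param cube single-dye [SpectralCube-class].
#' @param signalRoi [ROI-class] over pure-dye pixels.
#' @param backgroundRoi disjoint [ROI-class] over blank pixels.
#' @param name dye name for the library entry.
#' @return named list with elements `name` and `spectrum` (a normalized
#'   [Spectrum-class]), ready for [spectralLibrary()].
#' @export
buildReference <- function(cube, signalRoi, backgroundRoi, name) {
  a <- roiCoords(signalRoi); b <- roiCoords(backgroundRoi)
  if (nrow(merge(as.data.frame(a), as.data.frame(b))) > 0L)
    sqStop("sqValidation", "signal and background ROIs must be disjoint")
  sig <- estimateBackground(cube, signalRoi)@intensity
  bg <- estimateBackground(cube, backgroundRoi)@intensity
  v <- pmax(sig - bg, 0)
  if (sum(v) <= 0)
    sqStop("sqDegenerateSpectrum",
           "reference '%s' is all zero after background subtraction", name)
  list(name = name,
       spectrum = new("Spectrum", grid = cube@grid, intensity = v / sum(v)))
}

## Collinearity guard: condition number of the column-normalized library
## matrix above 1e6 means two references are (near-)identical; the error
## names the most similar pair.
checkCollinearity <- function(R, names_) {
  Rn <- sweep(R, 2L, sqrt(colSums(R^2)), "/")
  if (ncol(Rn) >= 2L && kappa(Rn, exact = TRUE) > 1e6) {
    G <- crossprod(Rn)
    diag(G) <- -Inf
    ij <- arrayInd(which.max(G), dim(G))
    sqStop("sqCollinear",
           "library entries '%s' and '%s' are collinear (cannot be separated)",
           names_[ij[1L]], names_[ij[2L]])
  }
  invisible(TRUE)
}

#' Un-mix one pixel spectrum against a reference library
#'
#' Decomposes a measured spectrum into nonnegative per-fluorochrome
#' abundances `a_k` with `spectrum ~ sum_k a_k R_k`. The default `"clamp"`
#' mode mirrors the behavior of the modeled analysis software: an
#' unconstrained least-squares fit whose occasional negative coefficients
#' are reported as zeros. `"nnls"` solves the nonnegative least-squares
#' problem properly (KKT-optimal). The residual is the L2 norm of the
#' spectrum minus the model at the reported (post-clamp) coefficients. A
#' library background spectrum, when present, participates in the fit but
#' its coefficient is reported separately.
#'
#' @param spectrum a [Spectrum-class].
#' @param library a [SpectralLibrary-class] on the same grid.
#' @param mode `"clamp"` or `"nnls"`.
#' @return list with `coefficients` (named, >= 0), `background` (coefficient
#'   or `NA` when the library has none) and `residual`.
#' @examples
#' g <- wavelengthGrid()
#' fl <- fluorophoreCatalog()
#' lib <- spectralLibrary(list(FITC = emissionSpectrum(fl$FITC, g),
#'                             Cy5 = emissionSpectrum(fl$Cy5, g)))
#' s <- spectrum(3 * intensity(lib[["FITC"]]), g)
#' unmixPixel(s, lib)$coefficients
#' @export
unmixPixel <- function(spectrum, library, mode = c("clamp", "nnls")) {
  mode <- match.arg(mode)
  stopIfGridMismatch(spectrum@grid, wlGrid(library), "spectrum and library")
  R <- libraryMatrix(library)
  nm <- colnames(R)
  checkCollinearity(R, nm)
  a <- if (mode == "clamp")
    as.numeric(qr.solve(R, spectrum@intensity))
  else
    pracma::lsqnonneg(R, spectrum@intensity)$x
  a <- pmax(a, 0)
  fit <- as.numeric(R %*% a)
  res <- sqrt(sum((spectrum@intensity - fit)^2))
  hasBg <- !is.null(library@background)
  k <- length(library@entries)
  list(coefficients = stats::setNames(a[seq_len(k)], names(library@entries)),
       background = if (hasBg) a[k + 1L] else NA_real_,
       residual = res)
}

#' Un-mix every pixel of a spectral cube
#'
#' Applies the per-pixel spectral decomposition of [unmixPixel()] across an
#' image. In `"clamp"` mode the unconstrained fit is a single linear
#' operator, so the whole cube is solved in one matrix product; `"nnls"`
#' iterates the active-set solver per pixel. When the cube is already
#' background-subtracted and the library also carries a background
#' component, both corrections apply and a warning notes the double
#' handling.
#'
#' @param cube a [SpectralCube-class].
#' @param library a [SpectralLibrary-class].
#' @param mode `"clamp"` (default) or `"nnls"`.
#' @return an [AbundanceMap-class].
#' @export
unmixCube <- function(cube, library, mode = c("clamp", "nnls")) {
  mode <- match.arg(mode)
  stopIfGridMismatch(cube@grid, wlGrid(library), "cube and library")
  R <- libraryMatrix(library)
  checkCollinearity(R, colnames(R))
  hasBg <- !is.null(library@background)
  if (hasBg && cube@backgroundSubtracted)
    sqWarn("sqDoubleBackground",
           "cube is background-subtracted and the library also fits a background component")
  S <- flattenCube(cube)
  if (mode == "clamp") {
    P <- solve(crossprod(R), t(R))       # (entries x bands) LS operator
    Afit <- S %*% t(P)
  } else {
    Afit <- t(apply(S, 1L, function(s) pracma::lsqnonneg(R, s)$x))
  }
  Afit[Afit < 0] <- 0
  resid <- sqrt(rowSums((S - Afit %*% t(R))^2))
  d <- dim(cube@values)
  k <- length(library@entries)
  coef <- array(Afit[, seq_len(k)], c(d[1L], d[2L], k),
                dimnames = list(NULL, NULL, names(library@entries)))
  bg <- if (hasBg) matrix(Afit[, k + 1L], d[1L], d[2L])
        else matrix(numeric(0), 0L, 0L)
  new("AbundanceMap", coef = coef, residual = matrix(resid, d[1L], d[2L]),
      backgroundCoef = bg)
}

#' @rdname unmixCube
#' @param x an [AbundanceMap-class].
#' @param name library entry name (or index).
setMethod("abundance", "AbundanceMap", function(x, name) x@coef[, , name])

#' @rdname unmixCube
setMethod("residuals2d", "AbundanceMap", function(x) x@residual)

#' @rdname unmixCube
setMethod("entryNames", "AbundanceMap", function(x) dimnames(x@coef)[[3L]])

setMethod("dim", "AbundanceMap", function(x) dim(x@coef))

setMethod("show", "AbundanceMap", function(object) {
  d <- dim(object@coef)
  cat(sprintf("AbundanceMap: %d x %d pixels, %d entries (%s)%s\n",
              d[1L], d[2L], d[3L],
              paste(dimnames(object@coef)[[3L]], collapse = ", "),
              if (length(object@backgroundCoef)) " + background" else ""))
})

#' Render a pseudo-color RGB display of a spectral cube
#'
#' Each display channel is the cube summed over a wavelength interval, and
#' all three channels are scaled jointly to 0-255 by the global maximum.
#' The default intervals are the false-color display settings of the
#' modeled system: blue 475-557 nm, green 561-635 nm, red 635-752 nm.
#'
#' @param cube a [SpectralCube-class].
#' @param bands named list with elements `red`, `green`, `blue`, each a
#'   `c(lo, hi)` wavelength interval (nm) containing at least one band
#'   center.
#' @return integer array (height, width, 3) with values 0-255, channel
#'   order red, green, blue.
#' @export
renderRgb <- function(cube, bands = list(red = c(635, 752),
                                         green = c(561, 635),
                                         blue = c(475, 557))) {
  stopifnot(all(c("red", "green", "blue") %in% names(bands)))
  ctr <- bandCenters(cube)
  d <- dim(cube@values)
  ch <- lapply(bands[c("red", "green", "blue")], function(iv) {
    sel <- which(ctr >= iv[1L] & ctr <= iv[2L])
    if (!length(sel))
      sqStop("sqEmptyBand", "interval %g-%g nm contains no grid band",
             iv[1L], iv[2L])
    apply(cube@values[, , sel, drop = FALSE], c(1L, 2L), sum)
  })
  mx <- max(unlist(lapply(ch, max)))
  out <- array(0L, c(d[1L], d[2L], 3L))
  if (mx > 0)
    for (i in 1:3) out[, , i] <- as.integer(round(ch[[i]] / mx * 255))
  out
}
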