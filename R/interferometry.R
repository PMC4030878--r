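#' Construct an optical-path-difference schedule
#'
#' OPD values are evenly spaced from 0 to `maxOpdNm` over `nFrames` frames
#' (one-sided sampling). The default records 128 frames (the modeled
#' instrument acquires 80-130 interferometric frames per object) with a
#' 220 nm step, safely below the 225 nm Nyquist limit of the default
#' 450-800 nm grid.
#'
#' @param nFrames number of frames.
#' @param maxOpdNm largest optical path difference, nm; default
#'   `(nFrames - 1) * 220`.
#' @return an [OPDSchedule-class].
#' @export
opdSchedule <- function(nFrames = 128L, maxOpdNm = (nFrames - 1) * 220) {
  new("OPDSchedule", nFrames = as.integer(nFrames),
      maxOpdNm = as.numeric(maxOpdNm))
}

#' @rdname opdSchedule
#' @param x an [OPDSchedule-class].
setMethod("opdSteps", "OPDSchedule", function(x)
  seq(0, x@maxOpdNm, length.out = x@nFrames))

setMethod("show", "OPDSchedule", function(object) {
  cat(sprintf("OPDSchedule: %d frames, 0-%g nm OPD (step %.4g nm)\n",
              object@nFrames, object@maxOpdNm,
              object@maxOpdNm / (object@nFrames - 1L)))
})

## Forward model matrix A (nFrames x nBands):
## I(d) = sum_b S(lambda_b) * (1 + cos(2 pi d / lambda_b)) / 2.
forwardMatrix <- function(grid, schedule) {
  d <- opdSteps(schedule)
  lam <- bandCenters(grid)
  outer(d, lam, function(dd, l) (1 + cos(2 * pi * dd / l)) / 2)
}

checkNyquist <- function(grid, schedule) {
  step <- schedule@maxOpdNm / (schedule@nFrames - 1L)
  lamMin <- min(bandCenters(grid))
  if (step >= lamMin / 2)
    sqStop("sqAliasing",
           "OPD step %.4g nm violates Nyquist for the shortest band (%g nm needs step < %g nm)",
           step, lamMin, lamMin / 2)
  invisible(TRUE)
}

## Windowed cosine-transform kernel K (nFrames x nBands): half-Hann
## apodization (unity at zero path difference, decaying to zero at maximum
## OPD) times cos(2 pi d / lambda_b), evaluated at the exact band
## wavenumbers 1/lambda_b (direct transform, no FFT-grid interpolation).
transformKernel <- function(grid, schedule) {
  d <- opdSteps(schedule)
  lam <- bandCenters(grid)
  w <- 0.5 * (1 + cos(pi * d / schedule@maxOpdNm))
  w * outer(d, lam, function(dd, l) cos(2 * pi * dd / l))
}

## Band-response (instrument line shape) matrix M (nBands x nBands): the
## windowed transform of the forward model of each unit band spectrum,
## including the mean-subtraction step. Reconstruction applies its inverse,
## undoing the finite-OPD line-shape blur exactly. Cached per
## (grid, schedule) pair.
.sqCache <- new.env(parent = emptyenv())

responseMatrices <- function(grid, schedule) {
  key <- sprintf("%g_%g_%d_%d_%g", grid@startNm, grid@stopNm, grid@nBands,
                 schedule@nFrames, schedule@maxOpdNm)
  hit <- .sqCache[[key]]
  if (!is.null(hit)) return(hit)
  A <- forwardMatrix(grid, schedule)
  K <- transformKernel(grid, schedule)
  Ac <- sweep(A, 2L, colMeans(A))        # mean-subtracted columns
  M <- t(K) %*% Ac                       # bands x bands response
  out <- list(A = A, K = K, Minv = solve(M))
  .sqCache[[key]] <- out
  out
}

#' Forward-model a Sagnac interferogram
#'
#' Intensity at optical path difference d is
#' `I(d) = sum_b S(lambda_b) (1 + cos(2 pi d / lambda_b)) / 2`, the
#' two-beam interference pattern of the spectrum summed over bands; in
#' particular `I(0)` equals the total intensity.
#'
#' @param spectrum a [Spectrum-class].
#' @param schedule an [OPDSchedule-class].
#' @return numeric vector of per-frame intensities, `length(opdSteps(schedule))`.
#' @examples
#' s <- spectrum(c(0, 1, 0), wavelengthGrid(500, 600, 3))
#' forwardInterferogram(s, opdSchedule(4, 300))[1]  # I(0) = 1
#' @export
forwardInterferogram <- function(spectrum, schedule) {
  as.numeric(forwardMatrix(spectrum@grid, schedule) %*% spectrum@intensity)
}

#' Reconstruct a spectrum from an interferogram
#'
#' The mean-subtracted interferogram is apodized (half-Hann window, unity at
#' zero path difference) and transformed by a direct windowed cosine
#' transform evaluated at the exact band wavenumbers `1/lambda_b`. By
#' default the known band-response (instrument line shape) of the schedule
#' is then inverted, which removes the finite-OPD blur and makes the
#' transform an exact linear inverse of [forwardInterferogram()]; with
#' `correct = FALSE` the raw transform values are returned instead.
#' Negative values are clamped to zero and the spectrum is rescaled so its
#' total equals `I(0)`, the total intensity recorded at zero path
#' difference.
#'
#' @param interferogram numeric vector of per-frame intensities.
#' @param schedule the [OPDSchedule-class] used for acquisition; must
#'   satisfy Nyquist for `grid`.
#' @param grid target [WavelengthGrid-class].
#' @param correct apply the line-shape correction (default `TRUE`).
#' @param clamp clamp negative band values to zero and renormalize to `I(0)`
#'   (default `TRUE`). `clamp = FALSE` exposes the exactly linear
#'   reconstruction core.
#' @return a [Spectrum-class] (for `clamp = FALSE`, a plain numeric vector
#'   that may contain negatives).
#' @export
reconstructSpectrum <- function(interferogram, schedule, grid,
                                correct = TRUE, clamp = TRUE) {
  checkNyquist(grid, schedule)
  if (length(interferogram) != schedule@nFrames)
    sqStop("sqFormat", "interferogram has %d frames, schedule expects %d",
           length(interferogram), schedule@nFrames)
  rm_ <- responseMatrices(grid, schedule)
  x <- interferogram - mean(interferogram)
  v <- as.numeric(crossprod(rm_$K, x))
  if (correct) v <- as.numeric(rm_$Minv %*% v)
  if (!clamp) return(v)
  v <- pmax(v, 0)
  tot <- interferogram[1L]               # I(0) = total intensity
  s <- sum(v)
  if (s > 0 && tot > 0) v <- v * tot / s
  else v[] <- 0
  new("Spectrum", grid = grid, intensity = v)
}

#' Forward-model interferograms for every pixel of a cube
#'
#' @param cube a [SpectralCube-class].
#' @param schedule an [OPDSchedule-class].
#' @return an [InterferogramStack-class].
#' @export
forwardCube <- function(cube, schedule) {
  A <- forwardMatrix(cube@grid, schedule)
  S <- flattenCube(cube)
  I <- S %*% t(A)
  d <- dim(cube@values)
  new("InterferogramStack", schedule = schedule,
      frames = array(I, c(d[1L], d[2L], schedule@nFrames)))
}

setMethod("show", "InterferogramStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("InterferogramStack: %d x %d pixels, %d frames (OPD 0-%g nm)\n",
              d[1L], d[2L], d[3L], object@schedule@maxOpdNm))
})

#' Simulate interferometric acquisition of a spectral cube
#'
#' Runs the full acquisition path per pixel: forward interferogram at each
#' OPD step, optional per-frame acquisition noise, then spectral
#' reconstruction (see [reconstructSpectrum()]) back onto the cube's own
#' grid. With noise off and the default line-shape correction the round trip
#' reproduces the input cube to numerical precision; the pipeline may also
#' skip this step entirely and consume the rendered cube directly.
#'
#' @param cube a [SpectralCube-class].
#' @param schedule an [OPDSchedule-class].
#' @param noise a [NoiseModel-class] applied per frame.
#' @param seed RNG seed for the acquisition noise (`NULL`: use current RNG
#'   stream).
#' @param correct apply the line-shape correction (default `TRUE`).
#' @return the reconstructed [SpectralCube-class].
#' @examples
#' sc <- sceneSpec(16, 16, list(diskObject(c(8, 8), 3, c(FITC = 500))),
#'                 panel = fluorophoreCatalog()["FITC"])
#' cube <- renderScene(sc)$cube
#' rec <- acquireCube(cube)
#' max(abs(cubeValues(rec) - cubeValues(cube))) < 1e-6
#' @export
acquireCube <- function(cube, schedule = opdSchedule(),
                        noise = noiseModel("none"), seed = NULL,
                        correct = TRUE) {
  checkNyquist(cube@grid, schedule)
  rm_ <- responseMatrices(cube@grid, schedule)
  S <- flattenCube(cube)
  I <- S %*% t(rm_$A)                    # pixels x frames
  if (noise@kind != "none")
    I <- withSeed(seed, applyNoise(I, noise))
  X <- I - rowMeans(I)
  V <- X %*% rm_$K                       # pixels x bands (raw transform)
  if (correct) V <- V %*% t(rm_$Minv)
  V[V < 0] <- 0
  tot <- I[, 1L]                         # per-pixel I(0)
  s <- rowSums(V)
  scale <- ifelse(s > 0 & tot > 0, tot / s, 0)
  V <- V * scale
  d <- dim(cube@values)
  unflattenCube(V, d[1L], d[2L], cube@grid,
                backgroundSubtracted = cube@backgroundSubtracted)
}
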