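## Shared fixture builders. Everything is generated in code; no binary
## fixtures are stored.

tinyGrid <- function(startNm = 500, stopNm = 600, nBands = 6L) {
  wavelengthGrid(startNm, stopNm, nBands)
}

## Normalized Gaussian intensities on a grid (independent of the package's
## emissionSpectrum, for use as an oracle input).
gaussIntensities <- function(grid, peakNm, fwhmNm = 30) {
  ctr <- bandCenters(grid)
  s <- fwhmNm / (2 * sqrt(2 * log(2)))
  v <- exp(-(ctr - peakNm)^2 / (2 * s^2))
  v / sum(v)
}

## A two-entry library of well-separated Gaussians on the default grid.
twoDyeLibrary <- function(grid = wavelengthGrid()) {
  spectralLibrary(list(
    A = spectrum(gaussIntensities(grid, 520), grid),
    B = spectrum(gaussIntensities(grid, 660), grid)))
}

## Single-disk scene helper.
diskScene <- function(dye = "FITC", brightness = 1000, radius = 4,
                      size = 24L, noise = noiseModel("none"), seed = 1,
                      background = 0) {
  sceneSpec(size, size,
            list(diskObject(c(size / 2, size / 2), radius,
                            stats::setNames(brightness, dye))),
            panel = fluorophoreCatalog()[dye], backgroundLevel = background,
            noise = noise, seed = seed)
}

## Brute-force nonnegative grid-search un-mixing oracle: minimizes
## || s - R a || over a >= 0 on regular coefficient grids, refined
## coarse-to-fine (the least-squares objective is convex, so shrinking the
## search window around the grid optimum is safe) down to the requested
## final step. Exhaustive over up to 3 coefficients; independent of the
## package's solvers.
gridSearchUnmix <- function(R, s, amax, step = 0.001) {
  k <- ncol(R)
  lo <- rep(0, k)
  hi <- amax
  cur <- (hi - lo) / 20
  best <- (lo + hi) / 2
  repeat {
    cur <- pmax(cur, step)
    grids <- lapply(seq_len(k), function(i)
      pmax(seq(lo[i], hi[i], by = cur[i]), 0))
    pts <- as.matrix(expand.grid(grids))
    fit <- pts %*% t(R)                         # candidates x bands
    err <- rowSums((fit - matrix(s, nrow(pts), length(s), byrow = TRUE))^2)
    best <- pts[which.min(err), ]
    if (all(cur <= step)) break
    lo <- pmax(best - 2 * cur, 0)
    hi <- best + 2 * cur
    cur <- cur / 10
  }
  as.numeric(best)
}
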