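#' Construct seeded region-growing parameters
#'
#' @param intensityTol admissible fractional deviation of a candidate
#'   pixel's total intensity from the seed pixel's (default 0.25).
#' @param spectralTol maximum spectral angle (radians) between a candidate's
#'   spectrum and the seed spectrum (default 0.15; the angle metric makes
#'   admission brightness-invariant).
#' @param maxArea growth budget in pixels.
#' @param connectivity 4 or 8 (default 8).
#' @return a [GrowParams-class].
#' @export
growParams <- function(intensityTol = 0.25, spectralTol = 0.15,
                       maxArea = Inf, connectivity = 8L) {
  new("GrowParams", intensityTol = as.numeric(intensityTol),
      spectralTol = as.numeric(spectralTol), maxArea = as.numeric(maxArea),
      connectivity = as.integer(connectivity))
}

#' Grow a region of interest from a seed pixel
#'
#' Breadth-first admission of connected pixels whose total intensity lies
#' within `intensityTol` of the seed pixel's total intensity and whose
#' spectral angle to the seed spectrum is at most `spectralTol`, stopping
#' when `maxArea` pixels have been admitted. Mirrors the interactive
#' "seed ROI" workflow in which the software finds areas of similar
#' intensity and/or spectral composition around a user-placed seed.
#'
#' @param cube a [SpectralCube-class].
#' @param seed `(row, col)` seed pixel inside the image; must have nonzero
#'   intensity.
#' @param params a [GrowParams-class].
#' @param label label for the returned ROI.
#' @return an [ROI-class] (always containing the seed, connected under the
#'   requested connectivity).
#' @export
growRoi <- function(cube, seed, params = growParams(), label = "seed-roi") {
  d <- dim(cube@values)
  H <- d[1L]; W <- d[2L]
  seed <- as.integer(round(seed))
  if (seed[1L] < 1L || seed[1L] > H || seed[2L] < 1L || seed[2L] > W)
    sqStop("sqBounds", "seed (%d, %d) outside %dx%d image",
           seed[1L], seed[2L], H, W)
  S <- flattenCube(cube)
  tot <- rowSums(S)
  sIdx <- (seed[2L] - 1L) * H + seed[1L]
  if (tot[sIdx] <= 0)
    sqStop("sqEmptySeed", "seed pixel (%d, %d) has zero intensity",
           seed[1L], seed[2L])
  s0 <- S[sIdx, ]
  s0n <- s0 / sqrt(sum(s0^2))
  lo <- tot[sIdx] * (1 - params@intensityTol)
  hi <- tot[sIdx] * (1 + params@intensityTol)
  cosTol <- cos(params@spectralTol)
  nbr <- if (params@connectivity == 4L)
    cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
  else
    cbind(rep(-1:1, 3L), rep(-1:1, each = 3L))[-5L, , drop = FALSE]
  admitted <- logical(H * W)
  queued <- logical(H * W)
  queue <- integer(H * W)
  queue[1L] <- sIdx; queued[sIdx] <- TRUE
  head <- 1L; tail <- 1L; nAdm <- 0L
  while (head <= tail && nAdm < params@maxArea) {
    p <- queue[head]; head <- head + 1L
    pr <- (p - 1L) %% H + 1L
    pc <- (p - 1L) %/% H + 1L
    ok <- p == sIdx ||
      (tot[p] >= lo && tot[p] <= hi && tot[p] > 0 &&
       sum(S[p, ] * s0n) / sqrt(sum(S[p, ]^2)) >= cosTol)
    if (!ok) next
    admitted[p] <- TRUE; nAdm <- nAdm + 1L
    for (k in seq_len(nrow(nbr))) {
      nr <- pr + nbr[k, 1L]; nc <- pc + nbr[k, 2L]
      if (nr < 1L || nr > H || nc < 1L || nc > W) next
      q <- (nc - 1L) * H + nr
      if (!queued[q]) {
        queued[q] <- TRUE
        tail <- tail + 1L
        queue[tail] <- q
      }
    }
  }
  idx <- which(admitted)
  roi(cbind((idx - 1L) %% H + 1L, (idx - 1L) %/% H + 1L), label = label)
}

#' Segment cells from a DAPI nucleus image
#'
#' Nuclei are the connected components of the DAPI image above its Otsu
#' threshold (computed on the max-normalized image, so the result is
#' invariant to global intensity rescaling), filtered by a minimum area.
#' Each cell ROI is its nucleus dilated by `dilationPx` (Euclidean
#' distance), with contested pixels assigned to the nearest nucleus and
#' ties going to the lower label index. Labels are deterministic: nuclei
#' are numbered in raster order of their centroids.
#'
#' @param dapi numeric matrix, the DAPI reference image.
#' @param dilationPx dilation radius in pixels (default 6, sized for the
#'   disk-cell fixtures: cytoplasm extends a few pixels beyond the nucleus).
#' @param minNucleusArea smallest accepted nucleus, pixels (default 20,
#'   rejecting noise specks).
#' @return list of [ROI-class], one per cell, labeled `"cell1"`, `"cell2"`,
#'   ... in raster order; an empty list for a blank image.
#' @export
segmentCells <- function(dapi, dilationPx = 6, minNucleusArea = 20) {
  stopifnot(is.matrix(dapi))
  H <- nrow(dapi); W <- ncol(dapi)
  mx <- max(dapi)
  if (!is.finite(mx) || mx <= 0 || mx == min(dapi)) return(list())
  norm <- dapi / mx
  th <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  mask <- norm > th
  if (!any(mask)) return(list())
  lab <- EBImage::bwlabel(EBImage::Image(mask))
  lab <- EBImage::imageData(lab)
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= minNucleusArea)
  if (!length(keep)) return(list())
  ## order kept nuclei by centroid raster position (row, then col)
  cent <- t(vapply(keep, function(l) {
    ix <- which(lab == l)
    c(mean((ix - 1L) %% H + 1L), mean((ix - 1L) %/% H + 1L))
  }, numeric(2)))
  ord <- order(cent[, 1L], cent[, 2L])
  keep <- keep[ord]
  L <- length(keep)
  ## per-nucleus Euclidean distance maps: distance of every pixel to the
  ## nucleus pixel set (EBImage::distmap measures distance to the nearest
  ## zero pixel)
  D <- matrix(0, H * W, L)
  for (i in seq_len(L)) {
    m <- matrix(1, H, W)
    m[lab == keep[i]] <- 0
    D[, i] <- as.numeric(EBImage::imageData(EBImage::distmap(
      EBImage::Image(m))))
  }
  minD <- do.call(pmin, lapply(seq_len(L), function(i) D[, i]))
  assigned <- max.col(-D, ties.method = "first")  # tie -> lower label
  inCell <- minD <= dilationPx
  lapply(seq_len(L), function(i) {
    idx <- which(inCell & assigned == i)
    roi(cbind((idx - 1L) %% H + 1L, (idx - 1L) %/% H + 1L),
        label = sprintf("cell%d", i))
  })
}
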