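#' Quantify a region of interest on an abundance map
#'
#' For each library entry d: total_d = sum of that dye's coefficients over
#' the ROI pixels, average intensity int_d = total_d / area (so that
#' total = area x average intensity per pixel holds exactly), and relative
#' contribution = 100 x total_d / sum of totals over dyes. The residual
#' fraction is the summed per-pixel residual divided by (residual + total
#' signal), a QC measure of unmodeled fluorescence. An ROI with zero total
#' signal reports zero relative contributions and is flagged degenerate.
#' Background coefficients and residuals never enter the relative-percent
#' denominator (relative levels are percent of total reporter
#' fluorescence).
#'
#' @param abundanceMap an [AbundanceMap-class].
#' @param roi an [ROI-class] within the image.
#' @return `data.frame` with one row per dye and columns `label`, `dye`,
#'   `area`, `int` (average intensity per pixel), `total`, `relative_pct`,
#'   `residual_frac`, `degenerate`.
#' @export
roiReport <- function(abundanceMap, roi) {
  d <- dim(abundanceMap@coef)
  idx <- roiIndices(roi, d[1L], d[2L])
  k <- d[3L]
  A <- matrix(abundanceMap@coef, d[1L] * d[2L], k)
  tot <- if (length(idx) == 1L) A[idx, ] else colSums(A[idx, , drop = FALSE])
  area <- length(idx)
  grand <- sum(tot)
  rel <- if (grand > 0) 100 * tot / grand else rep(0, k)
  resid <- sum(abundanceMap@residual[idx])
  data.frame(label = roi@label,
             dye = dimnames(abundanceMap@coef)[[3L]],
             area = area,
             int = tot / area,
             total = tot,
             relative_pct = rel,
             residual_frac = if (resid + grand > 0) resid / (resid + grand)
                             else 0,
             degenerate = grand <= 0,
             row.names = NULL)
}

#' Per-cell profiles for a set of ROIs
#'
#' Convenience wrapper stacking [roiReport()] rows for every ROI.
#'
#' @param abundanceMap an [AbundanceMap-class].
#' @param rois list of [ROI-class].
#' @return long-format `data.frame`, one row per (ROI, dye).
#' @export
cellProfiles <- function(abundanceMap, rois) {
  do.call(rbind, lapply(rois, function(r) roiReport(abundanceMap, r)))
}

#' Reproducibility statistics across replicate images
#'
#' Computes, for every object and dye, the mean, sample standard deviation
#' (n - 1 denominator, appropriate for small replicate counts) and
#' coefficient of variation CV = 100 x sd / mean of the total fluorescence
#' across replicates, plus per-object CVs of the summed (all-dye) totals
#' and their range and arithmetic mean over objects -- the replicate
#' reproducibility summary reported for calibration-bead panels. The result
#' is invariant to the order of the replicates.
#'
#' @param reports list (one element per replicate, >= 2) of [roiReport()] /
#'   [cellProfiles()] data frames; every object label must appear in every
#'   replicate.
#' @return list with `perDye` (data.frame: label, dye, mean, sd, cv_pct),
#'   `perObject` (data.frame: label, mean, sd, cv_pct of all-dye totals),
#'   `cvRange` (range of per-object CVs) and `cvMean` (their arithmetic
#'   mean).
#' @examples
#' rep1 <- data.frame(label = "bead1", dye = "FITC", area = 10, int = 10,
#'                    total = 100, relative_pct = 100, residual_frac = 0,
#'                    degenerate = FALSE)
#' rep2 <- rep1; rep2$total <- 110
#' replicateStats(list(rep1, rep2))$perObject$cv_pct  # ~6.734
#' @export
replicateStats <- function(reports) {
  if (length(reports) < 2L)
    sqStop("sqValidation", "need at least two replicates, got %d",
           length(reports))
  labels <- unique(reports[[1L]]$label)
  for (r in seq_along(reports)) {
    missing <- setdiff(labels, reports[[r]]$label)
    if (length(missing))
      sqStop("sqMatching", "object '%s' is missing from replicate %d",
             missing[1L], r)
  }
  dyes <- unique(reports[[1L]]$dye)
  perDye <- do.call(rbind, lapply(labels, function(lb) {
    do.call(rbind, lapply(dyes, function(dy) {
      v <- vapply(reports, function(rep_)
        sum(rep_$total[rep_$label == lb & rep_$dye == dy]), numeric(1))
      m <- mean(v); s <- stats::sd(v)
      data.frame(label = lb, dye = dy, mean = m, sd = s,
                 cv_pct = if (m > 0) 100 * s / m else NA_real_)
    }))
  }))
  perObject <- do.call(rbind, lapply(labels, function(lb) {
    v <- vapply(reports, function(rep_)
      sum(rep_$total[rep_$label == lb]), numeric(1))
    m <- mean(v); s <- stats::sd(v)
    data.frame(label = lb, mean = m, sd = s,
               cv_pct = if (m > 0) 100 * s / m else NA_real_)
  }))
  list(perDye = perDye, perObject = perObject,
       cvRange = range(perObject$cv_pct, na.rm = TRUE),
       cvMean = mean(perObject$cv_pct, na.rm = TRUE))
}

#' Match objects across replicates by centroid
#'
#' Aligns a replicate's ROIs with reference ROIs by removing the optimal
#' global translation (difference of mean centroids, emulating stage
#' repositioning) and assigning each reference object its nearest translated
#' centroid. An object without a counterpart within `maxDistPx` raises a
#' matching error naming the object.
#'
#' @param refRois reference list of [ROI-class].
#' @param rois replicate list of [ROI-class] (same length).
#' @param maxDistPx matching radius after translation, pixels (default 10).
#' @return the input `rois`, reordered and relabeled to correspond
#'   one-to-one with `refRois`.
#' @export
matchRois <- function(refRois, rois, maxDistPx = 10) {
  if (length(refRois) != length(rois))
    sqStop("sqMatching", "replicate has %d objects, reference has %d",
           length(rois), length(refRois))
  c1 <- t(vapply(refRois, roiCentroid, numeric(2)))
  c2 <- t(vapply(rois, roiCentroid, numeric(2)))
  shift <- colMeans(c2) - colMeans(c1)
  c2a <- sweep(c2, 2L, shift)
  taken <- logical(length(rois))
  out <- vector("list", length(refRois))
  for (i in seq_along(refRois)) {
    dist2 <- rowSums(sweep(c2a, 2L, c1[i, ])^2)
    dist2[taken] <- Inf
    j <- which.min(dist2)
    if (sqrt(dist2[j]) > maxDistPx)
      sqStop("sqMatching",
             "no counterpart for object '%s' within %g px (nearest at %.1f px)",
             roiLabel(refRois[[i]]), maxDistPx, sqrt(dist2[j]))
    taken[j] <- TRUE
    out[[i]] <- roi(roiCoords(rois[[j]]), label = roiLabel(refRois[[i]]))
  }
  out
}

#' Classify cells into populations from their dye profiles
#'
#' Two deterministic rules. Centroid rule: assign each cell to the nearest
#' population centroid in relative-percent space (Euclidean distance over
#' the dyes named by the centroids); exact ties give `"unassigned"`.
#' Threshold rule: assign `population` when the designated marker dye's
#' relative percent is at least `threshold`, `otherwise` below it, and
#' `"unassigned"` at exact equality of an ill-posed rule (never occurs for
#' a strict threshold).
#'
#' @param profiles long-format data frame from [cellProfiles()] (columns
#'   `label`, `dye`, `relative_pct`).
#' @param centroids matrix of population centroids (rows = populations,
#'   named; columns = dyes) in relative-percent units, or `NULL` to use
#'   `thresholdRule`.
#' @param thresholdRule list with elements `dye`, `threshold`, `population`
#'   and `otherwise`.
#' @return data frame with one row per cell: `label`, `population`.
#' @export
classifyCells <- function(profiles, centroids = NULL, thresholdRule = NULL) {
  labels <- unique(profiles$label)
  if (!length(labels))
    return(data.frame(label = character(0), population = character(0)))
  if (is.null(centroids) && is.null(thresholdRule))
    sqStop("sqValidation", "supply centroids or a threshold rule")
  assign1 <- function(lb) {
    rows <- profiles[profiles$label == lb, ]
    if (!is.null(centroids)) {
      dyes <- colnames(centroids)
      if (!all(dyes %in% rows$dye))
        sqStop("sqValidation", "profile '%s' lacks dye(s): %s", lb,
               paste(setdiff(dyes, rows$dye), collapse = ", "))
      v <- rows$relative_pct[match(dyes, rows$dye)]
      d2 <- apply(centroids, 1L, function(ce) sum((v - ce)^2))
      best <- min(d2)
      hits <- which(d2 == best)
      if (length(hits) > 1L) "unassigned" else rownames(centroids)[hits]
    } else {
      v <- rows$relative_pct[rows$dye == thresholdRule$dye]
      if (!length(v))
        sqStop("sqValidation", "profile '%s' lacks dye '%s'", lb,
               thresholdRule$dye)
      if (v >= thresholdRule$threshold) thresholdRule$population
      else thresholdRule$otherwise
    }
  }
  data.frame(label = labels,
             population = vapply(labels, assign1, character(1)),
             row.names = NULL)
}

#' Detect rare cells elevated in a target dye
#'
#' The majority baseline is the median of the target dye's totals across
#' all cells (robust to the rare cells themselves); a cell is flagged when
#' its target-dye total is at least `baseline x (1 + elevationThreshold /
#' 100)`. Deterministic; raising the threshold never adds flags.
#'
#' @param profiles long-format data frame with columns `label`, `dye`,
#'   `total` (from [cellProfiles()]); at least 5 cells.
#' @param targetDye dye whose elevation marks the rare population.
#' @param elevationThreshold percent elevation above baseline required to
#'   flag (>= 0).
#' @return character vector of flagged cell labels.
#' @examples
#' pr <- data.frame(label = sprintf("c%d", 1:6), dye = "FITC",
#'                  total = c(100, 100, 100, 100, 100, 160))
#' detectRare(pr, "FITC", 50)
#' @export
detectRare <- function(profiles, targetDye, elevationThreshold = 50) {
  rows <- profiles[profiles$dye == targetDye, ]
  if (nrow(rows) < 5L)
    sqStop("sqInsufficientCells",
           "rare-cell detection needs >= 5 cells, got %d", nrow(rows))
  baseline <- stats::median(rows$total)
  rows$label[rows$total >= baseline * (1 + elevationThreshold / 100)]
}
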