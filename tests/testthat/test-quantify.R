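makeAbundance <- function(coefList, residual = NULL) {
  k <- length(coefList)
  H <- nrow(coefList[[1]]); W <- ncol(coefList[[1]])
  coef <- array(unlist(coefList), c(H, W, k),
                dimnames = list(NULL, NULL, names(coefList)))
  if (is.null(residual)) residual <- matrix(0, H, W)
  new("AbundanceMap", coef = coef, residual = residual,
      backgroundCoef = matrix(numeric(0), 0, 0))
}

test_that("ROI reports satisfy total = area x average and percentages sum to 100", {
  am <- makeAbundance(list(A = matrix(50, 10, 10), B = matrix(0, 10, 10)))
  r <- roi(as.matrix(expand.grid(1:10, 1:10)), "obj")
  rep_ <- roiReport(am, r)
  expect_equal(rep_$area, c(100, 100))
  expect_equal(rep_$total[rep_$dye == "A"], 5000)
  expect_equal(rep_$int[rep_$dye == "A"], 50)
  expect_equal(rep_$relative_pct, c(100, 0))
  expect_true(all(rep_$total == rep_$area * rep_$int))
  expect_equal(sum(rep_$relative_pct), 100, tolerance = 1e-6)
  ## two dyes at equal totals split 50/50
  am2 <- makeAbundance(list(A = matrix(20, 4, 4), B = matrix(20, 4, 4)))
  rep2 <- roiReport(am2, roi(cbind(1:4, 1:4), "diag"))
  expect_equal(rep2$relative_pct, c(50, 50))
  ## degenerate ROI: zero totals flagged, percentages zero
  am0 <- makeAbundance(list(A = matrix(0, 4, 4)))
  rep0 <- roiReport(am0, roi(cbind(1, 1)))
  expect_true(rep0$degenerate)
  expect_equal(rep0$relative_pct, 0)
})

test_that("report identities hold on random abundance maps", {
  set.seed(31)
  for (i in 1:10) {
    am <- makeAbundance(list(A = matrix(runif(64, 0, 10), 8, 8),
                             B = matrix(runif(64, 0, 10), 8, 8),
                             C = matrix(runif(64, 0, 10), 8, 8)),
                        residual = matrix(runif(64), 8, 8))
    co <- unique(cbind(sample(8, 20, TRUE), sample(8, 20, TRUE)))
    rep_ <- roiReport(am, roi(co))
    expect_equal(rep_$total, rep_$area * rep_$int)
    expect_equal(sum(rep_$relative_pct), 100, tolerance = 1e-6)
    expect_true(all(rep_$residual_frac >= 0 & rep_$residual_frac <= 1))
  }
})

test_that("replicate statistics use the sample-sd CV convention", {
  mk <- function(total) data.frame(label = "bead1", dye = "green", area = 10,
                                   int = total / 10, total = total,
                                   relative_pct = 100, residual_frac = 0,
                                   degenerate = FALSE)
  st <- replicateStats(list(mk(100), mk(110)))
  ## sd(c(100,110)) = 7.0711, mean 105 -> CV 6.7343%
  expect_equal(st$perObject$cv_pct, 100 * sd(c(100, 110)) / 105,
               tolerance = 1e-9)
  expect_equal(st$perObject$cv_pct, 6.7343, tolerance = 1e-4)
  ## identical replicates: zero CV
  st0 <- replicateStats(list(mk(100), mk(100), mk(100)))
  expect_equal(st0$perObject$cv_pct, 0)
  expect_equal(st0$cvMean, 0)
})

test_that("replicate statistics are permutation-invariant and validate matching", {
  mk <- function(lab, total) data.frame(label = lab, dye = "d", area = 1,
                                        int = total, total = total,
                                        relative_pct = 100,
                                        residual_frac = 0,
                                        degenerate = FALSE)
  r1 <- rbind(mk("a", 10), mk("b", 30))
  r2 <- rbind(mk("a", 12), mk("b", 27))
  r3 <- rbind(mk("a", 11), mk("b", 33))
  sA <- replicateStats(list(r1, r2, r3))
  sB <- replicateStats(list(r3, r1, r2))
  expect_equal(sA$perObject$cv_pct, sB$perObject$cv_pct)
  expect_equal(sA$cvRange, sB$cvRange)
  err <- tryCatch(replicateStats(list(r1, mk("a", 12))),
                  error = function(e) e)
  expect_s3_class(err, "sqMatching")
  expect_match(conditionMessage(err), "'b'")
  expect_match(conditionMessage(err), "replicate 2")
})

test_that("nine noisy bead replicates give four positive CVs and their mean", {
  st <- beadReproducibility(seed = 2, nReplicates = 9, schedule = NULL)
  expect_length(st$cvs, 4L)
  expect_true(all(st$cvs > 0))
  expect_equal(st$avgCv, mean(st$cvs))
})

test_that("centroid classification assigns fixed points and ties to unassigned", {
  centroids <- rbind(MCF7 = c(FITC = 20, Cy3.5 = 50),
                     TPC1 = c(FITC = 60, Cy3.5 = 10))
  prof <- function(lab, fitc, cy35)
    data.frame(label = lab, dye = c("FITC", "Cy3.5"), area = 1,
               int = 1, total = 1, relative_pct = c(fitc, cy35),
               residual_frac = 0, degenerate = FALSE)
  res <- classifyCells(rbind(prof("c1", 20, 50),
                             prof("c2", 60, 10),
                             prof("c3", 40, 30)), centroids = centroids)
  expect_equal(res$population, c("MCF7", "TPC1", "unassigned"))
  thr <- classifyCells(prof("c4", 55, 5),
                       thresholdRule = list(dye = "FITC", threshold = 40,
                                            population = "TPC1",
                                            otherwise = "MCF7"))
  expect_equal(thr$population, "TPC1")
  empty <- classifyCells(prof("x", 1, 1)[0, ], centroids = centroids)
  expect_equal(nrow(empty), 0L)
})

test_that("two synthetic lines separate by their relative dye profiles", {
  dyes <- c("FITC", "Cy3", "Cy3.5", "TexasRed", "Cy5", "Cy5.5")
  mcf7 <- stats::setNames(c(500, 800, 1500, 800, 800, 1400), dyes)
  tpc1 <- stats::setNames(c(1600, 800, 700, 800, 800, 700), dyes)
  correct <- 0L; total <- 0L
  for (seed in 1:5) {
    mix <- makeCellMixture(16, rareFraction = 0.5, rareElevation = 0,
                           majorityMeans = mcf7, rareMeans = tpc1,
                           noise = noiseModel("shot"), seed = seed)
    am <- unmixCube(mix$cube, trueLibrary(dyes))
    profiles <- cellProfiles(am, truthRois(mix$truth))
    relOf <- function(means) 100 * means / sum(means)
    centroids <- rbind(MCF7 = relOf(mcf7), TPC1 = relOf(tpc1))
    res <- classifyCells(profiles, centroids = centroids)
    truthPop <- ifelse(truthPopulations(mix$truth) == "rare", "TPC1",
                       "MCF7")
    correct <- correct + sum(res$population == truthPop)
    total <- total + length(truthPop)
  }
  expect_gte(correct / total, 0.95)
})

test_that("rare-cell flagging applies the median-baseline rule deterministically", {
  prof <- data.frame(label = sprintf("c%03d", 1:100), dye = "FITC",
                     total = c(rep(100, 99), 160))
  expect_equal(detectRare(prof, "FITC", 50), "c100")
  ## all identical: nothing flagged above any positive threshold
  same <- transform(prof, total = 100)
  expect_length(detectRare(same, "FITC", 50), 0L)
  expect_error(detectRare(prof[1:4, ], "FITC", 50),
               class = "sqInsufficientCells")
})

test_that("rare-cell flagging is monotone in the threshold and catches >= median at zero", {
  set.seed(41)
  prof <- data.frame(label = sprintf("c%03d", 1:50), dye = "FITC",
                     total = rlnorm(50, log(100), 0.3))
  at0 <- detectRare(prof, "FITC", 0)
  expect_gte(length(at0), 25L)          # at least half at or above median
  prev <- at0
  for (thr in c(10, 25, 50, 100)) {
    cur <- detectRare(prof, "FITC", thr)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("cross-replicate matching absorbs global translations and names failures", {
  r1 <- list(roi(cbind(10, 10), "bead1"), roi(cbind(30, 40), "bead2"))
  shifted <- list(roi(cbind(32, 41), "x"), roi(cbind(12, 11), "y"))
  m <- matchRois(r1, shifted)
  expect_equal(vapply(m, roiLabel, character(1)), c("bead1", "bead2"))
  expect_equal(roiCoords(m[[1]]), roiCoords(shifted[[2]]))
  far <- list(roi(cbind(10, 10), "x"), roi(cbind(90, 90), "y"))
  err <- tryCatch(matchRois(r1, far), error = function(e) e)
  expect_s3_class(err, "sqMatching")
})

test_that("recovered per-cell totals track ground truth over a wide brightness range", {
  dyes <- c("FITC", "Cy5")
  lib <- trueLibrary(dyes)
  truthV <- c(); recV <- c()
  for (seed in 1:8) {
    bright <- 10^runif(1, log10(500), log10(50000))
    out <- renderScene(diskScene("FITC", brightness = bright, size = 16L,
                                 radius = 3, noise = noiseModel("shot"),
                                 seed = seed))
    am <- unmixCube(acquireCube(out$cube), lib)
    rep_ <- roiReport(am, truthRois(out$truth)[[1]])
    truthV <- c(truthV, truthTotals(out$truth)[1, "FITC"])
    recV <- c(recV, rep_$total[rep_$dye == "FITC"])
  }
  expect_gt(stats::cor(truthV, recV), 0.99)
})
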