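test_that("emission spectra peak at the band nearest the dye's emission maximum", {
  g <- wavelengthGrid()
  fl <- fluorophoreCatalog()
  cases <- list(FITC = 528, DAPI = 461, Cy5 = 667, bead.deepred = 660)
  for (nm in names(cases)) {
    s <- emissionSpectrum(fl[[nm]], g)
    ctr <- bandCenters(g)
    expect_equal(ctr[which.max(intensity(s))],
                 ctr[which.min(abs(ctr - cases[[nm]]))],
                 info = nm)
    expect_equal(sum(intensity(s)), 1, tolerance = 1e-12)
  }
})

test_that("the FWHM -> 0 limit collapses all mass into one band", {
  s <- emissionSpectrum(fluorophore("x", 500, 563, fwhmNm = 1e-6),
                        wavelengthGrid())
  expect_equal(max(intensity(s)), 1)
  expect_equal(bandCenters(s)[which.max(intensity(s))], 560)
})

test_that("a peak far outside the grid warns of being out of range", {
  expect_warning(emissionSpectrum(fluorophore("uv", 300, 320, 10),
                                  wavelengthGrid()),
                 class = "sqOutOfRange")
})

test_that("a single-dye disk renders as scalar multiples of the dye spectrum", {
  out <- renderScene(diskScene("FITC", brightness = 1000))
  cube <- out$cube
  ref <- intensity(emissionSpectrum(fluorophoreCatalog()$FITC,
                                    wlGrid(cube)))
  co <- roiCoords(truthRois(out$truth)[[1]])
  for (i in c(1L, nrow(co))) {
    px <- intensity(pixelSpectrum(cube, co[i, 1], co[i, 2]))
    expect_equal(px, 1000 * ref, tolerance = 1e-9)
  }
  ## off-disk pixels are dark
  expect_equal(sum(intensity(pixelSpectrum(cube, 1, 1))), 0)
})

test_that("an empty scene with background renders the flat background spectrum", {
  sc <- sceneSpec(8, 8, list(), panel = fluorophoreCatalog()["FITC"],
                  backgroundLevel = 10)
  cube <- renderScene(sc)$cube
  expect_equal(as.numeric(cubeValues(cube)[3, 5, ]), rep(10 / 36, 36),
               tolerance = 1e-12)
})

test_that("ground truth conserves noiseless ROI sums for disjoint disks", {
  fl <- fluorophoreCatalog()
  sc <- sceneSpec(40, 40, list(
    diskObject(c(10, 10), 4, c(FITC = 300), label = "a"),
    diskObject(c(30, 30), 4, c(Cy5 = 700), label = "b")),
    panel = fl[c("FITC", "Cy5")])
  out <- renderScene(sc)
  S <- cubeValues(out$cube)
  for (i in 1:2) {
    co <- roiCoords(truthRois(out$truth)[[i]])
    roiSum <- sum(vapply(seq_len(nrow(co)), function(j)
      sum(S[co[j, 1], co[j, 2], ]), numeric(1)))
    expect_equal(roiSum, sum(truthTotals(out$truth)[i, ]),
                 tolerance = 1e-9)
  }
  expect_error(renderScene(sceneSpec(20, 20,
    list(diskObject(c(100, 100), 3, c(FITC = 1))),
    panel = fl["FITC"])), class = "sqSceneError")
})

test_that("photobleaching decays band planes geometrically and is off by default", {
  base <- diskScene("Cy3", brightness = 500)
  plain <- renderScene(base)$cube
  bleached <- base
  bleached@bleachRate <- 0.02
  bl <- renderScene(bleached)$cube
  fac <- (1 - 0.02)^(0:35)
  for (b in c(1L, 10L, 36L))
    expect_equal(cubeValues(bl)[, , b], cubeValues(plain)[, , b] * fac[b],
                 tolerance = 1e-12)
})

test_that("bead panel replicates share one layout up to translation with identical truth totals", {
  reps <- makeBeadPanel(3, noiseModel("none"), seed = 4)
  expect_length(reps, 3L)
  for (r in reps) {
    expect_equal(rownames(truthTotals(r$truth)),
                 sprintf("bead%d", 1:4))
    expect_equal(truthTotals(r$truth), truthTotals(reps[[1]]$truth))
    expect_equal(sort(colnames(truthTotals(r$truth))),
                 sort(c("bead.green", "bead.orange", "bead.red",
                        "bead.deepred")))
  }
  ## noise-free totals equal brightness x area exactly
  expect_true(all(rowSums(truthTotals(reps[[1]]$truth)) ==
                  5000 * roiArea(truthRois(reps[[1]]$truth)[[1]])))
})

test_that("shot noise makes replicate bead totals vary but stays seed-reproducible", {
  repsA <- makeBeadPanel(3, noiseModel("shot"), seed = 9)
  repsB <- makeBeadPanel(3, noiseModel("shot"), seed = 9)
  expect_identical(cubeValues(repsA[[2]]$cube), cubeValues(repsB[[2]]$cube))
  measured <- vapply(repsA, function(r) {
    co <- roiCoords(truthRois(r$truth)[[1]])
    sum(vapply(seq_len(nrow(co)), function(j)
      sum(cubeValues(r$cube)[co[j, 1], co[j, 2], ]), numeric(1)))
  }, numeric(1))
  expect_gt(stats::sd(measured), 0)
})

test_that("cell mixtures contain a deterministic count of rare cells with elevated target means", {
  mix <- makeCellMixture(100, rareFraction = 0.01, rareElevation = 50,
                         cellCv = 0, noise = noiseModel("none"), seed = 2)
  pops <- truthPopulations(mix$truth)
  expect_equal(sum(pops == "rare"), 1L)
  tt <- truthTotals(mix$truth)
  rareRet <- tt[pops == "rare", "FITC"] / mean(tt[pops == "majority", "FITC"])
  expect_equal(as.numeric(rareRet), 1.5, tolerance = 1e-9)
  expect_error(makeCellMixture(0), class = "sqEmptyScene")
})

test_that("zero elevation makes rare and majority cells exchangeable in distribution", {
  mix <- makeCellMixture(30, rareFraction = 0.5, rareElevation = 0,
                         cellCv = 0, noise = noiseModel("none"), seed = 6)
  tt <- truthTotals(mix$truth)
  pops <- truthPopulations(mix$truth)
  areas <- vapply(truthRois(mix$truth), roiArea, integer(1))
  expect_equal(colMeans(tt[pops == "rare", ] / areas[pops == "rare"]),
               colMeans(tt[pops == "majority", ] / areas[pops == "majority"]),
               tolerance = 1e-9)
})
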