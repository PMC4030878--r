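test_that("background estimation means spectra over the ROI", {
  g <- tinyGrid(nBands = 3L)
  vals <- array(7, c(4, 4, 3))
  vals[2, 1, ] <- c(1, 2, 3)
  vals[3, 1, ] <- c(5, 6, 7)
  cube <- spectralCube(vals, g)
  expect_equal(intensity(estimateBackground(cube, roi(cbind(4, 4)))),
               c(7, 7, 7))
  expect_equal(intensity(estimateBackground(cube, roi(cbind(2, 1)))),
               c(1, 2, 3))                      # singleton: exact pixel
  expect_equal(intensity(estimateBackground(cube,
                                            roi(rbind(c(2, 1), c(3, 1))))),
               c(3, 4, 5))                      # two-pixel mean
  expect_error(estimateBackground(cube, roi(cbind(9, 9))),
               class = "sqBounds")
})

test_that("background subtraction cancels exactly, clamps at zero and flags the cube", {
  g <- tinyGrid(nBands = 3L)
  cube <- spectralCube(array(rep(c(2, 5, 1), each = 4), c(2, 2, 3)), g)
  zero <- subtractBackground(cube, spectrum(c(2, 5, 1), g))
  expect_true(all(cubeValues(zero) == 0))
  expect_true(zero@backgroundSubtracted)
  ident <- subtractBackground(cube, spectrum(c(0, 0, 0), g))
  expect_equal(cubeValues(ident), cubeValues(cube))
  over <- subtractBackground(cube, spectrum(c(3, 0, 0), g))
  expect_true(all(cubeValues(over)[, , 1] == 0))     # clamped, not negative
  expect_error(subtractBackground(cube, spectrum(rep(0, 4),
                                                 tinyGrid(nBands = 4L))),
               class = "sqGridMismatch")
})

test_that("references built from single-dye scenes match the true emission spectrum", {
  out <- renderScene(diskScene("FITC", brightness = 800, background = 50))
  cube <- out$cube
  sig <- truthRois(out$truth)[[1]]
  bgRoi <- roi(rbind(c(1, 1), c(1, 2), c(2, 1), c(2, 2)), "bg")
  ref <- buildReference(cube, sig, bgRoi, "FITC")
  truth <- intensity(emissionSpectrum(fluorophoreCatalog()$FITC,
                                      wlGrid(cube)))
  expect_equal(ref$name, "FITC")
  expect_lt(sqrt(sum((intensity(ref$spectrum) - truth)^2)), 0.02)
  ## scale invariance through normalization
  out10 <- renderScene(diskScene("FITC", brightness = 8000,
                                 background = 500))
  ref10 <- buildReference(out10$cube, sig, bgRoi, "FITC")
  expect_equal(intensity(ref10$spectrum), intensity(ref$spectrum),
               tolerance = 1e-9)
  ## blank field: signal statistics equal background statistics
  blank <- renderScene(diskScene("FITC", brightness = 0, background = 50))
  expect_error(buildReference(blank$cube, sig, bgRoi, "FITC"),
               class = "sqDegenerateSpectrum")
})

test_that("pure pixels and exact mixtures un-mix exactly in both modes", {
  lib <- twoDyeLibrary()
  g <- wlGrid(lib)
  for (mode in c("clamp", "nnls")) {
    pure <- unmixPixel(spectrum(3 * intensity(lib[["A"]]), g), lib, mode)
    expect_equal(pure$coefficients, c(A = 3, B = 0), tolerance = 1e-9)
    expect_lt(pure$residual, 1e-9)
    mixed <- unmixPixel(spectrum(0.5 * intensity(lib[["A"]]) +
                                   0.5 * intensity(lib[["B"]]), g),
                        lib, mode)
    expect_equal(mixed$coefficients, c(A = 0.5, B = 0.5), tolerance = 1e-9)
  }
})

test_that("partially negative mixtures follow the clamp rule and the NNLS optimum", {
  lib <- spectralLibrary(list(
    A = spectrum(gaussIntensities(wavelengthGrid(), 540)),
    B = spectrum(gaussIntensities(wavelengthGrid(), 570))))
  g <- wlGrid(lib)
  R <- cbind(intensity(lib[["A"]]), intensity(lib[["B"]]))
  s <- R[, 1] - 0.1 * R[, 2]
  s <- pmax(s, 0)
  sp <- spectrum(s, g)
  unconstrained <- qr.solve(R, s)
  clamp <- unmixPixel(sp, lib, "clamp")
  expect_equal(unname(clamp$coefficients["B"]), 0)
  expect_equal(unname(clamp$coefficients["A"]), max(unconstrained[1], 0),
               tolerance = 1e-9)
  ## NNLS matches the refining nonnegative grid-search oracle
  nn <- unmixPixel(sp, lib, "nnls")
  oracle <- gridSearchUnmix(R, s, amax = c(2, 2))
  expect_lt(max(abs(unname(nn$coefficients) - oracle)), 0.005)
})

test_that("collinear libraries are rejected naming the offending pair", {
  g <- wavelengthGrid()
  same <- gaussIntensities(g, 600)
  lib <- spectralLibrary(list(X = spectrum(same, g),
                              Y = spectrum(same, g),
                              Z = spectrum(gaussIntensities(g, 500), g)))
  err <- tryCatch(unmixPixel(spectrum(same, g), lib),
                  error = function(e) e)
  expect_s3_class(err, "sqCollinear")
  expect_match(conditionMessage(err), "X")
  expect_match(conditionMessage(err), "Y")
})

test_that("un-mixing is scale-equivariant and permutation-consistent", {
  set.seed(21)
  lib3 <- spectralLibrary(list(
    A = spectrum(gaussIntensities(wavelengthGrid(), 520)),
    B = spectrum(gaussIntensities(wavelengthGrid(), 600)),
    C = spectrum(gaussIntensities(wavelengthGrid(), 690))))
  g <- wlGrid(lib3)
  perm <- spectralLibrary(list(C = lib3[["C"]], A = lib3[["A"]],
                               B = lib3[["B"]]))
  for (mode in c("clamp", "nnls")) {
    for (i in 1:5) {
      a <- runif(3, 0, 4)
      s <- spectrum(as.numeric(
        cbind(intensity(lib3[["A"]]), intensity(lib3[["B"]]),
              intensity(lib3[["C"]])) %*% a + runif(36, 0, 0.005)), g)
      base <- unmixPixel(s, lib3, mode)$coefficients
      c_ <- runif(1, 0.5, 10)
      scaled <- unmixPixel(spectrum(c_ * intensity(s), g), lib3,
                           mode)$coefficients
      expect_equal(scaled, c_ * base, tolerance = 1e-9)
      permuted <- unmixPixel(s, perm, mode)$coefficients
      expect_equal(permuted, base[c("C", "A", "B")], tolerance = 1e-9)
    }
  }
})

test_that("cube un-mixing recovers per-pixel truth on the five-dye transcript panel", {
  dyes <- c("FITC", "Cy3", "TexasRed", "Cy5", "Cy5.5")
  fl <- fluorophoreCatalog()[dyes]
  objs <- lapply(seq_along(dyes), function(i)
    diskObject(c(6 + 9 * ((i - 1) %/% 3), 6 + 9 * ((i - 1) %% 3)), 3,
               stats::setNames(200 * i, dyes[i]),
               label = sprintf("d%d", i)))
  sc <- sceneSpec(24, 28, objs, panel = fl)
  out <- renderScene(sc)
  am <- unmixCube(out$cube, trueLibrary(dyes))
  for (i in seq_along(dyes)) {
    co <- roiCoords(truthRois(out$truth)[[i]])
    vals <- abundance(am, dyes[i])[co]
    expect_equal(vals, rep(200 * i, nrow(co)), tolerance = 0.01)
  }
  ## zero cube: all-zero abundances and residuals
  zero <- spectralCube(array(0, c(3, 3, 36)))
  amz <- unmixCube(zero, trueLibrary(dyes))
  expect_true(all(amz@coef == 0) && all(residuals2d(amz) == 0))
})

test_that("six-dye overlapping-cell un-mixing conserves image totals within 2%", {
  dyes <- c("FITC", "Cy3", "Cy3.5", "TexasRed", "Cy5", "Cy5.5")
  mix <- makeCellMixture(6, rareFraction = 0, noise = noiseModel("none"),
                         seed = 13, spacingPx = 9L)   # overlapping cells
  am <- unmixCube(mix$cube, trueLibrary(dyes))
  tt <- colSums(truthTotals(mix$truth))
  rec <- apply(am@coef, 3L, sum)
  expect_equal(rec[dyes], tt[dyes], tolerance = 0.02)
})

test_that("a fitted background component captures flat background without dye leakage", {
  g <- wavelengthGrid()
  bgSpec <- spectrum(rep(1 / 36, 36), g)
  lib <- spectralLibrary(list(FITC = emissionSpectrum(
    fluorophoreCatalog()$FITC, g)), background = bgSpec)
  out <- renderScene(diskScene("FITC", brightness = 400, background = 90))
  am <- unmixCube(out$cube, lib)
  ## off-disk pixels: all signal goes to the background component
  expect_equal(abundance(am, "FITC")[1, 1], 0, tolerance = 1e-6)
  expect_equal(am@backgroundCoef[1, 1], 90, tolerance = 1e-6)
  ## double background handling warns
  sub <- subtractBackground(out$cube, estimateBackground(out$cube,
                                                         roi(cbind(1, 1))))
  expect_warning(unmixCube(sub, lib), class = "sqDoubleBackground")
})

test_that("RGB pseudo-color rendering picks the expected dominant channel", {
  fitc <- renderScene(diskScene("FITC", brightness = 1000))
  rgbF <- renderRgb(fitc$cube)
  co <- roiCoords(truthRois(fitc$truth)[[1]])[1, ]
  px <- rgbF[co[1], co[2], ]
  expect_true(px[3] > px[1] && px[3] > px[2])   # FITC 528 nm -> blue band
  deep <- renderScene(diskScene("bead.deepred", brightness = 1000))
  pxD <- renderRgb(deep$cube)[co[1], co[2], ]
  expect_true(pxD[1] > pxD[2] && pxD[1] > pxD[3])  # 660 nm -> red band
  expect_true(all(renderRgb(spectralCube(array(0, c(2, 2, 36)))) == 0))
  expect_error(renderRgb(fitc$cube, list(red = c(900, 950),
                                         green = c(561, 635),
                                         blue = c(475, 557))),
               class = "sqEmptyBand")
})

test_that("noisy ROI total abundances stay within 5% of truth in 95% of runs", {
  dyes <- c("FITC", "Cy5")
  lib <- trueLibrary(dyes)
  ok <- vapply(1:50, function(seed) {
    out <- renderScene(diskScene("FITC", brightness = 5000, size = 16L,
                                 radius = 3,
                                 noise = noiseModel("shot"), seed = seed))
    am <- unmixCube(out$cube, lib)
    rep_ <- roiReport(am, truthRois(out$truth)[[1]])
    truthTot <- truthTotals(out$truth)[1, "FITC"]
    abs(rep_$total[rep_$dye == "FITC"] - truthTot) / truthTot < 0.05
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})
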