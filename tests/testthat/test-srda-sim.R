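test_that("simulated counts are linear in scene reflectance", {
  cam <- tinyCamera()
  m <- noiseFreeModel(cam)
  f1 <- simulateMosaicFrame(makeTileScene(flatSpectrum(0.8), c(8, 8)),
                            cam, m)
  f2 <- simulateMosaicFrame(makeTileScene(flatSpectrum(0.4), c(8, 8)),
                            cam, m)
  ratio <- (pixelData(f1) - m@darkLevel) / (pixelData(f2) - m@darkLevel)
  expect_equal(max(abs(ratio - 2)), 0, tolerance = 1e-9)

  # zero-reflectance scene gives the dark level exactly (noise off)
  f0 <- simulateMosaicFrame(makeTileScene(flatSpectrum(0), c(8, 8)), cam, m)
  expect_true(all(pixelData(f0) == m@darkLevel))

  # a 95% flat scene equals the white-reference generator output
  w1 <- simulateMosaicFrame(makeTileScene(flatSpectrum(0.95), c(8, 8)),
                            cam, m)
  pair <- makeReferencePair(cam, m, c(8, 8), n = 1)
  expect_equal(pixelData(w1), pixelData(pair@white), tolerance = 1e-12)
})

test_that("seeded simulation is deterministic; seeds decorrelate noise", {
  cam <- tinyCamera()
  m <- noisyModel(cam)
  scn <- makeTileScene(flatSpectrum(0.6), c(16, 16))
  a <- simulateMosaicFrame(scn, cam, m, seed = 7)
  b <- simulateMosaicFrame(scn, cam, m, seed = 7)
  expect_identical(pixelData(a), pixelData(b))
  c <- simulateMosaicFrame(scn, cam, m, seed = 8)
  expect_gt(max(abs(pixelData(a) - pixelData(c))), 0)
})

test_that("white and dark references behave physically", {
  cam <- cameraPreset("VIS")
  m <- noisyModel(cam)
  set.seed(10)
  pair <- makeReferencePair(cam, m, c(32, 32), n = 30)
  W <- pixelData(pair@white); D <- pixelData(pair@dark)
  expect_true(all(W > D))
  # dark frame mean = dark level within averaged read noise
  expect_lt(abs(mean(D) - m@darkLevel), 3 * m@readNoiseSd / sqrt(30 * 32))
  # calibrating the white frame against itself returns 0.95
  cal <- calibrate(reconstructHypercube(pair@white), pair)
  expect_true(all(abs(pixelData(cal) - 0.95) < 1e-12))
})

test_that("inactive mosaic cells record dark and read noise only", {
  cam <- cameraPreset("NIR")  # cell (5,5) inactive
  m <- noiseFreeModel(cam)
  fr <- simulateMosaicFrame(makeTileScene(flatSpectrum(0.9), c(10, 10)),
                            cam, m)
  expect_equal(pixelData(fr)[5, 5], m@darkLevel)
  expect_equal(pixelData(fr)[10, 10], m@darkLevel)
  expect_gt(pixelData(fr)[1, 1], m@darkLevel)
})

test_that("tile scenes are spatially constant with the given spectrum", {
  sp <- tileSpectrum("cyan")
  scn <- makeTileScene(sp, c(12, 16))
  expect_true(all(scn@weights == 1))
  expect_equal(dim(scn@weights), c(12L, 16L))
  expect_identical(scn@spectrumHigh@values, sp@values)
  expect_error(makeTileScene(SpectralCurve(c(400, 500), c(0.5, 1.2)),
                             c(8, 8)), "\\[0, 1\\]")
})

test_that("sine scenes encode the analytic modulation", {
  scn <- makeSineScene(0.05, 0.3, 0.5, "vertical", c(64, 8))
  # reconstruct R(row) from the blend and check extrema
  hi <- scn@spectrumHigh@values[1]; lo <- scn@spectrumLow@values[1]
  r <- scn@weights[, 1] * hi + (1 - scn@weights[, 1]) * lo
  expect_equal(max(r), 0.8, tolerance = 1e-3)
  expect_equal(min(r), 0.2, tolerance = 1e-3)
  expect_equal(michelsonContrast(max(r), min(r)), 0.6, tolerance = 1e-2)
  # amplitude 0 is a flat scene (blend endpoints coincide)
  flat <- makeSineScene(0.05, 0, 0.5, extent = c(16, 16))
  hf <- flat@spectrumHigh@values[1]; lf <- flat@spectrumLow@values[1]
  rFlat <- flat@weights * hf + (1 - flat@weights) * lf
  expect_equal(diff(range(rFlat)), 0)
  expect_error(makeSineScene(0.05, 0.6, 0.5), "within")
})

test_that("USAF scenes draw bars at the exact geometric width", {
  us <- makeUsafScene(data.frame(group = 1, element = 1),
                      mmPerPixel = 0.025)
  # 0.250 mm at 0.025 mm/px = 10 px bars
  expect_equal(us$elements$widthPx, c(10L, 10L))
  w <- us$scene@weights
  # three dark bars of exactly 10 rows along the vertical profile column
  colIdx <- us$elements$c0[1]
  runs <- rle(w[, colIdx] == 0)
  expect_equal(runs$lengths[runs$values], c(10, 10, 10))
  expect_error(makeUsafScene(data.frame(group = 5, element = 6),
                             mmPerPixel = 0.025), "unprintable")
})

test_that("end-to-end spectral recovery matches the generating spectra", {
  cam <- cameraPreset("VIS")
  ext <- c(48, 48)
  # noise-free: RMSE < 0.5% per tile
  m0 <- noiseFreeModel(cam)
  pair0 <- makeReferencePair(cam, m0, ext, n = 1)
  for (nm in c("red", "blue", "orange")) {
    sp <- tileSpectrum(nm)
    fr <- simulateMosaicFrame(makeTileScene(sp, ext), cam, m0)
    cube <- calibrate(reconstructHypercube(fr), pair0)
    meas <- roiMeanSpectrum(cube, matrix(TRUE, 12, 12))
    ref <- resampleReference(sp, bandCenters(cam))$curve
    expect_lt(spectralRMSE(curveValues(meas), curveValues(ref)), 0.5)
  }
  # with shot + read noise and 30-frame averaging: RMSE < 2%
  m1 <- noisyModel(cam)
  set.seed(201)
  pair1 <- makeReferencePair(cam, m1, ext, n = 30)
  sp <- tileSpectrum("green")
  frames <- simulateFrameSequence(makeTileScene(sp, ext), cam, m1, 30)
  cube <- calibrate(reconstructHypercube(temporalAverage(frames)), pair1)
  meas <- roiMeanSpectrum(cube, matrix(TRUE, 12, 12))
  ref <- resampleReference(sp, bandCenters(cam))$curve
  expect_lt(spectralRMSE(curveValues(meas), curveValues(ref)), 2)
})

test_that("zero-noise simulator round trip recovers band-integrated
           reflectance to 1e-6", {
  cam <- tinyCamera()
  m <- noiseFreeModel(cam)
  sp <- tileSpectrum("violet")
  fr <- simulateMosaicFrame(makeTileScene(sp, c(8, 8)), cam, m)
  pair <- makeReferencePair(cam, m, c(8, 8), n = 1)
  cube <- calibrate(reconstructHypercube(fr), pair)
  # oracle: the illuminant- and filter-weighted band average of the scene
  # reflectance (what an ideal instrument reports after white calibration)
  grid <- m@illuminant@wavelengthsNm
  L <- m@illuminant@values
  Tb <- gaussianFilterBank(cam, grid)@transmission
  R <- approx(sp@wavelengthsNm, sp@values, xout = grid, rule = 2)$y
  expected <- as.numeric((Tb %*% (L * R)) / (Tb %*% L))
  for (b in seq_len(4))
    expect_lt(max(abs(pixelData(cube)[, , b] - expected[b])), 1e-6)
})
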