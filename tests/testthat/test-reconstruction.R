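test_that("reconstruction picks each band from its own tile cell", {
  cam <- tinyCamera()
  # pixel value = band index of its cell, so every cube voxel must equal
  # its band index
  cb <- cam@layout@cellBand
  px <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8)
    px[i, j] <- cb[(i - 1) %% 2 + 1, (j - 1) %% 2 + 1]
  cube <- reconstructHypercube(new("RawMosaicFrame", pixels = px,
                                   camera = cam, meta = list()))
  expect_equal(dim(pixelData(cube)), c(4L, 4L, 4L))
  for (b in 1:4)
    expect_true(all(pixelData(cube)[, , b] == b))

  # constant frame -> constant cube
  cube2 <- reconstructHypercube(new("RawMosaicFrame",
                                    pixels = matrix(7, 8, 8),
                                    camera = cam, meta = list()))
  expect_true(all(pixelData(cube2) == 7))

  # VIS frame gives 16 bands at quarter resolution
  vis <- cameraPreset("VIS")
  fr <- new("RawMosaicFrame", pixels = matrix(1, 16, 32), camera = vis,
            meta = list())
  expect_equal(dim(pixelData(reconstructHypercube(fr))), c(4L, 8L, 16L))
})

test_that("inactive cells are never read", {
  cam <- cameraSpec("gap", c(500, 520, 540), 2L)  # cell (2,2) inactive
  px <- matrix(c(1, 3, 2, 999), 2, 2)  # poison the inactive cell
  cube <- reconstructHypercube(new("RawMosaicFrame", pixels = px,
                                   camera = cam, meta = list()))
  expect_equal(as.numeric(pixelData(cube)[1, 1, ]), c(1, 2, 3))
})

test_that("temporal averaging is the element-wise mean and shrinks noise", {
  cam <- tinyCamera()
  mk <- function(v) new("RawMosaicFrame", pixels = matrix(v, 4, 4),
                        camera = cam, meta = list())
  expect_equal(pixelData(temporalAverage(list(mk(5)))), matrix(5, 4, 4))
  expect_equal(pixelData(temporalAverage(list(mk(2), mk(4)))),
               matrix(3, 4, 4))
  expect_error(temporalAverage(list()), "at least one")
  expect_error(
    temporalAverage(list(matrix(1, 2, 2), matrix(1, 3, 3))), "mismatch")

  # SE of the 30-frame mean is ~ 1/sqrt(30) of the single-frame SD
  set.seed(7)
  n <- 30
  singleSDs <- meanSDs <- numeric(40)
  for (k in 1:40) {
    frames <- replicate(n, matrix(rnorm(64, 100, 5), 8, 8),
                        simplify = FALSE)
    singleSDs[k] <- frames[[1]][1, 1]
    meanSDs[k] <- temporalAverage(frames)[1, 1]
  }
  ratio <- stats::sd(meanSDs) / stats::sd(singleSDs)
  expect_lt(ratio, 1.6 / sqrt(n))
  expect_gt(ratio, 0.6 / sqrt(n))
})

test_that("averaging commutes with reconstruction", {
  cam <- tinyCamera()
  set.seed(21)
  frames <- replicate(5, new("RawMosaicFrame",
                             pixels = matrix(runif(64, 10, 100), 8, 8),
                             camera = cam, meta = list()),
                      simplify = FALSE)
  a <- reconstructHypercube(temporalAverage(frames))
  b <- temporalAverage(lapply(frames, reconstructHypercube))
  expect_equal(pixelData(a), pixelData(b), tolerance = 1e-12)
})

test_that("calibration maps white to 0.95, dark to 0, and is exact", {
  mkCube <- function(v) Hypercube(array(v, c(2, 2, 2)), c(500, 600))
  pair <- calibrationPair(mkCube(9), mkCube(1))
  expect_true(all(pixelData(calibrate(mkCube(9), pair)) == 0.95))
  expect_true(all(pixelData(calibrate(mkCube(1), pair)) == 0))
  # R = 0.95 * (5 - 1) / (9 - 1) = 0.475
  expect_equal(pixelData(calibrate(mkCube(5), pair))[1, 1, 1], 0.475)
  # unity white standard gives relative reflectance
  pair1 <- calibrationPair(mkCube(9), mkCube(1), whiteReflectance = 1)
  expect_equal(pixelData(calibrate(mkCube(5), pair1))[1, 1, 1], 0.5)
})

test_that("calibration is invariant to global illumination gain", {
  set.seed(5)
  I <- array(runif(32, 50, 500), c(4, 4, 2))
  W <- array(runif(32, 600, 900), c(4, 4, 2))
  D <- array(runif(32, 50, 60), c(4, 4, 2))
  mk <- function(a) Hypercube(a, c(500, 600))
  r1 <- calibrate(mk(I), calibrationPair(mk(W), mk(D)))
  k <- 3.7  # scale I - D and W - D by the same gain
  r2 <- calibrate(mk(k * (I - D) + D), calibrationPair(mk(k * (W - D) + D),
                                                       mk(D)))
  expect_equal(pixelData(r1), pixelData(r2), tolerance = 1e-12)
})

test_that("near-zero white-dark denominators are flagged invalid", {
  W <- array(9, c(2, 2, 1)); W[1, 1, 1] <- 1
  D <- array(1, c(2, 2, 1))
  pair <- calibrationPair(Hypercube(W, 500), Hypercube(D, 500))
  cal <- calibrate(Hypercube(array(5, c(2, 2, 1)), 500), pair)
  expect_true(is.na(pixelData(cal)[1, 1, 1]))
  expect_equal(cal@meta$nInvalid, 1L)
  # all-invalid calibration is an error
  badPair <- calibrationPair(Hypercube(D, 500), Hypercube(D, 500))
  expect_error(calibrate(Hypercube(array(5, c(2, 2, 1)), 500), badPair),
               "calibration failed")
})

test_that("glare clipping thresholds and counts", {
  d <- array(0.5, c(3, 3, 2))
  cube <- Hypercube(d, c(500, 600), kind = "reflectance")
  expect_equal(clipGlare(cube)@meta$nClipped, 0L)
  expect_equal(pixelData(clipGlare(cube)), d)

  d[2, 2, 1] <- 1.7
  cube2 <- Hypercube(d, c(500, 600), kind = "reflectance")
  out <- clipGlare(cube2)
  expect_equal(pixelData(out)[2, 2, 1], 1.0)
  expect_equal(out@meta$nClipped, 1L)
  # a permissive ceiling is the identity
  expect_equal(pixelData(clipGlare(cube2, maxValue = 2)), d)
})

test_that("ROI mean spectra average masked pixels and skip invalid ones", {
  d <- array(0, c(2, 2, 2))
  d[, , 1] <- matrix(c(0.2, 0.4, 0.6, 0.8), 2, 2)
  d[, , 2] <- 0.5
  cube <- Hypercube(d, c(500, 600), kind = "reflectance")
  mask <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  cur <- roiMeanSpectrum(cube, mask)
  expect_equal(curveValues(cur), c(0.3, 0.5))
  expect_equal(wavelengths(cur), c(500, 600))
  expect_error(roiMeanSpectrum(cube, matrix(FALSE, 2, 2)), "empty")

  # invalid pixel excluded band-wise; clipped glare raises the mean when
  # the glare pixel stays in the mask
  d[1, 1, 1] <- NA
  cur2 <- roiMeanSpectrum(Hypercube(d, c(500, 600), kind = "reflectance"),
                          mask)
  expect_equal(curveValues(cur2)[1], 0.4)
  d3 <- array(0.5, c(3, 1, 1)); d3[3, 1, 1] <- 1.0  # clipped glare pixel
  cube3 <- Hypercube(d3, 500, kind = "reflectance")
  withGlare <- curveValues(roiMeanSpectrum(cube3, matrix(TRUE, 3, 1)))
  without <- curveValues(roiMeanSpectrum(cube3,
                                         matrix(c(TRUE, TRUE, FALSE), 3, 1)))
  expect_gt(withGlare, without)
})
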