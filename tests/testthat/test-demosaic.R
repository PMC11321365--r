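# All demosaicing flatness checks run on the native-scale field (display
# min-max normalization of a near-constant image would stretch its residual
# ripple to full range by construction).

flatAndWhite <- function(camera, extent, reflectance = 0.6) {
  m <- pureModulationModel(camera)
  list(raw = simulateMosaicFrame(makeTileScene(flatSpectrum(reflectance),
                                               extent), camera, m),
       white = simulateMosaicFrame(makeTileScene(flatSpectrum(0.95),
                                                 extent), camera, m))
}

test_that("WRC cancels the white frame exactly and is scale invariant", {
  fw <- flatAndWhite(cameraPreset("VIS"), c(64, 64))
  out <- demosaicWRC(fw$raw, fw$white)
  expect_equal(relResidualSD(out@field), 0)
  # raw = white -> constant ratio -> degenerate normalization to zeros
  same <- demosaicWRC(fw$white, fw$white)
  expect_true(all(same@image == 0))
  # raw = 0.5 * white: identical output (ratio constant at 0.5)
  half <- new("RawMosaicFrame", pixels = fw$white@pixels * 0.5,
              camera = fw$white@camera, meta = list())
  expect_equal(demosaicWRC(half, fw$white)@image, same@image)
})

test_that("WRC absorbs arbitrary per-cell gain fields", {
  cam <- tinyCamera()
  set.seed(2)
  base <- matrix(runif(64, 100, 200), 8, 8)
  white <- matrix(runif(64, 500, 900), 8, 8)
  gain <- matrix(rep(c(0.5, 2, 1.5, 0.8), 16)[1:64], 8, 8)
  mk <- function(px) new("RawMosaicFrame", pixels = px, camera = cam,
                         meta = list())
  a <- demosaicWRC(mk(base), mk(white))
  b <- demosaicWRC(mk(base * gain), mk(white * gain))
  expect_equal(a@image, b@image, tolerance = 1e-12)
})

test_that("WRC flags sub-eps white pixels invalid", {
  cam <- tinyCamera()
  white <- matrix(800, 8, 8); white[3, 3] <- 0
  mk <- function(px) new("RawMosaicFrame", pixels = px, camera = cam,
                         meta = list())
  out <- demosaicWRC(mk(matrix(400, 8, 8)), mk(white))
  expect_true(is.na(out@image[3, 3]))
  expect_equal(out@params$nInvalid, 1L)
  expect_error(demosaicWRC(mk(matrix(1, 8, 8)), mk(matrix(0, 8, 8))),
               "usable")
})

test_that("LPF removes mosaic harmonics from a flat modulated scene", {
  for (nm in c("VIS", "NIR")) {
    cam <- cameraPreset(nm)
    ext <- if (nm == "NIR") c(120, 120) else c(128, 128)
    fw <- flatAndWhite(cam, ext)
    out <- demosaicLPF(fw$raw)
    expect_lt(relResidualSD(out@field), 0.01)
  }
  # constant image passes through (only DC present)
  cam <- tinyCamera()
  cst <- new("RawMosaicFrame", pixels = matrix(5, 16, 16), camera = cam,
             meta = list())
  expect_equal(relResidualSD(demosaicLPF(cst)@field), 0)
})

test_that("LPF preserves low-frequency scene content", {
  cam <- cameraPreset("VIS")
  m <- pureModulationModel(cam)
  scn <- makeSineScene(1 / 32, 0.2, 0.5, "horizontal", c(128, 128))
  fld <- demosaicLPF(simulateMosaicFrame(scn, cam, m))@field
  fit <- fitSineProfile(colMeans(fld), 1 / 32)
  relAmp <- fit@amplitude / fit@offset
  expect_lt(abs(relAmp - 0.4) / 0.4, 0.02)  # analytic 0.2/0.5
})

test_that("FC kernels are tile sums normalized to unit mean", {
  cam <- tinyCamera()
  # frame equal to one repeated tile: H is the tile normalized to mean 1
  tile <- matrix(c(2, 6, 4, 8), 2, 2)
  px <- tile[rep(1:2, 4), rep(1:2, 4)]
  k <- formFCKernel(new("RawMosaicFrame", pixels = px, camera = cam,
                        meta = list()))
  expect_equal(k@H, tile / mean(tile))
  expect_equal(k@Hinv, mean(tile) / tile)

  # constant raw gives all-ones kernels
  k1 <- formFCKernel(new("RawMosaicFrame", pixels = matrix(3, 8, 8),
                         camera = cam, meta = list()))
  expect_equal(k1@H, matrix(1, 2, 2))

  # kernel size follows the mosaic period
  fw <- flatAndWhite(cameraPreset("NIR"), c(40, 40))
  expect_equal(dim(formFCKernel(fw$raw)@H), c(5L, 5L))
  # inactive cell carries the active-cell mean
  expect_equal(formFCKernel(fw$raw)@H[5, 5], 1)

  zero <- new("RawMosaicFrame", pixels = matrix(0, 8, 8), camera = cam,
              meta = list())
  expect_error(formFCKernel(zero), "zero filter-cell sum")
})

test_that("FC flattens modulation and is invariant to global scaling", {
  for (nm in c("VIS", "RNIR", "NIR")) {
    cam <- cameraPreset(nm)
    ext <- if (nm == "NIR") c(120, 120) else c(128, 128)
    fw <- flatAndWhite(cam, ext)
    out <- demosaicFC(fw$raw)
    expect_lt(relResidualSD(out@field), 0.02)
  }
  # global intensity scale invariance
  cam <- cameraPreset("VIS")
  fw <- flatAndWhite(cam, c(64, 64))
  scaled <- new("RawMosaicFrame", pixels = fw$raw@pixels * 2.5,
                camera = cam, meta = list())
  expect_equal(demosaicFC(fw$raw)@image, demosaicFC(scaled)@image,
               tolerance = 1e-9)
  # constant raw -> constant output
  cst <- new("RawMosaicFrame", pixels = matrix(4, 16, 16),
             camera = tinyCamera(), meta = list())
  expect_equal(relResidualSD(demosaicFC(cst)@field), 0)
})

test_that("FC keeps step edges sharp (10-90% rise within 2 periods)", {
  cam <- cameraPreset("VIS")
  m <- pureModulationModel(cam)
  w <- matrix(1, 128, 128); w[, 65:128] <- 0
  scn <- new("SceneSpec", weights = w, spectrumHigh = flatSpectrum(0.9),
             spectrumLow = flatSpectrum(0.1), mmPerPixel = 0.05)
  fld <- demosaicFC(simulateMosaicFrame(scn, cam, m))@field
  pr <- colMeans(fld[33:96, ])
  hi <- mean(pr[1:40]); lo <- mean(pr[89:128])
  i10 <- max(which(pr >= hi - 0.1 * (hi - lo)))
  i90 <- min(which(pr <= hi - 0.9 * (hi - lo)))
  expect_lte(i90 - i10, 2 * mosaicPeriod(cam))
})

test_that("demosaicing is deterministic", {
  fw <- flatAndWhite(cameraPreset("VIS"), c(64, 64))
  expect_identical(demosaicLPF(fw$raw)@image, demosaicLPF(fw$raw)@image)
  expect_identical(demosaicFC(fw$raw)@image, demosaicFC(fw$raw)@image)
  expect_identical(demosaicWRC(fw$raw, fw$white)@image,
                   demosaicWRC(fw$raw, fw$white)@image)
})

test_that("unsharp masking behaves as documented", {
  set.seed(9)
  img <- matrix(runif(256, 0.2, 0.8), 16, 16)
  expect_equal(unsharpMask(img, amount = 0), img)
  expect_equal(unsharpMask(matrix(0.5, 16, 16)), matrix(0.5, 16, 16))

  # sinusoid of period 8 px gains amplitude; closed-form Gaussian MTF
  # attenuation at f = 1/8, sigma = 1 predicts the boost
  x <- 0:63
  prof <- 0.5 + 0.2 * sin(2 * pi * x / 8)
  img2 <- matrix(rep(prof, each = 32), 32, 64)
  sharp <- unsharpMask(img2, sigma = 1, amount = 0.5)
  fit <- fitSineProfile(sharp[16, ], 1 / 8)
  atten <- exp(-2 * pi^2 * 1^2 * (1 / 8)^2)  # continuous-domain estimate
  predicted <- 0.2 * (1 + 0.5 * (1 - atten))
  expect_gt(fit@amplitude, 0.2)
  expect_equal(fit@amplitude, predicted, tolerance = 0.02)
  expect_error(unsharpMask(img, sigma = 0), "sigma")
})
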