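# Forward simulator of snapshot-mosaic acquisition: synthetic reflectance
# scenes imaged through a filter bank under a broadband illuminant with dark
# offset, shot and read noise.

#' Flat (wavelength-constant) spectrum
#' @param value reflectance in `[0, 1]`.
#' @param range wavelength range covered (nm).
#' @param label curve label.
#' @return a [SpectralCurve-class].
#' @export
flatSpectrum <- function(value, range = c(300, 1100), label = "flat") {
  SpectralCurve(range, c(value, value), label = label)
}

#' Halogen-like illuminant
#'
#' Relative spectral power of a tungsten-halogen source modeled as a
#' 3200 K Planck curve (normalized to peak 1 on the grid). Power density
#' rises from the short-visible toward the NIR, which is why short-VIS
#' bands of halogen-lit systems are light-starved.
#'
#' @param grid wavelength grid (nm), default 360-1000 nm at 1 nm.
#' @param temperatureK color temperature (K).
#' @return a [SpectralCurve-class].
#' @export
halogenIlluminant <- function(grid = seq(360, 1000, by = 1),
                              temperatureK = 3200) {
  c2 <- 1.4387769e7  # second radiation constant, nm K
  B <- grid^-5 / (exp(c2 / (grid * temperatureK)) - 1)
  SpectralCurve(grid, B / max(B), label = "halogen")
}

#' Construct an acquisition model
#'
#' @param illuminant a [SpectralCurve-class] of relative spectral power;
#'   default [halogenIlluminant()].
#' @param darkLevel dark-current offset in counts (default 60).
#' @param gain counts per unit band-integrated radiance (see
#'   [exposureGain()] for an exposure rule).
#' @param readNoiseSd read noise SD in counts (default 2).
#' @param shotNoise include shot noise (Gaussian, variance = signal counts;
#'   adequate above ~100 counts).
#' @return an [AcquisitionModel-class].
#' @export
acquisitionModel <- function(illuminant = halogenIlluminant(),
                             darkLevel = 60, gain = 1, readNoiseSd = 2,
                             shotNoise = TRUE) {
  new("AcquisitionModel", illuminant = illuminant, darkLevel = darkLevel,
      gain = gain, readNoiseSd = readNoiseSd, shotNoise = shotNoise)
}

# Per-band integrated signal coefficients for a spectrum (counts at gain 1):
# sum_lambda L(lambda) R(lambda) T_b(lambda) dlambda on the illuminant grid
# (rectangular quadrature; scene spectra are edge-extended beyond their
# support).
.bandCoefficients <- function(spectrum, camera, model) {
  grid <- model@illuminant@wavelengthsNm
  bc <- camera@bandCentersNm
  if (min(bc) < min(grid) || max(bc) > max(grid))
    stop("illuminant does not cover the camera's filter support")
  fb <- gaussianFilterBank(camera, grid)
  L <- model@illuminant@values
  R <- stats::approx(spectrum@wavelengthsNm, spectrum@values, xout = grid,
                     method = "linear", rule = 2)$y
  dl <- mean(diff(grid))
  as.numeric(fb@transmission %*% (L * R)) * dl
}

#' Simulate a raw mosaic frame
#'
#' For the pixel at (x, y) sampling band b (per the mosaic layout),
#' `counts = dark + gain * sum_lambda L(lambda) R(x, y, lambda) T_b(lambda)
#' dlambda + noise`, clipped to the ADC range. Inactive cells record dark
#' level plus read noise only.
#'
#' @param scene a [SceneSpec-class]; its weight-map dimensions (which must
#'   divide the mosaic period) set the frame size.
#' @param camera a [CameraSpec-class].
#' @param model an [AcquisitionModel-class].
#' @param seed optional RNG seed for the noise draw; identical seeds give
#'   identical frames.
#' @return a [RawMosaicFrame-class].
#' @export
simulateMosaicFrame <- function(scene, camera, model, seed = NULL) {
  stopifnot(is(scene, "SceneSpec"), is(camera, "CameraSpec"),
            is(model, "AcquisitionModel"))
  W <- scene@weights
  p <- mosaicPeriod(camera)
  if (any(dim(W) %% p != 0L))
    stop(sprintf("scene extent %dx%d must divide the mosaic period %d",
                 nrow(W), ncol(W), p))
  aHi <- .bandCoefficients(scene@spectrumHigh, camera, model)
  aLo <- .bandCoefficients(scene@spectrumLow, camera, model)
  cb <- camera@layout@cellBand
  # band index per sensor pixel (NA at inactive cells)
  bmap <- cb[cbind(rep_len(rep(seq_len(p), length.out = nrow(W)),
                           nrow(W) * ncol(W)),
                   rep(rep(seq_len(p), length.out = ncol(W)),
                       each = nrow(W)))]
  dim(bmap) <- dim(W)
  hi <- lo <- matrix(0, nrow(W), ncol(W))
  act <- !is.na(bmap)
  hi[act] <- aHi[bmap[act]]
  lo[act] <- aLo[bmap[act]]
  signal <- model@gain * (W * hi + (1 - W) * lo)
  if (!is.null(seed)) set.seed(seed)
  counts <- model@darkLevel + signal
  if (model@shotNoise)
    counts <- counts + stats::rnorm(length(signal),
                                    sd = sqrt(pmax(signal, 0)))
  if (model@readNoiseSd > 0)
    counts <- counts + stats::rnorm(length(signal), sd = model@readNoiseSd)
  full <- 2^camera@bitDepth - 1
  counts <- pmin(pmax(counts, 0), full)
  dim(counts) <- dim(W)
  new("RawMosaicFrame", pixels = counts, camera = camera,
      meta = list(simulated = TRUE))
}

#' Simulate a burst of frames
#'
#' @inheritParams simulateMosaicFrame
#' @param n number of frames.
#' @param seed optional seed set once before the burst (frames then draw
#'   independent noise).
#' @return list of [RawMosaicFrame-class].
#' @export
simulateFrameSequence <- function(scene, camera, model, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n), function(i)
    simulateMosaicFrame(scene, camera, model, seed = NULL))
}

#' Exposure rule: gain that nearly saturates on the white standard
#'
#' Mirrors the acquisition protocol of maximizing intensity on a white
#' reference without saturating: returns the gain at which the brightest
#' band of a 95% reflectance surface reaches `fraction` of full scale.
#'
#' @param camera a [CameraSpec-class].
#' @param model an [AcquisitionModel-class] (its gain is ignored).
#' @param fraction target fraction of full scale (default 0.9).
#' @param whiteReflectance reflectance of the standard (default 0.95).
#' @return the gain (counts per unit band-integrated radiance).
#' @export
exposureGain <- function(camera, model, fraction = 0.9,
                         whiteReflectance = 0.95) {
  a <- .bandCoefficients(flatSpectrum(whiteReflectance), camera, model)
  full <- 2^camera@bitDepth - 1
  (fraction * full - model@darkLevel) / max(a)
}

#' Simulate white and dark calibration references
#'
#' The white reference images a flat 95% reflectance (Spectralon-like)
#' surface; the dark reference is acquired with the light blocked (signal
#' zero, counts = dark level + read noise). Both are temporally averaged
#' over `n` frames.
#'
#' @inheritParams simulateMosaicFrame
#' @param extent frame extent `c(rows, cols)`.
#' @param n frames to average (default 30, the validation protocol).
#' @param seed optional seed.
#' @param whiteReflectance reflectance of the white standard.
#' @return a [CalibrationPair-class] of averaged [RawMosaicFrame-class]s.
#' @export
makeReferencePair <- function(camera, model, extent, n = 30, seed = NULL,
                              whiteReflectance = 0.95) {
  if (!is.null(seed)) set.seed(seed)
  whiteScene <- makeTileScene(flatSpectrum(whiteReflectance), extent)
  darkScene <- makeTileScene(flatSpectrum(0), extent)
  darkModel <- acquisitionModel(model@illuminant, model@darkLevel,
                                model@gain, model@readNoiseSd,
                                shotNoise = FALSE)
  white <- temporalAverage(simulateFrameSequence(whiteScene, camera, model, n))
  dark <- temporalAverage(simulateFrameSequence(darkScene, camera,
                                                darkModel, n))
  calibrationPair(white, dark, whiteReflectance = whiteReflectance)
}

#' Flat reflectance-tile scene
#'
#' Spatially constant reflectance equal to the given spectrum, emulating a
#' Spectralon calibration tile.
#'
#' @param spectrum a [SpectralCurve-class] with values in `[0, 1]`.
#' @param extent scene extent `c(rows, cols)` in pixels (scalar = square).
#' @param mmPerPixel physical pitch (mm/pixel).
#' @return a [SceneSpec-class].
#' @export
makeTileScene <- function(spectrum, extent, mmPerPixel = 0.05) {
  extent <- rep_len(extent, 2)
  if (any(spectrum@values < 0 | spectrum@values > 1))
    stop("tile spectrum must lie in [0, 1]")
  new("SceneSpec", weights = matrix(1, extent[1], extent[2]),
      spectrumHigh = spectrum, spectrumLow = flatSpectrum(0),
      mmPerPixel = mmPerPixel)
}

#' Sinusoidal test-pattern scene
#'
#' Wavelength-flat reflectance `offset + amplitude * sin(2*pi*f*x)` along
#' one axis; the analytic Michelson contrast is
#' `amplitude / offset` (from extrema `offset +/- amplitude`).
#'
#' @param frequency cycles per pixel.
#' @param amplitude,offset sinusoid parameters; `offset +/- amplitude` must
#'   stay within `[0, 1]`.
#' @param orientation `"vertical"`: the pattern varies along rows (vertical
#'   profile); `"horizontal"`: along columns.
#' @param extent scene extent `c(rows, cols)`.
#' @param mmPerPixel physical pitch (mm/pixel).
#' @return a [SceneSpec-class].
#' @export
makeSineScene <- function(frequency, amplitude, offset,
                          orientation = c("vertical", "horizontal"),
                          extent = c(64, 64), mmPerPixel = 0.05) {
  orientation <- match.arg(orientation)
  extent <- rep_len(extent, 2)
  if (offset - amplitude < 0 || offset + amplitude > 1)
    stop("offset +/- amplitude must stay within [0, 1]")
  if (amplitude < 0) stop("amplitude must be >= 0")
  x <- if (orientation == "vertical") {
    matrix(rep(seq_len(extent[1]) - 1, extent[2]), extent[1], extent[2])
  } else {
    matrix(rep(seq_len(extent[2]) - 1, each = extent[1]),
           extent[1], extent[2])
  }
  w <- (sin(2 * pi * frequency * x) + 1) / 2
  new("SceneSpec", weights = w,
      spectrumHigh = flatSpectrum(offset + amplitude),
      spectrumLow = flatSpectrum(max(offset - amplitude, 0)),
      mmPerPixel = mmPerPixel)
}

#' USAF-1951 style three-bar target scene
#'
#' Wavelength-flat scene holding, for each requested element, two
#' three-bar blocks at the exact line width from [usafLinewidthMm()]: one
#' with horizontal bars (intensity varies along rows; assesses vertical
#' resolution) and one with vertical bars. Background is bright, bars are
#' dark. Alongside the scene a table of profile segments for
#' [resolutionLimit()] is returned.
#'
#' @param elements data frame with integer columns `group` and `element`,
#'   ordered coarse to fine.
#' @param mmPerPixel physical pitch (mm/pixel); every bar must be at least
#'   2 pixels wide at this scale.
#' @param background,barReflectance reflectance of background and bars.
#' @return list with `scene` (a [SceneSpec-class]) and `elements` (data
#'   frame with `group`, `element`, `orientation`, `widthPx` and profile
#'   segment endpoints `r0, c0, r1, c1`).
#' @export
makeUsafScene <- function(elements, mmPerPixel, background = 0.9,
                          barReflectance = 0.05) {
  if (!nrow(elements)) {
    return(list(scene = makeTileScene(flatSpectrum(background), c(20, 20),
                                      mmPerPixel = mmPerPixel),
                elements = data.frame()))
  }
  widthMm <- usafLinewidthMm(elements$group, elements$element)
  wPx <- round(widthMm / mmPerPixel)
  if (any(wPx < 2))
    stop("element(s) unprintable at this scale: bar width < 2 px")
  maxW <- max(wPx)
  margin <- 2L * maxW
  # each element row: horizontal-bar block (5w x 5w), gap 2w, vertical block
  blockH <- 5L * wPx
  rowH <- blockH + margin
  totalH <- margin + sum(rowH)
  totalW <- margin + max(5L * wPx * 2L + 2L * wPx) + margin
  # round extent up to a multiple of 20 (divisible by both 4x4 and 5x5)
  up20 <- function(v) as.integer(ceiling((v) / 20) * 20)
  extent <- c(up20(totalH), up20(totalW))
  w <- matrix(1, extent[1], extent[2])
  seg <- list()
  r0 <- margin + 1L
  for (i in seq_len(nrow(elements))) {
    wp <- wPx[i]
    c0 <- margin + 1L
    # horizontal bars: rows vary, three bars of height wp, gaps wp
    for (k in 0:2) {
      rr <- r0 + k * 2L * wp
      w[rr:(rr + wp - 1L), c0:(c0 + 5L * wp - 1L)] <- 0
    }
    cc <- c0 + (5L * wp) %/% 2L
    seg[[length(seg) + 1L]] <- data.frame(
      group = elements$group[i], element = elements$element[i],
      orientation = "vertical", widthPx = wp,
      r0 = r0 - wp, c0 = cc, r1 = r0 + 6L * wp, c1 = cc)
    # vertical bars block to the right
    cv <- c0 + 5L * wp + 2L * wp
    for (k in 0:2) {
      ccb <- cv + k * 2L * wp
      w[r0:(r0 + 5L * wp - 1L), ccb:(ccb + wp - 1L)] <- 0
    }
    rr <- r0 + (5L * wp) %/% 2L
    seg[[length(seg) + 1L]] <- data.frame(
      group = elements$group[i], element = elements$element[i],
      orientation = "horizontal", widthPx = wp,
      r0 = rr, c0 = cv - wp, r1 = rr, c1 = cv + 6L * wp)
    r0 <- r0 + rowH[i]
  }
  scene <- new("SceneSpec", weights = w,
               spectrumHigh = flatSpectrum(background),
               spectrumLow = flatSpectrum(barReflectance),
               mmPerPixel = mmPerPixel)
  list(scene = scene, elements = do.call(rbind, seg))
}

#' Smooth color-tile reflectance spectra
#'
#' Synthetic stand-ins for the eight Spectralon color calibration tiles
#' (plus a NIR tile): smooth logistic/Gaussian blends with transition
#' scales of 26 nm or more, spanning a broad range of reflectance
#' intensities. They emulate the spectral smoothness of sintered-PTFE
#' color standards; they are not vendor calibration data.
#'
#' @param name one of `"red"`, `"green"`, `"blue"`, `"yellow"`,
#'   `"violet"`, `"cyan"`, `"orange"`, `"purple"`, `"nir"`.
#' @param grid wavelength grid (nm), default 360-1000 at 1 nm (mirroring
#'   1-nm spectrophotometer calibration curves).
#' @return a [SpectralCurve-class].
#' @export
tileSpectrum <- function(name = c("red", "green", "blue", "yellow",
                                  "violet", "cyan", "orange", "purple",
                                  "nir"),
                         grid = seq(360, 1000, by = 1)) {
  name <- match.arg(name)
  lg <- function(c0, s) 1 / (1 + exp(-(grid - c0) / s))
  gs <- function(c0, s) exp(-(grid - c0)^2 / (2 * s^2))
  v <- switch(name,
    red    = 0.07 + 0.75 * lg(600, 30),
    green  = 0.06 + 0.55 * gs(535, 55) + 0.55 * lg(770, 40),
    blue   = 0.08 + 0.55 * gs(465, 50) + 0.60 * lg(780, 45),
    yellow = 0.07 + 0.75 * lg(540, 28),
    violet = 0.10 + 0.45 * gs(430, 45) + 0.65 * lg(640, 35),
    cyan   = 0.08 + 0.60 * gs(500, 60) + 0.50 * lg(800, 50),
    orange = 0.06 + 0.80 * lg(575, 26),
    purple = 0.09 + 0.35 * gs(445, 50) + 0.55 * lg(660, 38),
    nir    = 0.30 + 0.45 * gs(800, 120))
  SpectralCurve(grid, pmin(pmax(v, 0.02), 0.95), label = name)
}
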