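# Shared fixtures: small cameras, noise-free / noisy acquisition models,
# and a relative-SD helper tolerant of exactly-flat images.

# tiny 2x2 4-band camera for cheap index bookkeeping tests
tinyCamera <- function() {
  cameraSpec("tiny", c(500, 520, 540, 560), 2L, bitDepth = 10L,
             filterFwhmNm = 15)
}

noiseFreeModel <- function(camera, darkLevel = 60, fraction = 0.9) {
  m <- acquisitionModel(darkLevel = darkLevel, shotNoise = FALSE,
                        readNoiseSd = 0)
  m@gain <- exposureGain(camera, m, fraction = fraction)
  m
}

noisyModel <- function(camera, darkLevel = 60, fraction = 0.9) {
  m <- acquisitionModel(darkLevel = darkLevel)
  m@gain <- exposureGain(camera, m, fraction = fraction)
  m
}

# purely multiplicative mosaic modulation: no dark offset, no noise
pureModulationModel <- function(camera) noiseFreeModel(camera, darkLevel = 0)

# sd/mean, treating an exactly (or numerically) flat image as zero residual
relResidualSD <- function(img) {
  v <- img[!is.na(img)]
  if (diff(range(v)) <= 1e-9 * max(abs(v), 1)) return(0)
  stats::sd(v) / mean(v)
}

tileNames <- c("red", "green", "blue", "yellow", "violet", "cyan",
               "orange", "purple")
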