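# mosaicHSI

Processing toolkit for **snapshot-mosaic hyperspectral cameras**
(spectrally resolved detector arrays, SRDAs) as used in laparoscopic and
endoscopic imaging. SRDAs carry a repeating p×p tile of micro-optical
bandpass filters over the sensor, so a single exposure captures a full
spectral image — at the price of a periodic "mosaic" pattern in the raw
frame and a p-fold loss of spatial sampling per band.

The package covers the full desk-side processing chain for such systems:

- **Hypercube reconstruction** — tile sampling of raw H×W mosaic frames
  into h×w×B spectral volumes, temporal averaging of repeated
  acquisitions, white/dark reflectance calibration
  `R = ρ_white · (I − D) / (W − D)`, and glare clipping.
- **Demosaicing** of the full-resolution raw frame by three methods:
  white-reference calibration (WRC, element-wise division by the white
  mosaic), Fourier low-pass notch filtering (LPF), and filter-kernel
  convolution (FC, matched H / H⁻¹ kernel pair formed from tile-wise
  sums, plus an unsharp step).
- **Spatial resolution assessment** — sinusoid fits over bar-target
  intensity profiles, Michelson contrast
  `C = (S_max − S_min)/(S_max + S_min)` with a 20% resolvability cutoff,
  and exact USAF-1951 geometry
  (`width = 1 / (2 · 2^(group + (element−1)/6))` mm).
- **Spectral validation** — resampling reference reflectance curves onto
  camera band centers, least-squares scale alignment, percent RMSE
  (`100 · sqrt(mean((R_meas − R_ref)²))`), and mean ± sample-SD summary
  tables.
- **Dual-camera registration** — spectral-mean collapse, binarization,
  control-point affine estimation, per-band bilinear warping.
- **Pseudo-RGB rendering** by nearest-band selection at 700.0 / 546.1 /
  435.8 nm.
- A **forward simulator** of SRDA acquisition (Gaussian filter bank,
  halogen-like illuminant, dark level, shot and read noise, flat-tile /
  USAF / sinusoid scenes) so the entire stack is testable without
  hardware.

Camera presets are included for VIS (16 bands, 4×4 mosaic, 461–597 nm),
RNIR (15 bands, 4×4, 614–853 nm) and NIR (24 bands, 5×5, 669–949 nm)
configurations.

## Worked example

Simulate a red calibration tile through the VIS camera, reconstruct and
calibrate it, and score the recovered spectrum against the generating
one:

```r
library(mosaicHSI)

cam <- cameraPreset("VIS")
cam
#> CameraSpec 'VIS': 16 bands, 461-597 nm, 4x4 mosaic, 10-bit

model <- acquisitionModel()            # halogen illuminant, shot + read noise
model@gain <- exposureGain(cam, model) # expose to ~90% full scale on white

set.seed(42)
pair <- makeReferencePair(cam, model, extent = c(64, 64), n = 30)
sp <- tileSpectrum("red")
frames <- simulateFrameSequence(makeTileScene(sp, c(64, 64)), cam, model,
                                n = 30)
cube <- calibrate(reconstructHypercube(temporalAverage(frames)), pair)
cube
#> Hypercube 16x16x16 [reflectance], 461-597 nm
#>   meta: camera=VIS, nInvalid=0

meas <- roiMeanSpectrum(cube, matrix(TRUE, 16, 16), label = "red tile")
ref <- resampleReference(sp, bandCenters(cam))$curve
spectralRMSE(curveValues(meas), curveValues(ref))
#> 0.18      # percent RMSE: 30-frame averaging keeps the error well below 1%
```

Resolution assessment pieces work standalone:

```r
fit <- fitSineProfile(0.5 + 0.3 * sin(2 * pi * 0.1 * (0:63)),
                      expectedFreq = 0.1)
michelsonContrast(fit)      # 0.6  = (0.8 - 0.2) / (0.8 + 0.2)
round(usafLinewidthMm(1, 1), 3)  # 0.250 mm
```

The 0.18% RMSE above is the noise-and-quantization floor of the simulated
instrument; contrast 0.6 is the analytic Michelson contrast of a sinusoid
with amplitude 0.3 about offset 0.5.

## Command line

A thin CLI over the same functions lives at
`inst/cli/mosaichsi.R` (after installation:
`system.file("cli", "mosaichsi.R", package = "mosaicHSI")`):

```sh
Rscript mosaichsi.R simulate --camera cam.json --scene scene.json \
    --frames 30 --seed 7 --out seq.tif
Rscript mosaichsi.R reconstruct --camera cam.json --frames seq.tif \
    --white w.tif --dark d.tif --average --clip-glare 1.0 --out cube.hdr
Rscript mosaichsi.R demosaic --method fc --camera cam.json --in raw.tif \
    --out demosaiced.tif
```

Every run writes a JSON run report next to its output. Hypercubes
serialize as band-per-page float32 TIFF with a JSON sidecar, or as ENVI
BSQ (`.hdr`/`.dat`).

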