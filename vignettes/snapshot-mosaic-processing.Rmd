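---
title: "Snapshot-mosaic hyperspectral processing: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Snapshot-mosaic hyperspectral processing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaicHSI)
```

## The measurement model

A spectrally resolved detector array (SRDA) overlays a repeating
p×p tile of bandpass filters on a monochrome sensor. Cell (r, c) of the
tile always samples the same spectral band, so a raw H×W frame is a
spatially interleaved sampling of B ≤ p² bands. Two views of such a frame
matter in practice:

* **Reconstruction** decimates the frame into an (H/p)×(W/p)×B hypercube:
  `cube[i, j, b] = frame[i·p + r_b, j·p + c_b]` (0-based). Full spectral
  information, 1/p spatial sampling per axis.
* **Demosaicing** keeps the full H×W raster and removes the periodic
  per-cell gain pattern, yielding a single grayscale image with p-fold
  better sampling but no spectral separation. This is what the spatial
  resolution of the system is assessed on.

Counts at an active cell follow the linear radiometric model

$$N(x,y) = N_{dark} + g \sum_\lambda L(\lambda)\, R(x,y,\lambda)\,
T_b(\lambda)\, \Delta\lambda + \varepsilon,$$

with illuminant L, scene reflectance R, band transmission T_b, and noise
ε (optional shot noise with variance equal to the signal counts, plus
Gaussian read noise). Reflectance calibration against temporally averaged
white (W, a 95% diffuse standard) and dark (D) references is

$$R = \rho_{white} \cdot \frac{I - D}{W - D},$$

which cancels the illuminant, filter transmission and gain exactly —
to the extent the scene is at the same working distance as the white
reference. Pixels with `W − D ≤ ε` (default 10⁻⁶ of the maximum white
signal) are flagged `NA` and excluded from all downstream means;
`whiteReflectance = 1` gives relative reflectance with the standard as
unity instead of the absolute-referenced 0.95 default.

### Cameras

Presets cover the three supported configurations: VIS (16 bands, 4×4,
461–597 nm), RNIR (15 bands, 4×4, 614–853 nm), NIR (24 bands, 5×5,
669–949 nm). Only the realized range endpoints of these cameras are
public, so the presets place band centers uniformly between them; vendors
do not publish the cell-to-band map either, so the default layout is
row-major in ascending wavelength with trailing (bottom-right) cells
inactive when B < p², all overridable through the JSON camera config.
Vendor-nominal ranges for such cameras (e.g. 600–870 nm for an RNIR
unit) are typically wider than the realized ones; the presets follow the
realized endpoints since those are what the instruments actually report.

## Demosaicing methods

**WRC** divides the raw frame element-wise by the white-reference mosaic.
It is exact for purely multiplicative per-cell gains (any gain common to
raw and white cancels identically) but inherits two caveats: a dark
offset is *not* removed (the ratio of two offset signals is not flat),
and the output inherits the white frame's noise.

**LPF** treats the mosaic as high-frequency noise: 2D FFT, then zeroing
of every frequency bin outside a protected central disk whose magnitude
exceeds `notchThreshold` × (maximum magnitude outside DC), then inverse
transform. Defaults: disk radius `1/(2p)` of Nyquist (the first mosaic
harmonic at 1/p lies outside it), threshold 0.1. Both are exposed and
documented as tuning starting points — in the original workflow this
threshold is tuned per dataset. Zeroing removes the full complex bin;
retaining phase under a magnitude-only threshold is a possible
alternative reading, but a zeroed magnitude makes the phase moot.

**FC** forms a p×p kernel H of tile-wise sums (the relative response of
each filter in the array, normalized to mean 1 over active cells) and its
reciprocal H⁻¹, convolves the frame with both, normalizes each branch,
averages, and sharpens. Writing the per-cell gain as exp(u), the H branch
perturbs the local average by +Σu·u′ terms and the H⁻¹ branch by the same
terms with opposite sign, so the average cancels the gain pattern to
second order in u.

Two deliberate design choices here:

* **Branch normalization is to unit mean, not min-max.** Min-max
  stretching of each branch applies different affine maps to the two
  branches and destroys the cancellation (measured on a flat modulated
  scene: 15% residual with per-branch min-max vs 0.7% with mean
  normalization). The final *display* image is still min-max normalized
  to [0, 1]; the `DemosaicResult` therefore carries both `image` (display
  scale) and `field` (native scale). All flatness and contrast statements
  are about `field` — min-max normalization of a near-constant image
  stretches its residual ripple to full range by construction, so the
  display image of a perfectly demosaiced flat scene is *maximally*
  noisy-looking while the field is flat.
* **The FC convolution border replicates whole tiles** (out-of-range
  indices map to in-range ones with the same index mod p) instead of
  mirror reflection. Plain mirroring reverses the mosaic phase at the
  border, and the resulting rim artifact dominated the residual of an
  otherwise clean demosaic (2.2% → 0.7% on a 128×128 flat scene).
  Scene-content convolution (Gaussian blur, unsharp) keeps ordinary
  mirror reflection, which avoids dark rims in endoscopic circular
  fields.

The unsharp step is `x + amount · (x − G_σ(x))` with σ = 1 px and
amount = 0.5 by default (the original description cites no parameters;
these are conventional mild settings). A degenerate constant image
min-max normalizes to all zeros by documented convention.

## Resolution assessment

Bar-target profiles are extracted along user-chosen segments
(perpendicular to the bars, ~1 sample/px, bilinear interpolation) and fit
with `offset + amplitude·sin(2πfx + φ)` by Levenberg–Marquardt with
`amplitude ≥ 0`, initialized from a linear sin/cos regression at the
frequency expected from the bar geometry (frequency stays free in the
fit; three-bar elements provide ~3 cycles, enough to refine it). If the
linear initialization already fits to numerical precision the fit returns
it directly — the LM Jacobian is degenerate at an exactly zero residual.
Michelson contrast is computed from the fitted extrema
`S_max/min = offset ± amplitude`; an element counts as resolved at
contrast ≥ 0.20 (the cutoff is inclusive: "20%" is taken as attainable).
USAF-1951 geometry is exact: `2^(group + (element−1)/6)` line pairs/mm,
width = half a line-pair period. Reports round to 3 decimals
(round-half-even) but full precision is returned; note that published
tables occasionally carry doubling-then-rounding slips (0.446 for
group 0 element 2 where exact geometry gives 0.44545 → 0.445), so the
geometry, not any printed digit, is authoritative here.

On a noiseless square-wave bar pattern the sine fit overshoots slightly
(the fundamental of a square wave exceeds its amplitude by 4/π), which
can push fitted contrast above 1; that is expected behavior of the
single-sinusoid model, not an error.

## Spectral validation

Reference curves are linearly interpolated onto the camera band centers;
band centers outside the reference support are excluded, never
extrapolated (RNIR bands beyond a 830 nm reference end are the practical
case). Percent RMSE is computed on the 0–1 reflectance scale; per-tile
values are summarized as mean ± sample SD (n−1), which reproduces the
published 3.51±2.03 / 3.43±0.84 summaries from their printed per-tile
rows exactly. Tile comparisons apply no scale alignment (alignment is a
tissue-workflow step, where the system's relative reflectance needs one
least-squares gain against the spectrometer); `scaleAlign` implements the
closed-form gain `⟨m, r⟩/⟨r, r⟩` and returns it without applying it.
Camera spectra are compared at band centers, ignoring filter bandwidth,
matching how such comparisons are plotted.

## The simulator: what it does and does not emulate

The simulator exists so every stage is testable without hardware. It
emulates: the periodic band-to-cell sampling including inactive cells,
Gaussian filter transmissions (FWHM 15 nm, vendor-typical for mosaic
SRDAs), a halogen-like 3200 K Planck illuminant (so short-VIS bands are
light-starved, as observed with real halogen sources), dark offset
(60 counts), Gaussian shot noise (variance = signal; adequate above
~100 counts), read noise (2 counts SD), 10-bit ADC clipping, and the
acquisition protocol of exposing to ~90% of full scale on the white
standard and averaging ~30 frames. Scenes are blends
`R = w·high(λ) + (1−w)·low(λ)` of two spectra with a spatial weight map,
which expresses flat tiles, three-bar targets at exact USAF widths, and
sinusoidal patterns. The bundled color-tile spectra are smooth
logistic/Gaussian blends (transition scales ≥ 26 nm) emulating the
spectral smoothness of sintered-PTFE color standards; they are
synthetic, not vendor calibration data (as is
`inst/extdata/red-tile-synthetic.csv`).

Not emulated: laparoscope optics (PSF, vignetting, the circular field),
specular glare (glare handling is tested with hand-planted saturated
pixels), working-distance dependence of the calibration (the
inverse-square-law issue), chromatic filter cross-talk, and true Poisson
statistics at very low counts. Passing simulator-based tests therefore
demonstrates the correctness of the *processing*, not the imaging
performance of any physical instrument.

Quadrature is rectangular on the illuminant's 1-nm grid, mirroring 1-nm
spectrophotometer reference curves; scene spectra are edge-extended
beyond their support. With no noise the
simulate→reconstruct→calibrate round trip recovers the illuminant- and
filter-weighted band average of the scene reflectance to < 10⁻⁶, so the
residual RMSE against *center-sampled* references (~0.2% for the bundled
tiles) is pure band-integration-vs-center-sampling mismatch.

## Numerical choices and degenerate inputs

* Invalid-pixel sentinel: `NA`, excluded from ROI means, spectral means
  and warps; counts of invalid/clipped pixels travel in `meta`.
* Min-max display normalization maps a constant image (range below 10⁻⁹
  relative) to all zeros.
* Raw frames average *before* reconstruction; the two orders are
  mathematically identical (and tested to be), averaging first just does
  less work.
* Nearest-band ties break to the lower index; width reporting rounds
  half-even.
* Affine estimation is the exact least-squares solve via QR; collinear
  control points are rejected by rank. Warping inverse-maps destination
  pixel centers (0-based convention at the interfaces, 1-based
  internally) with bilinear interpolation; out-of-domain pixels are `NA`,
  and nearest-neighbor is available for masks.
* Problem sizes in the tests — 48–128 px frames, 30-frame bursts,
  50-seed Monte-Carlo loops — were chosen as the smallest at which the
  measured quantities are stable against their tolerances; they mirror,
  at reduced raster size, the 30-frame validation protocol of the
  physical workflow.

## Known limitations

* Demosaicing targets a single grayscale image, not per-band
  full-resolution interpolation.
* USAF element localization is manual (segment coordinates are inputs);
  there is no automatic chart detection, and no perception-based
  no-reference quality score.
* The LPF notch threshold is scene-dependent by design and has no
  auto-tuner.
* Shot noise is Gaussian; at dark-limited signal levels a Poisson model
  would be more faithful.
* Registration assumes rigidly co-mounted cameras (a single affine for
  all bands and frames); there is no nonrigid or feature-based matching.
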