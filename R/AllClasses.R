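#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' MosaicLayout: periodic band-to-cell map of a multispectral filter array
#'
#' Describes the repeating p x p tile of a snapshot-mosaic sensor. Each cell
#' of the tile samples one spectral band; `cellBand` holds the (1-based) band
#' index of every cell, with `NA` marking inactive cells (cells whose samples
#' are never read, used when the band count is below p^2).
#'
#' @slot period integer, tile edge in pixels (4 or 5 for the supported
#'   cameras, any value >= 1 is accepted).
#' @slot cellBand integer matrix, `period x period`, band index per cell or
#'   `NA` for an inactive cell. Every band index `1..B` must appear exactly
#'   once.
#'
#' @examples
#' layout <- MosaicLayout(4L)                 # row-major 16-band layout
#' mosaicPeriod(layout)
#' @export
setClass("MosaicLayout",
  representation(period = "integer", cellBand = "matrix"))

setValidity("MosaicLayout", function(object) {
  p <- object@period
  cb <- object@cellBand
  if (length(p) != 1L || is.na(p) || p < 1L)
    return("'period' must be a single positive integer")
  if (!all(dim(cb) == c(p, p)))
    return(sprintf("'cellBand' must be a %d x %d matrix", p, p))
  bands <- cb[!is.na(cb)]
  if (length(bands) == 0L)
    return("layout has no active cells")
  b <- sort(as.integer(bands))
  if (!identical(b, seq_len(length(b))))
    return("active cells must carry each band index 1..B exactly once")
  TRUE
})

#' CameraSpec: declarative description of a snapshot hyperspectral camera
#'
#' @slot name character, camera label.
#' @slot bandCentersNm numeric, strictly ascending band-center wavelengths in
#'   nm; its length must equal the number of active layout cells.
#' @slot layout a [MosaicLayout-class].
#' @slot bitDepth integer, ADC bit depth (full scale `2^bitDepth - 1`).
#' @slot filterFwhmNm numeric, full width at half maximum of the per-band
#'   filter transmission in nm; scalar (shared) or one value per band.
#'   Used only by the acquisition simulator.
#' @seealso [cameraPreset()], [loadCameraSpec()]
#' @export
setClass("CameraSpec",
  representation(name = "character", bandCentersNm = "numeric",
                 layout = "MosaicLayout", bitDepth = "integer",
                 filterFwhmNm = "numeric"))

setValidity("CameraSpec", function(object) {
  bc <- object@bandCentersNm
  if (length(bc) < 1L || any(!is.finite(bc)))
    return("'bandCentersNm' must be finite and non-empty")
  if (is.unsorted(bc, strictly = TRUE))
    return("'bandCentersNm' must be strictly ascending")
  nActive <- sum(!is.na(object@layout@cellBand))
  if (length(bc) != nActive)
    return(sprintf("band count (%d) does not match active layout cells (%d)",
                   length(bc), nActive))
  if (object@bitDepth < 1L || object@bitDepth > 32L)
    return("'bitDepth' must be in 1..32")
  fw <- object@filterFwhmNm
  if (!(length(fw) %in% c(1L, length(bc))) || any(fw <= 0))
    return("'filterFwhmNm' must be positive, scalar or one per band")
  TRUE
})

#' FilterBank: sampled per-band filter transmission curves
#'
#' @slot wavelengthGridNm numeric, ascending wavelength sample grid (nm).
#' @slot transmission numeric matrix, B x G, transmission in `[0, 1]`;
#'   row b is band b's curve.
#' @seealso [gaussianFilterBank()]
#' @export
setClass("FilterBank",
  representation(wavelengthGridNm = "numeric", transmission = "matrix"))

setValidity("FilterBank", function(object) {
  g <- object@wavelengthGridNm
  tr <- object@transmission
  if (is.unsorted(g, strictly = TRUE))
    return("wavelength grid must be strictly ascending")
  if (ncol(tr) != length(g))
    return("transmission columns must match the wavelength grid")
  if (any(tr < 0 | tr > 1))
    return("transmission values must lie in [0, 1]")
  TRUE
})

#' RawMosaicFrame: full-resolution 2D sensor raster with mosaic pattern
#'
#' @slot pixels numeric matrix, H x W intensity raster (counts).
#' @slot camera the acquiring [CameraSpec-class].
#' @slot meta list, free-form metadata (exposure, timestamp, source file).
#' @export
setClass("RawMosaicFrame",
  representation(pixels = "matrix", camera = "CameraSpec", meta = "list"))

setValidity("RawMosaicFrame", function(object) {
  p <- object@camera@layout@period
  d <- dim(object@pixels)
  if (any(d %% p != 0L))
    return(sprintf("frame dimensions %dx%d not divisible by mosaic period %d",
                   d[1], d[2], p))
  if (any(object@pixels < 0, na.rm = TRUE))
    return("pixel intensities must be nonnegative")
  TRUE
})

#' Hypercube: spectral image volume
#'
#' @slot data numeric 3D array, rows x cols x bands.
#' @slot bandCentersNm numeric, one wavelength (nm) per band, ascending.
#' @slot kind character, `"raw_intensity"` or `"reflectance"`.
#' @slot meta list, processing metadata (e.g. `nInvalid`, `nClipped`).
#' @export
setClass("Hypercube",
  representation(data = "array", bandCentersNm = "numeric",
                 kind = "character", meta = "list"))

setValidity("Hypercube", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L)
    return("'data' must be a 3D array (rows x cols x bands)")
  if (d[3] != length(object@bandCentersNm))
    return("third dimension must match the number of band centers")
  if (!object@kind %in% c("raw_intensity", "reflectance"))
    return("'kind' must be 'raw_intensity' or 'reflectance'")
  if (object@kind == "reflectance" &&
      any(object@data < 0 & !is.na(object@data)))
    return("reflectance values must be >= 0 (NA marks invalid pixels)")
  TRUE
})

#' SpectralCurve: wavelength-indexed reflectance vector
#'
#' @slot wavelengthsNm numeric, strictly ascending wavelengths (nm).
#' @slot values numeric, same length as `wavelengthsNm`.
#' @slot label character, curve label.
#' @export
setClass("SpectralCurve",
  representation(wavelengthsNm = "numeric", values = "numeric",
                 label = "character"))

setValidity("SpectralCurve", function(object) {
  if (length(object@wavelengthsNm) != length(object@values))
    return("wavelengths and values must have equal length")
  if (is.unsorted(object@wavelengthsNm, strictly = TRUE))
    return("wavelengths must be strictly ascending (no duplicates)")
  TRUE
})

setClassUnion("FrameOrCube", c("RawMosaicFrame", "Hypercube"))

#' CalibrationPair: temporally averaged white and dark references
#'
#' White frame of a diffuse reflectance standard (default 95% reflectance,
#' Spectralon-like) and dark frame (light blocked), used to convert raw
#' counts to reflectance. Either raw mosaic frames or reconstructed cubes may
#' be stored; [calibrate()] reconstructs frames on the fly.
#'
#' @slot white,dark [RawMosaicFrame-class] or [Hypercube-class], averaged.
#' @slot whiteReflectance numeric, reflectance of the white standard.
#' @export
setClass("CalibrationPair",
  representation(white = "FrameOrCube", dark = "FrameOrCube",
                 whiteReflectance = "numeric"))

setValidity("CalibrationPair", function(object) {
  wr <- object@whiteReflectance
  if (length(wr) != 1L || !is.finite(wr) || wr <= 0 || wr > 1)
    return("'whiteReflectance' must be a single value in (0, 1]")
  if (!identical(class(object@white)[1], class(object@dark)[1]))
    return("white and dark references must be of the same type")
  TRUE
})

#' FCKernelPair: matched kernels for filter-convolution demosaicing
#'
#' `H` holds the normalized per-cell filter response (tile-wise sums of the
#' raw image, scaled to mean 1 over active cells); `Hinv` its element-wise
#' reciprocal. Convolving with both and averaging cancels the periodic
#' mosaic gain pattern to second order.
#'
#' @slot H,Hinv numeric `period x period` matrices, strictly positive.
#' @seealso [formFCKernel()], [demosaicFC()]
#' @export
setClass("FCKernelPair", representation(H = "matrix", Hinv = "matrix"))

setValidity("FCKernelPair", function(object) {
  if (!all(dim(object@H) == dim(object@Hinv)))
    return("H and Hinv must have equal dimensions")
  if (any(object@H <= 0))
    return("H must be strictly positive")
  if (max(abs(object@Hinv - 1 / object@H)) > 1e-12 * max(abs(object@Hinv)))
    return("Hinv must be the element-wise reciprocal of H")
  TRUE
})

#' DemosaicResult: output of a demosaicing method
#'
#' @slot image numeric matrix, same shape as the input frame, min-max
#'   normalized to `[0, 1]` for display (NA marks invalid pixels).
#' @slot field numeric matrix, the demosaiced field on its native intensity
#'   scale, before display normalization. Flatness and contrast are
#'   meaningfully measured here: min-max normalization of a near-constant
#'   image stretches its residual ripple to full range.
#' @slot method character, one of `"WRC"`, `"LPF"`, `"FC"`.
#' @slot params list, the settings used.
#' @export
setClass("DemosaicResult",
  representation(image = "matrix", field = "matrix", method = "character",
                 params = "list"))

setValidity("DemosaicResult", function(object) {
  if (!object@method %in% c("WRC", "LPF", "FC"))
    return("'method' must be one of WRC, LPF, FC")
  v <- object@image[!is.na(object@image)]
  if (any(!is.finite(v)))
    return("image must be finite (NA marks invalid pixels)")
  TRUE
})

#' SineFitResult: sinusoid fitted to a bar-target intensity profile
#'
#' @slot amplitude,offset,frequency,phase fitted parameters of
#'   `offset + amplitude * sin(2*pi*frequency*x + phase)`; `amplitude >= 0`,
#'   frequency in cycles/pixel.
#' @slot smax,smin `offset + amplitude` and `offset - amplitude`, the fitted
#'   peak and trough intensities entering the Michelson contrast.
#' @slot rmsResidual numeric, root-mean-square fit residual.
#' @seealso [fitSineProfile()], [michelsonContrast()]
#' @export
setClass("SineFitResult",
  representation(amplitude = "numeric", offset = "numeric",
                 frequency = "numeric", phase = "numeric",
                 smax = "numeric", smin = "numeric",
                 rmsResidual = "numeric"))

setValidity("SineFitResult", function(object) {
  if (object@amplitude < 0) return("amplitude must be >= 0")
  if (object@smax < object@smin) return("smax must be >= smin")
  TRUE
})

#' UsafElement: group/element coordinate on a USAF-1951 target
#'
#' Resolution in line pairs per mm is `2^(group + (element - 1)/6)`; it
#' doubles per group and grows by `2^(1/6)` per element.
#'
#' @slot group integer, may be negative.
#' @slot element integer in 1..6.
#' @seealso [usafLinewidthMm()]
#' @export
setClass("UsafElement",
  representation(group = "integer", element = "integer"))

setValidity("UsafElement", function(object) {
  if (!object@element %in% 1:6) return("element must be in 1..6")
  TRUE
})

#' AffineTransform: 2D affine map between pixel coordinate frames
#'
#' Maps source `(row, col)` to destination via `dst = A %*% src + t`, stored
#' as the 2 x 3 matrix `[A | t]`.
#'
#' @slot matrix numeric 2 x 3; the 2 x 2 linear part must be non-singular.
#' @seealso [estimateAffine()], [applyAffine()]
#' @export
setClass("AffineTransform", representation(matrix = "matrix"))

setValidity("AffineTransform", function(object) {
  m <- object@matrix
  if (!all(dim(m) == c(2L, 3L)))
    return("'matrix' must be 2 x 3 (linear part + translation)")
  if (abs(det(m[, 1:2])) < 1e-12)
    return("linear part is singular")
  TRUE
})

#' SceneSpec: synthetic ground-truth reflectance scene
#'
#' Reflectance is a spatial blend of two spectra:
#' `R(r, c, lambda) = w(r, c) * high(lambda) + (1 - w(r, c)) * low(lambda)`
#' with blending weights `w` in `[0, 1]`. Flat tiles, bar targets and
#' sinusoidal patterns are all expressible this way.
#'
#' @slot weights numeric matrix, spatial blending weights in `[0, 1]` at
#'   sensor resolution.
#' @slot spectrumHigh,spectrumLow [SpectralCurve-class] with values in
#'   `[0, 1]`.
#' @slot mmPerPixel numeric, physical sampling pitch (used by bar targets).
#' @seealso [makeTileScene()], [makeUsafScene()], [makeSineScene()]
#' @export
setClass("SceneSpec",
  representation(weights = "matrix", spectrumHigh = "SpectralCurve",
                 spectrumLow = "SpectralCurve", mmPerPixel = "numeric"))

setValidity("SceneSpec", function(object) {
  w <- object@weights
  if (any(w < 0 | w > 1))
    return("weights must lie in [0, 1]")
  for (s in c("spectrumHigh", "spectrumLow")) {
    v <- slot(object, s)@values
    if (any(v < 0 | v > 1))
      return(sprintf("'%s' reflectance must lie in [0, 1]", s))
  }
  if (object@mmPerPixel <= 0) return("'mmPerPixel' must be positive")
  TRUE
})

#' AcquisitionModel: radiometric and noise model of mosaic acquisition
#'
#' Detector counts at an active cell of band b are
#' `dark + gain * sum_lambda L(lambda) R(lambda) T_b(lambda) dlambda`
#' plus optional shot noise (Gaussian, variance = signal counts) and read
#' noise, clipped to the ADC range. Inactive cells record dark + read noise.
#'
#' @slot illuminant [SpectralCurve-class], relative spectral power of the
#'   light source (halogen-like by default; see [halogenIlluminant()]).
#' @slot darkLevel numeric >= 0, dark-current offset in counts.
#' @slot gain numeric > 0, counts per unit band-integrated radiance.
#' @slot readNoiseSd numeric >= 0, read noise standard deviation in counts.
#' @slot shotNoise logical, include signal-dependent shot noise.
#' @seealso [acquisitionModel()], [simulateMosaicFrame()]
#' @export
setClass("AcquisitionModel",
  representation(illuminant = "SpectralCurve", darkLevel = "numeric",
                 gain = "numeric", readNoiseSd = "numeric",
                 shotNoise = "logical"))

setValidity("AcquisitionModel", function(object) {
  if (object@darkLevel < 0) return("'darkLevel' must be >= 0")
  if (object@gain <= 0) return("'gain' must be > 0")
  if (object@readNoiseSd < 0) return("'readNoiseSd' must be >= 0")
  TRUE
})
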