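# Generics, accessors and show methods for the core classes.

#' Mosaic tile period of a layout, camera or frame
#' @param x a `MosaicLayout`, `CameraSpec` or `RawMosaicFrame`.
#' @return integer tile edge in pixels.
#' @export
setGeneric("mosaicPeriod", function(x) standardGeneric("mosaicPeriod"))

#' @rdname mosaicPeriod
#' @export
setMethod("mosaicPeriod", "MosaicLayout", function(x) x@period)
#' @rdname mosaicPeriod
#' @export
setMethod("mosaicPeriod", "CameraSpec", function(x) x@layout@period)
#' @rdname mosaicPeriod
#' @export
setMethod("mosaicPeriod", "RawMosaicFrame", function(x) x@camera@layout@period)

#' Band-center wavelengths (nm)
#' @param x a `CameraSpec` or `Hypercube`.
#' @return numeric vector of band centers in nm.
#' @export
setGeneric("bandCenters", function(x) standardGeneric("bandCenters"))

#' @rdname bandCenters
#' @export
setMethod("bandCenters", "CameraSpec", function(x) x@bandCentersNm)
#' @rdname bandCenters
#' @export
setMethod("bandCenters", "Hypercube", function(x) x@bandCentersNm)

#' Number of spectral bands
#' @param x a `CameraSpec`, `MosaicLayout` or `Hypercube`.
#' @return integer band count.
#' @export
setGeneric("nBands", function(x) standardGeneric("nBands"))

#' @rdname nBands
#' @export
setMethod("nBands", "CameraSpec", function(x) length(x@bandCentersNm))
#' @rdname nBands
#' @export
setMethod("nBands", "MosaicLayout", function(x) sum(!is.na(x@cellBand)))
#' @rdname nBands
#' @export
setMethod("nBands", "Hypercube", function(x) dim(x@data)[3])

#' Pixel data of a frame or cube
#' @param x a `RawMosaicFrame` (matrix) or `Hypercube` (3D array).
#' @return the underlying numeric data.
#' @export
setGeneric("pixelData", function(x) standardGeneric("pixelData"))

#' @rdname pixelData
#' @export
setMethod("pixelData", "RawMosaicFrame", function(x) x@pixels)
#' @rdname pixelData
#' @export
setMethod("pixelData", "Hypercube", function(x) x@data)

#' Wavelengths and values of a spectral curve
#' @param x a `SpectralCurve`.
#' @return numeric vector.
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))
#' @rdname wavelengths
#' @export
setMethod("wavelengths", "SpectralCurve", function(x) x@wavelengthsNm)

#' @rdname wavelengths
#' @export
setGeneric("curveValues", function(x) standardGeneric("curveValues"))
#' @rdname wavelengths
#' @export
setMethod("curveValues", "SpectralCurve", function(x) x@values)

#' Michelson contrast of a fitted sinusoid or explicit extrema
#'
#' `(smax - smin) / (smax + smin)`, the modulation depth of a periodic
#' intensity pattern.
#'
#' @param smax peak intensity, or a `SineFitResult`.
#' @param smin trough intensity (ignored when `smax` is a fit result).
#' @return contrast in `[0, 1]` for nonnegative extrema.
#' @examples
#' michelsonContrast(3, 1)   # 0.5
#' @export
setGeneric("michelsonContrast",
           function(smax, smin) standardGeneric("michelsonContrast"))

setMethod("show", "MosaicLayout", function(object) {
  cat(sprintf("MosaicLayout: %dx%d tile, %d active band cell(s)\n",
              object@period, object@period, nBands(object)))
})

setMethod("show", "CameraSpec", function(object) {
  bc <- object@bandCentersNm
  cat(sprintf("CameraSpec '%s': %d bands, %.0f-%.0f nm, %dx%d mosaic, %d-bit\n",
              object@name, length(bc), min(bc), max(bc),
              object@layout@period, object@layout@period, object@bitDepth))
})

setMethod("show", "RawMosaicFrame", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("RawMosaicFrame %dx%d px (camera '%s', period %d)\n",
              d[1], d[2], object@camera@name, mosaicPeriod(object)))
})

setMethod("show", "Hypercube", function(object) {
  d <- dim(object@data)
  cat(sprintf("Hypercube %dx%dx%d [%s], %.0f-%.0f nm\n",
              d[1], d[2], d[3], object@kind,
              min(object@bandCentersNm), max(object@bandCentersNm)))
  if (length(object@meta))
    cat("  meta:", paste(names(object@meta), unlist(lapply(object@meta, format)),
                         sep = "=", collapse = ", "), "\n")
})

setMethod("show", "SpectralCurve", function(object) {
  cat(sprintf("SpectralCurve '%s': %d samples, %.0f-%.0f nm\n",
              object@label, length(object@values),
              min(object@wavelengthsNm), max(object@wavelengthsNm)))
})

setMethod("show", "SineFitResult", function(object) {
  cat(sprintf(
    "SineFitResult: amp %.4g, offset %.4g, freq %.4g cyc/px, contrast %.4g\n",
    object@amplitude, object@offset, object@frequency,
    michelsonContrast(object)))
})

setMethod("show", "AffineTransform", function(object) {
  cat("AffineTransform (dst = A src + t):\n")
  print(object@matrix)
})

setMethod("show", "UsafElement", function(object) {
  cat(sprintf("USAF-1951 group %d element %d: %.3f mm line width\n",
              object@group, object@element,
              round(usafLinewidthMm(object), 3)))
})
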