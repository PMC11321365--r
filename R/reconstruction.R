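# Hypercube reconstruction and reflectance calibration.

#' Reconstruct a hypercube from a raw mosaic frame
#'
#' Each mosaic tile of the H x W frame contributes one pixel per band:
#' `cube[i, j, b] = frame[(i-1)*p + r_b, (j-1)*p + c_b]` where `(r_b, c_b)`
#' is band b's cell within the tile. The cube is `H/p x W/p x B`; inactive
#' cells are never read.
#'
#' @param frame a [RawMosaicFrame-class] (dimensions divisible by the
#'   period, enforced at construction).
#' @return a raw-intensity [Hypercube-class].
#' @export
reconstructHypercube <- function(frame) {
  stopifnot(is(frame, "RawMosaicFrame"))
  px <- frame@pixels
  cam <- frame@camera
  p <- mosaicPeriod(cam)
  cells <- bandCells(cam@layout)
  h <- nrow(px) %/% p
  w <- ncol(px) %/% p
  B <- nrow(cells)
  cube <- array(0, c(h, w, B))
  for (b in seq_len(B)) {
    cube[, , b] <- px[seq(cells[b, 1], by = p, length.out = h),
                      seq(cells[b, 2], by = p, length.out = w)]
  }
  Hypercube(cube, cam@bandCentersNm, kind = "raw_intensity",
            meta = list(camera = cam@name))
}

#' Temporal average of repeated acquisitions
#'
#' Element-wise arithmetic mean of a homogeneous list of frames, cubes or
#' numeric arrays, computed in floating point. Averaging raw frames before
#' reconstruction is equivalent to averaging reconstructed cubes.
#'
#' @param x non-empty list of same-shape [RawMosaicFrame-class],
#'   [Hypercube-class], matrices or arrays (a single object passes through).
#' @return the averaged object, same type as the elements.
#' @export
temporalAverage <- function(x) {
  if (!is.list(x)) x <- list(x)
  if (!length(x)) stop("temporalAverage needs at least one element")
  getData <- function(e) {
    if (is(e, "RawMosaicFrame")) e@pixels
    else if (is(e, "Hypercube")) e@data
    else e
  }
  d0 <- getData(x[[1]])
  acc <- d0 * 0
  for (e in x) {
    d <- getData(e)
    if (!identical(dim(d), dim(d0)))
      stop("shape mismatch in temporalAverage")
    acc <- acc + d
  }
  acc <- acc / length(x)
  first <- x[[1]]
  if (is(first, "RawMosaicFrame")) {
    new("RawMosaicFrame", pixels = acc, camera = first@camera,
        meta = c(first@meta, list(nAveraged = length(x))))
  } else if (is(first, "Hypercube")) {
    Hypercube(acc, first@bandCentersNm, kind = first@kind,
              meta = c(first@meta, list(nAveraged = length(x))))
  } else acc
}

#' Construct a calibration pair
#'
#' @param white,dark temporally averaged white/dark references, either
#'   [RawMosaicFrame-class]s or reconstructed [Hypercube-class]s (matched
#'   types and shapes).
#' @param whiteReflectance reflectance of the white standard (default 0.95,
#'   a Spectralon tile). Set to 1 to produce relative reflectance with the
#'   white standard as unity.
#' @return a [CalibrationPair-class].
#' @export
calibrationPair <- function(white, dark, whiteReflectance = 0.95) {
  new("CalibrationPair", white = white, dark = dark,
      whiteReflectance = whiteReflectance)
}

.asCube <- function(x) {
  if (is(x, "RawMosaicFrame")) reconstructHypercube(x) else x
}

#' White/dark reflectance calibration
#'
#' Converts raw intensities to reflectance per band:
#' `R = whiteReflectance * (I - D) / (W - D)`.
#' Pixels where `W - D <= eps` are flagged invalid (`NA`) and counted in the
#' result's `meta$nInvalid`; they are excluded from downstream means.
#'
#' @param raw a raw-intensity [Hypercube-class].
#' @param cal a [CalibrationPair-class] (averaged beforehand); raw-frame
#'   references are reconstructed on the fly.
#' @param eps guard for the white-minus-dark denominator; default `1e-6` of
#'   full scale, taken as the maximum white signal.
#' @return a reflectance [Hypercube-class].
#' @examples
#' # I = 5, D = 1, W = 9 gives R = 0.95 * 4/8 = 0.475
#' @export
calibrate <- function(raw, cal, eps = NULL) {
  stopifnot(is(raw, "Hypercube"), is(cal, "CalibrationPair"))
  W <- .asCube(cal@white)@data
  D <- .asCube(cal@dark)@data
  I <- raw@data
  if (!identical(dim(W), dim(I)) || !identical(dim(D), dim(I)))
    stop("calibration references do not match the target cube shape")
  denom <- W - D
  if (is.null(eps)) eps <- 1e-6 * max(W)
  bad <- denom <= eps
  if (all(bad)) stop("calibration failed: white - dark <= eps everywhere")
  R <- cal@whiteReflectance * (I - D) / denom
  R[bad] <- NA_real_
  R[R < 0 & !is.na(R)] <- 0
  Hypercube(R, raw@bandCentersNm, kind = "reflectance",
            meta = c(raw@meta, list(nInvalid = sum(bad))))
}

#' Clip glare pixels to a maximum reflectance
#'
#' Specular glare on wet tissue saturates the sensor and produces
#' anomalously high reflectance; values above `maxValue` are thresholded
#' rather than removed, and the clip count is recorded in `meta$nClipped`.
#'
#' @param cube a reflectance [Hypercube-class].
#' @param maxValue clipping ceiling (default 1).
#' @return the clipped [Hypercube-class].
#' @export
clipGlare <- function(cube, maxValue = 1.0) {
  stopifnot(is(cube, "Hypercube"))
  if (cube@kind != "reflectance")
    stop("clipGlare expects a reflectance cube")
  d <- cube@data
  over <- !is.na(d) & d > maxValue
  d[over] <- maxValue
  Hypercube(d, cube@bandCentersNm, kind = "reflectance",
            meta = c(cube@meta, list(nClipped = sum(over))))
}

#' Mean spectrum over a region of interest
#'
#' Per-band mean reflectance over the masked pixels, excluding invalid
#' (`NA`) pixels band-wise.
#'
#' @param cube a reflectance [Hypercube-class].
#' @param mask logical matrix matching the cube's spatial shape, with at
#'   least one `TRUE` pixel.
#' @param label label for the returned curve.
#' @return a [SpectralCurve-class] on the cube's band centers.
#' @export
roiMeanSpectrum <- function(cube, mask, label = "ROI") {
  stopifnot(is(cube, "Hypercube"))
  d <- cube@data
  if (!identical(dim(mask), dim(d)[1:2]))
    stop("mask shape does not match the cube's spatial shape")
  if (!any(mask)) stop("empty ROI mask")
  vals <- vapply(seq_len(dim(d)[3]), function(b) {
    v <- d[, , b][mask]
    mean(v, na.rm = TRUE)
  }, numeric(1))
  SpectralCurve(cube@bandCentersNm, vals, label = label)
}
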