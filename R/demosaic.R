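# Demosaicing: removal of the periodic mosaic pattern from full-resolution
# raw frames by white-reference calibration (WRC), Fourier low-pass notch
# filtering (LPF), or filter-kernel convolution (FC).

.demosaicResult <- function(field, method, params) {
  new("DemosaicResult", image = minmax01(field), field = field,
      method = method, params = params)
}

#' White-reference-calibration demosaicing
#'
#' Element-wise division of the raw frame by the (temporally averaged)
#' white-reference mosaic of the same camera cancels the per-cell filter
#' gain pattern. Pixels where the white frame is at or below `eps` are
#' flagged invalid; the ratio image is min-max normalized to `[0, 1]`
#' (a constant ratio maps to all zeros).
#'
#' @param raw,white [RawMosaicFrame-class]s of equal shape; `white` should
#'   be a temporal average of white-reference acquisitions.
#' @param eps validity guard on the white frame; default `1e-6` of its
#'   maximum.
#' @return a [DemosaicResult-class] (`method = "WRC"`).
#' @export
demosaicWRC <- function(raw, white, eps = NULL) {
  stopifnot(is(raw, "RawMosaicFrame"), is(white, "RawMosaicFrame"))
  I <- raw@pixels; W <- white@pixels
  if (!identical(dim(I), dim(W)))
    stop("raw and white frames must have equal shape")
  if (is.null(eps)) eps <- 1e-6 * max(W)
  bad <- W <= eps
  if (all(bad)) stop("white frame has no usable (above-eps) pixels")
  out <- I / W
  out[bad] <- NA_real_
  .demosaicResult(out, "WRC", list(eps = eps, nInvalid = sum(bad)))
}

#' Fourier low-pass notch demosaicing
#'
#' The periodic mosaic pattern behaves as high-frequency noise concentrated
#' at harmonics of 1/period. The frame is transformed with a 2D FFT;
#' frequency bins outside a protected central disk of radius
#' `keepRadiusFrac * Nyquist` whose magnitude exceeds
#' `notchThreshold * max(|F|)` (maximum taken outside DC) are zeroed; the
#' real part of the inverse transform is min-max normalized to `[0, 1]`.
#' Zeroing removes the full complex bin (magnitude and phase).
#'
#' @param raw a [RawMosaicFrame-class].
#' @param keepRadiusFrac protected-disk radius as a fraction of Nyquist, in
#'   `(0, 0.5]`; default `1/(2*period)` so the first mosaic harmonic falls
#'   outside the disk. Tuning starting point, not a calibrated constant.
#' @param notchThreshold relative magnitude threshold for zeroing, `>= 0`;
#'   default 0.1.
#' @return a [DemosaicResult-class] (`method = "LPF"`).
#' @export
demosaicLPF <- function(raw, keepRadiusFrac = NULL, notchThreshold = 0.1) {
  stopifnot(is(raw, "RawMosaicFrame"))
  p <- mosaicPeriod(raw)
  if (is.null(keepRadiusFrac)) keepRadiusFrac <- 1 / (2 * p)
  if (keepRadiusFrac <= 0 || keepRadiusFrac > 0.5)
    stop("'keepRadiusFrac' must be in (0, 0.5]")
  if (notchThreshold < 0) stop("'notchThreshold' must be >= 0")
  img <- raw@pixels
  n <- nrow(img); w <- ncol(img)
  F <- stats::fft(img)
  # signed frequency coordinates in cycles/pixel
  fr <- ((seq_len(n) - 1) / n); fr[fr >= 0.5] <- fr[fr >= 0.5] - 1
  fc <- ((seq_len(w) - 1) / w); fc[fc >= 0.5] <- fc[fc >= 0.5] - 1
  dist <- sqrt(outer(fr^2, fc^2, `+`))
  mag <- Mod(F)
  magNoDC <- mag; magNoDC[1, 1] <- 0
  ceilMag <- max(magNoDC)
  protect <- dist <= keepRadiusFrac * 0.5
  kill <- !protect & (mag > notchThreshold * ceilMag)
  F[kill] <- 0
  out <- Re(stats::fft(F, inverse = TRUE)) / (n * w)
  .demosaicResult(out, "LPF",
                  list(keepRadiusFrac = keepRadiusFrac,
                       notchThreshold = notchThreshold,
                       nZeroed = sum(kill)))
}

#' Form the filter-convolution kernel pair
#'
#' A tile-wise sum of the raw frame yields a `period x period` kernel `H`
#' characterizing the relative response of each filter in the array; it is
#' normalized to mean 1 over active cells and paired with its element-wise
#' reciprocal. Inactive cells are assigned the active-cell mean (1).
#'
#' @param raw a [RawMosaicFrame-class].
#' @return an [FCKernelPair-class].
#' @export
formFCKernel <- function(raw) {
  stopifnot(is(raw, "RawMosaicFrame"))
  px <- raw@pixels
  p <- mosaicPeriod(raw)
  layout <- raw@camera@layout
  H <- matrix(0, p, p)
  for (r in seq_len(p)) {
    for (c in seq_len(p)) {
      H[r, c] <- sum(px[seq(r, nrow(px), by = p), seq(c, ncol(px), by = p)])
    }
  }
  active <- !is.na(layout@cellBand)
  if (any(H[active] <= 0))
    stop("zero filter-cell sum; cannot form FC kernel")
  H <- H / mean(H[active])
  H[!active] <- 1
  new("FCKernelPair", H = H, Hinv = 1 / H)
}

#' Filter-convolution demosaicing
#'
#' The raw frame is convolved (phase-preserving tile-replicated border, so
#' the mosaic pattern continues across the frame edge) with the response
#' kernel `H` and with its reciprocal `H^-1`; each branch is normalized to unit
#' mean and the two are averaged, cancelling the periodic gain pattern to
#' second order (the log-gains enter the two branches with opposite sign).
#' An unsharp step then restores edge sharpness; the display image is the
#' min-max normalized result.
#'
#' @param raw a [RawMosaicFrame-class].
#' @param sigma,amount unsharp parameters, see [unsharpMask()].
#' @param kernels optional precomputed [FCKernelPair-class] (e.g. from a
#'   white-reference frame); defaults to kernels formed from `raw` itself.
#' @return a [DemosaicResult-class] (`method = "FC"`).
#' @export
demosaicFC <- function(raw, sigma = 1.0, amount = 0.5, kernels = NULL) {
  stopifnot(is(raw, "RawMosaicFrame"))
  if (is.null(kernels)) kernels <- formFCKernel(raw)
  px <- raw@pixels
  p <- mosaicPeriod(raw)
  A <- convolveReflect(px, kernels@H, tilePeriod = p)
  B <- convolveReflect(px, kernels@Hinv, tilePeriod = p)
  out <- (A / mean(A) + B / mean(B)) / 2
  if (amount > 0)
    out <- out + amount * (out - gaussianBlur(out, sigma))
  .demosaicResult(out, "FC", list(sigma = sigma, amount = amount))
}

#' Unsharp masking
#'
#' `out = image + amount * (image - gaussianBlur(image, sigma))`, clipped
#' to `[0, 1]`. `amount = 0` is the identity (up to clipping).
#'
#' @param image numeric matrix with values in `[0, 1]`.
#' @param sigma Gaussian blur standard deviation in pixels, `> 0`.
#' @param amount sharpening strength, `>= 0`.
#' @return sharpened matrix, clipped to `[0, 1]`.
#' @export
unsharpMask <- function(image, sigma = 1.0, amount = 0.5) {
  if (sigma <= 0) stop("'sigma' must be > 0")
  if (amount < 0) stop("'amount' must be >= 0")
  if (amount == 0) return(pmin(pmax(image, 0), 1))
  out <- image + amount * (image - gaussianBlur(image, sigma))
  pmin(pmax(out, 0), 1)
}
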