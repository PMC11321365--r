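# Spectral validation: resampling reference curves onto camera bands,
# least-squares scale alignment, percent RMSE, and summary tables.

#' Resample a reference spectrum onto camera band centers
#'
#' Linear interpolation of the reference at each band center. Band centers
#' outside the reference's wavelength support are excluded (never
#' extrapolated) and reported; camera ranges commonly extend marginally
#' beyond spectrophotometer calibration ranges.
#'
#' @param ref a [SpectralCurve-class] with >= 2 samples.
#' @param bandCentersNm target band centers (nm).
#' @return list with `curve` (a [SpectralCurve-class] on the in-range band
#'   centers) and `excluded` (the out-of-range band centers).
#' @export
resampleReference <- function(ref, bandCentersNm) {
  stopifnot(is(ref, "SpectralCurve"))
  if (length(ref@values) < 2)
    stop("reference spectrum needs at least 2 samples")
  v <- interpCurve(ref, bandCentersNm)
  inRange <- !is.na(v)
  if (!any(inRange))
    stop("no band centers fall inside the reference spectrum's range")
  list(curve = SpectralCurve(bandCentersNm[inRange], v[inRange],
                             label = ref@label),
       excluded = bandCentersNm[!inRange])
}

#' Least-squares scale alignment between measured and reference spectra
#'
#' Systems producing relative (not absolute) reflectance are compared to
#' spectrometer curves after a single multiplicative gain fitted by least
#' squares: `gain = <measured, ref> / <ref, ref>`. The gain is returned,
#' not applied.
#'
#' @param measured,ref [SpectralCurve-class]s on common wavelengths (after
#'   resampling), >= 2 points.
#' @return the scalar gain.
#' @export
scaleAlign <- function(measured, ref) {
  stopifnot(is(measured, "SpectralCurve"), is(ref, "SpectralCurve"))
  if (length(measured@values) != length(ref@values) ||
      max(abs(measured@wavelengthsNm - ref@wavelengthsNm)) > 1e-9)
    stop("curves must share wavelengths; resample first")
  if (length(ref@values) < 2) stop("need at least 2 points")
  denom <- sum(ref@values^2)
  if (denom <= 0) stop("reference spectrum is identically zero")
  sum(measured@values * ref@values) / denom
}

#' Percent RMSE between two spectra
#'
#' `100 * sqrt(mean((measured - ref)^2))` with reflectance on the 0-1
#' scale; symmetric in its arguments.
#'
#' @param measured,ref [SpectralCurve-class]s (or bare numeric vectors) on
#'   common wavelengths, excluded bands already removed.
#' @return RMSE in percentage points.
#' @examples
#' a <- SpectralCurve(c(500, 600), c(0.1, 0.5))
#' b <- SpectralCurve(c(500, 600), c(0.2, 0.3))
#' spectralRMSE(a, b)  # 15.81
#' @export
spectralRMSE <- function(measured, ref) {
  mv <- if (is(measured, "SpectralCurve")) measured@values else measured
  rv <- if (is(ref, "SpectralCurve")) ref@values else ref
  if (length(mv) != length(rv))
    stop("spectra must have equal length (remove excluded bands first)")
  if (is(measured, "SpectralCurve") && is(ref, "SpectralCurve") &&
      max(abs(measured@wavelengthsNm - ref@wavelengthsNm)) > 1e-9)
    stop("spectra must share wavelengths")
  100 * sqrt(mean((mv - rv)^2))
}

#' Summary of per-tile RMSE values
#'
#' Arithmetic mean and sample standard deviation (n-1 denominator) of a set
#' of per-tile percent RMSEs, as reported in `mean +/- SD` form. With a
#' single value the SD is undefined and reported as 0 with `sdDefined =
#' FALSE`.
#'
#' @param rmse numeric vector of percent RMSE values, length >= 1.
#' @param digits rounding used in the formatted report (default 2).
#' @return list with `mean`, `sd`, `n`, `sdDefined`, and `formatted`
#'   ("mean±SD", rounded).
#' @export
rmseTable <- function(rmse, digits = 2) {
  rmse <- as.numeric(rmse)
  if (!length(rmse)) stop("rmseTable needs at least one value")
  n <- length(rmse)
  m <- mean(rmse)
  sdDefined <- n > 1
  s <- if (sdDefined) stats::sd(rmse) else 0
  list(mean = m, sd = s, n = n, sdDefined = sdDefined,
       formatted = sprintf("%.*f±%.*f", digits, m, digits, s))
}
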