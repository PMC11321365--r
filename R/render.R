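# Pseudo-RGB rendering by nearest-band selection.

#' Index of the band nearest a target wavelength
#'
#' Minimizes `|center - target|`; ties break to the lower index.
#'
#' @param bandCentersNm band-center wavelengths (nm), or a
#'   [Hypercube-class]/[CameraSpec-class].
#' @param targetNm target wavelength (nm).
#' @return 1-based band index.
#' @export
nearestBand <- function(bandCentersNm, targetNm) {
  if (is(bandCentersNm, "Hypercube") || is(bandCentersNm, "CameraSpec"))
    bandCentersNm <- bandCenters(bandCentersNm)
  if (!length(bandCentersNm)) stop("no bands")
  which.min(abs(bandCentersNm - targetNm))
}

#' Pseudo-RGB rendering of a hypercube
#'
#' Selects the bands nearest the canonical red, green and blue primaries
#' (700.0, 546.1 and 435.8 nm by default) and stacks them as an RGB image,
#' clipped to `[0, 1]`. No white balance or gamma is applied; an optional
#' percentile stretch is available for display.
#'
#' @param cube a reflectance [Hypercube-class].
#' @param targets length-3 target wavelengths (nm) in R, G, B order.
#' @param stretch optional percentile (e.g. 0.99) for a symmetric
#'   percentile stretch per channel; `NULL` (default) leaves values as-is.
#' @return rows x cols x 3 array with attribute `"bands"` giving the
#'   selected band indices.
#' @export
pseudoRGB <- function(cube, targets = c(700.0, 546.1, 435.8),
                      stretch = NULL) {
  stopifnot(is(cube, "Hypercube"), length(targets) == 3)
  idx <- vapply(targets, function(t) nearestBand(cube, t), integer(1))
  img <- cube@data[, , idx, drop = FALSE]
  if (!is.null(stretch)) {
    stopifnot(stretch > 0, stretch <= 1)
    for (k in 1:3) {
      ch <- img[, , k]
      q <- stats::quantile(ch, c(1 - stretch, stretch), na.rm = TRUE,
                           names = FALSE)
      if (q[2] > q[1]) img[, , k] <- (ch - q[1]) / (q[2] - q[1])
    }
  }
  img[!is.na(img) & img < 0] <- 0
  img[!is.na(img) & img > 1] <- 1
  attr(img, "bands") <- idx
  img
}
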