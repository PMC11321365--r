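# Camera model: mosaic layouts, camera presets, JSON configs, filter banks.

#' Construct a mosaic layout
#'
#' By default bands are assigned row-major within the tile in ascending
#' wavelength order; when `nBands < period^2`, trailing cells (ending at the
#' bottom-right corner) are inactive and their sensor samples are never read.
#' A custom `cellBand` matrix overrides the default assignment.
#'
#' @param period integer tile edge in pixels.
#' @param nBands number of active bands, `<= period^2`; default `period^2`.
#' @param cellBand optional `period x period` integer matrix of band indices
#'   (1..B, `NA` = inactive cell).
#' @return a [MosaicLayout-class].
#' @examples
#' MosaicLayout(4)            # 16 bands, fully populated
#' MosaicLayout(5, nBands = 24)  # bottom-right cell inactive
#' @export
MosaicLayout <- function(period, nBands = period^2, cellBand = NULL) {
  period <- as.integer(period)
  if (is.null(cellBand)) {
    v <- rep(NA_integer_, period^2)
    v[seq_len(nBands)] <- seq_len(nBands)
    cellBand <- matrix(v, nrow = period, ncol = period, byrow = TRUE)
  } else {
    cellBand <- matrix(as.integer(cellBand), nrow = period, ncol = period)
  }
  new("MosaicLayout", period = period, cellBand = cellBand)
}

#' Tile-cell position of each band
#'
#' @param layout a [MosaicLayout-class].
#' @return integer matrix B x 2 of (row, col) cell coordinates within the
#'   tile, 1-based, ordered by band index.
#' @export
bandCells <- function(layout) {
  cb <- layout@cellBand
  idx <- which(!is.na(cb), arr.ind = TRUE)
  idx[order(cb[idx]), , drop = FALSE]
}

#' Construct a camera specification
#'
#' @param name camera label.
#' @param bandCentersNm strictly ascending band centers (nm).
#' @param layout a [MosaicLayout-class] (or integer period, in which case a
#'   default layout for `length(bandCentersNm)` bands is built).
#' @param bitDepth ADC bit depth.
#' @param filterFwhmNm filter FWHM in nm, scalar or per band (simulation
#'   only).
#' @return a [CameraSpec-class].
#' @export
cameraSpec <- function(name, bandCentersNm, layout, bitDepth = 10L,
                       filterFwhmNm = 15) {
  if (is.numeric(layout) && length(layout) == 1L)
    layout <- MosaicLayout(layout, nBands = length(bandCentersNm))
  new("CameraSpec", name = as.character(name),
      bandCentersNm = as.numeric(bandCentersNm), layout = layout,
      bitDepth = as.integer(bitDepth),
      filterFwhmNm = as.numeric(filterFwhmNm))
}

#' Built-in camera presets
#'
#' Three snapshot-mosaic cameras as used in dual-camera laparoscopic
#' hyperspectral imaging:
#' \describe{
#'   \item{VIS}{16 bands, 4x4 mosaic, 461-597 nm.}
#'   \item{RNIR}{15 bands, 4x4 mosaic (one inactive cell), 614-853 nm.}
#'   \item{NIR}{24 bands, 5x5 mosaic (one inactive cell), 669-949 nm.}
#' }
#' Only the realized range endpoints are published for these cameras, so the
#' presets place band centers uniformly between them.
#'
#' @param name one of `"VIS"`, `"RNIR"`, `"NIR"`.
#' @return a [CameraSpec-class].
#' @examples
#' cameraPreset("VIS")
#' @export
cameraPreset <- function(name = c("VIS", "RNIR", "NIR")) {
  name <- match.arg(name)
  switch(name,
    VIS  = cameraSpec("VIS",  seq(461, 597, length.out = 16), 4L),
    RNIR = cameraSpec("RNIR", seq(614, 853, length.out = 15), 4L),
    NIR  = cameraSpec("NIR",  seq(669, 949, length.out = 24), 5L))
}

# JSON uses 0 as the inactive-cell sentinel and 1-based band indices.
.layoutToJson <- function(layout) {
  cb <- layout@cellBand
  cb[is.na(cb)] <- 0L
  unname(lapply(seq_len(nrow(cb)), function(i) as.integer(cb[i, ])))
}

.layoutFromJson <- function(period, rows) {
  cb <- do.call(rbind, lapply(rows, as.integer))
  cb[cb == 0L] <- NA_integer_
  MosaicLayout(period, cellBand = cb)
}

#' Read / write camera configuration JSON
#'
#' The config is a JSON object with keys `name`, `band_centers_nm`,
#' `period`, `bit_depth`, `filter_fwhm_nm` and optional `cell_band`
#' (`period x period` rows of 1-based band indices, 0 marking an inactive
#' cell). Omitting `cell_band` yields the default row-major ascending
#' assignment.
#'
#' @param path file path of the JSON config.
#' @return `loadCameraSpec`: a validated [CameraSpec-class];
#'   `writeCameraSpec`: `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".json")
#' writeCameraSpec(cameraPreset("NIR"), f)
#' loadCameraSpec(f)
#' @export
loadCameraSpec <- function(path) {
  if (!file.exists(path)) stop("camera config not found: ", path)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyMatrix = FALSE)
  for (key in c("name", "band_centers_nm", "period")) {
    if (is.null(cfg[[key]]))
      stop("camera config missing required field '", key, "'")
  }
  if (!is.numeric(cfg$band_centers_nm) || length(cfg$band_centers_nm) < 1L)
    stop("camera config field 'band_centers_nm' must be a numeric vector")
  period <- as.integer(cfg$period)
  if (is.na(period) || period < 1L)
    stop("camera config field 'period' must be a positive integer")
  nb <- length(cfg$band_centers_nm)
  layout <- if (!is.null(cfg$cell_band)) {
    .layoutFromJson(period, cfg$cell_band)
  } else {
    if (nb > period^2)
      stop(sprintf(
        "camera config inconsistent: %d bands declared for a %dx%d layout (%d cells)",
        nb, period, period, period^2))
    MosaicLayout(period, nBands = nb)
  }
  if (nb != nBands(layout))
    stop(sprintf(
      "camera config inconsistent: %d band centers but %d active layout cells",
      nb, nBands(layout)))
  cameraSpec(cfg$name, cfg$band_centers_nm, layout,
             bitDepth = if (is.null(cfg$bit_depth)) 10L else cfg$bit_depth,
             filterFwhmNm = if (is.null(cfg$filter_fwhm_nm)) 15
                            else cfg$filter_fwhm_nm)
}

#' @rdname loadCameraSpec
#' @param spec a [CameraSpec-class] to serialize.
#' @export
writeCameraSpec <- function(spec, path) {
  stopifnot(is(spec, "CameraSpec"))
  cfg <- list(name = spec@name,
              band_centers_nm = spec@bandCentersNm,
              period = spec@layout@period,
              cell_band = .layoutToJson(spec@layout),
              bit_depth = spec@bitDepth,
              filter_fwhm_nm = spec@filterFwhmNm)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Gaussian filter bank for a camera
#'
#' Models each band's transmission as a unit-peak Gaussian
#' `exp(-4 ln2 (lambda - center)^2 / FWHM^2)` sampled on `grid`.
#'
#' @param spec a [CameraSpec-class].
#' @param grid ascending wavelength grid (nm) covering all band centers.
#' @return a [FilterBank-class], one row per band.
#' @examples
#' fb <- gaussianFilterBank(cameraPreset("VIS"), seq(400, 700, by = 1))
#' dim(fb@transmission)  # 16 bands x grid
#' @export
gaussianFilterBank <- function(spec, grid) {
  grid <- as.numeric(grid)
  if (is.unsorted(grid, strictly = TRUE))
    stop("wavelength grid must be strictly ascending")
  bc <- spec@bandCentersNm
  if (min(bc) < min(grid) || max(bc) > max(grid))
    stop("wavelength grid does not cover all band centers")
  fwhm <- rep_len(spec@filterFwhmNm, length(bc))
  tr <- t(vapply(seq_along(bc), function(b) {
    exp(-4 * log(2) * (grid - bc[b])^2 / fwhm[b]^2)
  }, numeric(length(grid))))
  new("FilterBank", wavelengthGridNm = grid, transmission = tr)
}
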