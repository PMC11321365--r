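# Raster and spectrum I/O: multi-page TIFF frame sequences, hypercube
# serialization (TIFF stack + JSON sidecar, or ENVI BSQ), CSV spectra.

#' Construct a hypercube
#'
#' @param data numeric 3D array, rows x cols x bands.
#' @param bandCentersNm one wavelength per band (nm).
#' @param kind `"raw_intensity"` or `"reflectance"`.
#' @param meta optional metadata list.
#' @return a [Hypercube-class].
#' @export
Hypercube <- function(data, bandCentersNm,
                      kind = c("raw_intensity", "reflectance"),
                      meta = list()) {
  new("Hypercube", data = data, bandCentersNm = as.numeric(bandCentersNm),
      kind = match.arg(kind), meta = meta)
}

#' Construct a spectral curve
#'
#' @param wavelengthsNm wavelengths (nm); reordered ascending together with
#'   `values` if needed.
#' @param values reflectance values, same length.
#' @param label curve label.
#' @return a [SpectralCurve-class].
#' @export
SpectralCurve <- function(wavelengthsNm, values, label = "") {
  o <- order(wavelengthsNm)
  new("SpectralCurve", wavelengthsNm = as.numeric(wavelengthsNm)[o],
      values = as.numeric(values)[o], label = as.character(label))
}

# Crop a raster so both dimensions divide the mosaic period, dropping
# trailing rows/columns (mosaic phase stays anchored at the top-left origin).
.cropToPeriod <- function(m, period, warn = TRUE) {
  d <- dim(m)
  keep <- d - d %% period
  if (any(keep < d)) {
    if (warn)
      warning(sprintf("cropping frame %dx%d -> %dx%d to match period %d",
                      d[1], d[2], keep[1], keep[2], period))
    m <- m[seq_len(keep[1]), seq_len(keep[2]), drop = FALSE]
  }
  m
}

#' Read a raw mosaic frame sequence from multi-page TIFF
#'
#' Pages are read in file order (and files in the order given, after glob
#' expansion). Frames whose dimensions do not divide the mosaic period are
#' cropped by dropping trailing rows/columns, with a warning.
#'
#' @param paths file path(s); glob patterns are expanded.
#' @param camera the acquiring [CameraSpec-class].
#' @return list of [RawMosaicFrame-class], page/file order.
#' @export
readFrameSequence <- function(paths, camera) {
  expanded <- unlist(lapply(paths, function(p) {
    g <- Sys.glob(p)
    if (length(g)) g else p
  }))
  missing <- expanded[!file.exists(expanded)]
  if (length(missing))
    stop("frame file(s) not found: ", paste(missing, collapse = ", "))
  frames <- list()
  p <- mosaicPeriod(camera)
  for (f in expanded) {
    pages <- tiff::readTIFF(f, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    for (k in seq_along(pages)) {
      page <- pages[[k]]
      if (length(dim(page)) == 3L)
        stop("multi-channel (e.g. RGB) TIFF is not a raw mosaic frame: ", f)
      page <- .cropToPeriod(page, p)
      frames[[length(frames) + 1L]] <-
        new("RawMosaicFrame", pixels = page, camera = camera,
            meta = list(file = f, page = k))
    }
  }
  if (!length(frames)) stop("empty frame sequence")
  frames
}

#' Write a raw mosaic frame sequence to multi-page TIFF
#'
#' Counts are stored as 16-bit unsigned integers (rounded); the camera's ADC
#' range must fit.
#'
#' @param frames list of [RawMosaicFrame-class] or numeric matrices.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
writeFrameSequence <- function(frames, path) {
  pages <- lapply(frames, function(fr) {
    m <- if (is(fr, "RawMosaicFrame")) fr@pixels else fr
    if (max(m) > 65535) stop("counts exceed 16-bit storage range")
    round(m) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Write / read a hypercube
#'
#' Two dialects:
#' \describe{
#'   \item{tiff_stack}{one 32-bit float TIFF page per band in ascending
#'     wavelength plus a JSON sidecar (`<path>.json`) holding band centers,
#'     kind and the scale factor used to map data into the TIFF's `[0, 1]`
#'     storage range. Non-finite values are rejected (use `envi` for cubes
#'     carrying invalid-pixel NAs).}
#'   \item{envi}{ENVI BSQ: 32-bit little-endian float `.dat` plus a text
#'     `.hdr` declaring samples/lines/bands, interleave and wavelengths.
#'     `NA`/`NaN` round-trips.}
#' }
#' A write/read round trip preserves data to float32 precision and the band
#' metadata exactly.
#'
#' @param cube a [Hypercube-class].
#' @param path output path (for `envi`, the `.hdr`/`.dat` pair shares this
#'   base name).
#' @param dialect `"tiff_stack"` or `"envi"`.
#' @return `writeHypercube`: `path` invisibly; `readHypercube`: a
#'   [Hypercube-class].
#' @export
writeHypercube <- function(cube, path, dialect = c("tiff_stack", "envi")) {
  dialect <- match.arg(dialect)
  stopifnot(is(cube, "Hypercube"))
  if (dialect == "tiff_stack") .writeCubeTiff(cube, path)
  else .writeCubeEnvi(cube, path)
  invisible(path)
}

#' @rdname writeHypercube
#' @export
readHypercube <- function(path, dialect = NULL) {
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.(hdr|dat)$", path, ignore.case = TRUE)) "envi"
               else "tiff_stack"
  }
  dialect <- match.arg(dialect, c("tiff_stack", "envi"))
  if (dialect == "tiff_stack") .readCubeTiff(path) else .readCubeEnvi(path)
}

.writeCubeTiff <- function(cube, path) {
  d <- cube@data
  if (any(!is.finite(d)))
    stop("tiff_stack dialect cannot store non-finite values; use 'envi'")
  lo <- min(d); hi <- max(d)
  scale <- max(hi, 1)
  offset <- 0
  if (lo < 0) { offset <- lo; scale <- max(hi - lo, 1) }
  pages <- lapply(seq_len(dim(d)[3]),
                  function(b) (d[, , b] - offset) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  sidecar <- list(band_centers_nm = cube@bandCentersNm, kind = cube@kind,
                  scale = scale, offset = offset)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

.readCubeTiff <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side))
    stop("missing sidecar metadata: ", side)
  meta <- jsonlite::fromJSON(side)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- array(0, c(dim(pages[[1]]), length(pages)))
  for (b in seq_along(pages))
    d[, , b] <- pages[[b]] * meta$scale + meta$offset
  Hypercube(d, meta$band_centers_nm, kind = meta$kind)
}

.enviDatPath <- function(path) sub("\\.hdr$", ".dat", path)
.enviHdrPath <- function(path) {
  if (grepl("\\.hdr$", path)) path
  else if (grepl("\\.dat$", path)) sub("\\.dat$", ".hdr", path)
  else paste0(path, ".hdr")
}

.writeCubeEnvi <- function(cube, path) {
  hdr <- .enviHdrPath(path)
  dat <- .enviDatPath(hdr)
  d <- cube@data
  dims <- dim(d)
  # BSQ: band-sequential, each band stored line (row) by line.
  con <- file(dat, "wb")
  on.exit(close(con))
  for (b in seq_len(dims[3]))
    writeBin(as.numeric(t(d[, , b])), con, size = 4, endian = "little")
  lines <- c(
    "ENVI",
    "description = {hypercube written by mosaicHSI}",
    sprintf("samples = %d", dims[2]),
    sprintf("lines = %d", dims[1]),
    sprintf("bands = %d", dims[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    "interleave = bsq",
    "byte order = 0",
    sprintf("cube kind = %s", cube@kind),
    sprintf("wavelength units = nm"),
    sprintf("wavelength = {%s}",
            paste(format(cube@bandCentersNm, digits = 15), collapse = ", ")))
  writeLines(lines, hdr)
}

.parseEnviHeader <- function(hdr) {
  txt <- paste(readLines(hdr, warn = FALSE), collapse = "\n")
  getField <- function(key, required = TRUE) {
    m <- regmatches(txt, regexec(
      paste0("(?mi)^", key, "\\s*=\\s*(\\{[^}]*\\}|[^\n]*)"), txt,
      perl = TRUE))[[1]]
    if (length(m) < 2) {
      if (required) stop("ENVI header missing field '", key, "': ", hdr)
      return(NULL)
    }
    trimws(gsub("[{}]", "", m[2]))
  }
  list(samples = as.integer(getField("samples")),
       lines = as.integer(getField("lines")),
       bands = as.integer(getField("bands")),
       dataType = as.integer(getField("data type")),
       interleave = tolower(getField("interleave")),
       kind = getField("cube kind", required = FALSE),
       wavelength = as.numeric(strsplit(getField("wavelength"),
                                        ",")[[1]]))
}

.readCubeEnvi <- function(path) {
  hdr <- .enviHdrPath(path)
  if (!file.exists(hdr)) stop("missing ENVI header: ", hdr)
  h <- .parseEnviHeader(hdr)
  if (h$dataType != 4L)
    stop("only ENVI data type 4 (float32) is supported")
  if (h$interleave != "bsq")
    stop("only BSQ interleave is supported")
  dat <- .enviDatPath(hdr)
  con <- file(dat, "rb")
  on.exit(close(con))
  n <- h$samples * h$lines * h$bands
  v <- readBin(con, "numeric", n = n, size = 4, endian = "little")
  d <- array(0, c(h$lines, h$samples, h$bands))
  per <- h$samples * h$lines
  for (b in seq_len(h$bands))
    d[, , b] <- t(matrix(v[((b - 1) * per + 1):(b * per)],
                         nrow = h$samples))
  kind <- if (is.null(h$kind)) "raw_intensity" else h$kind
  Hypercube(d, h$wavelength, kind = kind)
}

#' Read a two-column reflectance spectrum CSV
#'
#' Columns are wavelength (nm) and reflectance; a non-numeric header row is
#' skipped. Rows are sorted ascending by wavelength; duplicate wavelengths
#' are an error.
#'
#' @param path CSV file path.
#' @param label curve label; defaults to the file base name.
#' @return a [SpectralCurve-class].
#' @export
readSpectrumCSV <- function(path, label = NULL) {
  if (!file.exists(path)) stop("spectrum file not found: ", path)
  raw <- utils::read.csv(path, header = FALSE,
                         stringsAsFactors = FALSE,
                         colClasses = "character")
  if (ncol(raw) < 2) stop("spectrum CSV must have two columns: ", path)
  # drop a header row if the first row is not numeric
  first <- suppressWarnings(as.numeric(raw[1, 1:2]))
  if (any(is.na(first))) raw <- raw[-1, , drop = FALSE]
  wl <- suppressWarnings(as.numeric(raw[[1]]))
  v <- suppressWarnings(as.numeric(raw[[2]]))
  if (any(is.na(wl)) || any(is.na(v)))
    stop("non-numeric rows in spectrum CSV: ", path)
  if (length(wl) < 2) stop("spectrum needs at least 2 samples: ", path)
  if (anyDuplicated(wl)) stop("duplicate wavelengths in spectrum CSV: ", path)
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  SpectralCurve(wl, v, label = label)
}

#' Write a spectral curve to CSV
#' @param curve a [SpectralCurve-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeSpectrumCSV <- function(curve, path) {
  utils::write.table(
    data.frame(wavelength_nm = curve@wavelengthsNm,
               reflectance = curve@values),
    path, sep = ",", row.names = FALSE, col.names = TRUE, quote = FALSE)
  invisible(path)
}
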