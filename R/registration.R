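# Dual-camera registration: spectral-mean collapse, binarization,
# control-point affine estimation, and per-band warping.

#' Collapse a hypercube to its spectral-mean image
#'
#' Per-pixel mean over bands, excluding invalid (`NA`) bands pixel-wise;
#' used to produce a single grayscale image for mask generation and
#' registration.
#'
#' @param cube a [Hypercube-class].
#' @return numeric matrix of the cube's spatial shape.
#' @export
spectralMeanImage <- function(cube) {
  stopifnot(is(cube, "Hypercube"))
  rowMeans(cube@data, dims = 2, na.rm = TRUE)
}

#' Threshold an image into a boolean mask
#'
#' `mask = image >= threshold`. The threshold is scene-dependent and chosen
#' by the user (no automatic selection).
#'
#' @param image numeric matrix.
#' @param threshold finite scalar.
#' @return logical matrix.
#' @export
binarizeImage <- function(image, threshold) {
  if (!is.finite(threshold)) stop("'threshold' must be finite")
  image >= threshold
}

#' Construct an affine transform
#' @param A 2 x 2 linear part (non-singular).
#' @param t length-2 translation (rows, cols).
#' @return an [AffineTransform-class].
#' @export
affineTransform <- function(A = diag(2), t = c(0, 0)) {
  new("AffineTransform", matrix = cbind(A, t, deparse.level = 0))
}

#' Estimate an affine transform from control points
#'
#' Least-squares solution of `dst ~ A src + t` from paired control points;
#' exact for 3 non-collinear pairs. Coordinates are (row, col) pixel
#' centers.
#'
#' @param src,dst numeric n x 2 matrices of matched (row, col) points,
#'   n >= 3, not collinear.
#' @return an [AffineTransform-class] mapping source to destination.
#' @export
estimateAffine <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  if (nrow(src) != nrow(dst) || ncol(src) != 2 || ncol(dst) != 2)
    stop("'src' and 'dst' must be matched n x 2 point sets")
  if (nrow(src) < 3)
    stop("need at least 3 control-point pairs")
  X <- cbind(src, 1)
  if (qr(X)$rank < 3)
    stop("control points are collinear or degenerate")
  # one least-squares solve per output coordinate
  beta <- qr.solve(X, dst)            # 3 x 2: rows = (a_r, a_c, t)
  M <- rbind(c(beta[1, 1], beta[2, 1], beta[3, 1]),
             c(beta[1, 2], beta[2, 2], beta[3, 2]))
  tr <- new("AffineTransform", matrix = M)
  validObject(tr)
  tr
}

#' Apply an affine transform to a point set
#' @param transform an [AffineTransform-class].
#' @param points n x 2 (row, col) matrix.
#' @return transformed n x 2 matrix.
#' @export
transformPoints <- function(transform, points) {
  m <- transform@matrix
  pts <- as.matrix(points)
  t(m[, 1:2] %*% t(pts) + m[, 3])
}

#' Warp a hypercube (or image) with an affine transform
#'
#' Every band is resampled onto the destination grid with bilinear
#' interpolation (nearest-neighbor optional, e.g. for masks) by inverse
#' mapping; destination pixels that map outside the source domain are
#' marked invalid (`NA`). The same transform is applied to every band, as
#' appropriate for rigidly co-mounted cameras.
#'
#' @param x a [Hypercube-class] or numeric matrix (source, e.g. the RNIR
#'   cube).
#' @param transform an [AffineTransform-class] mapping source to
#'   destination (e.g. RNIR to VIS) pixel coordinates.
#' @param outShape destination spatial shape `c(rows, cols)`; defaults to
#'   the source shape.
#' @param interpolation `"bilinear"` or `"nearest"`.
#' @return warped object of the same type as `x`.
#' @export
applyAffine <- function(x, transform, outShape = NULL,
                        interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  m <- transform@matrix
  A <- m[, 1:2]; tr <- m[, 3]
  Ainv <- solve(A)
  isCube <- is(x, "Hypercube")
  src <- if (isCube) x@data else x
  srcDim <- if (isCube) dim(src)[1:2] else dim(src)
  if (is.null(outShape)) outShape <- srcDim
  # inverse map destination pixel centers to source coordinates
  gr <- rep(seq_len(outShape[1]), times = outShape[2])
  gc <- rep(seq_len(outShape[2]), each = outShape[1])
  sp <- Ainv %*% (rbind(gr, gc) - tr)
  sr <- sp[1, ]; sc <- sp[2, ]
  if (interpolation == "nearest") { sr <- round(sr); sc <- round(sc) }
  sampleBand <- function(band) {
    v <- if (interpolation == "nearest") {
      out <- rep(NA_real_, length(sr))
      ok <- sr >= 1 & sr <= srcDim[1] & sc >= 1 & sc <= srcDim[2]
      out[ok] <- band[cbind(sr[ok], sc[ok])]
      out
    } else bilinearSample(band, sr, sc)
    matrix(v, outShape[1], outShape[2])
  }
  if (!isCube) return(sampleBand(src))
  B <- dim(src)[3]
  out <- array(NA_real_, c(outShape, B))
  for (b in seq_len(B)) out[, , b] <- sampleBand(src[, , b])
  Hypercube(out, x@bandCentersNm, kind = x@kind,
            meta = c(x@meta, list(registered = TRUE)))
}

#' Normalized cross-correlation between two images
#'
#' Pearson correlation over pixels finite in both images; used to score
#' post-registration overlap of spectral-mean images.
#'
#' @param a,b numeric matrices of equal shape.
#' @return correlation in `[-1, 1]`.
#' @export
imageNCC <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("images must have equal shape")
  ok <- is.finite(a) & is.finite(b)
  stats::cor(a[ok], b[ok])
}
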