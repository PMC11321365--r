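# Internal numeric helpers shared across modules.

# Min-max normalization to [0, 1]; a (near-)constant image maps to all zeros
# so that degenerate inputs stay displayable. NA entries are preserved.
minmax01 <- function(x) {
  rng <- range(x, na.rm = TRUE)
  if (!all(is.finite(rng)))
    stop("cannot normalize: no finite values")
  # relative tolerance: an image constant up to rounding is degenerate too
  if (rng[2] - rng[1] <= 1e-9 * max(abs(rng), 1)) {
    x[!is.na(x)] <- 0
    return(x)
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

# Reflective (mirror, edge not repeated) padding of a matrix by `m` pixels.
padReflect <- function(x, m) {
  n <- nrow(x); k <- ncol(x)
  if (m >= n || m >= k)
    stop("padding exceeds image size")
  ri <- c((m + 1):2, 1:n, (n - 1):(n - m))
  ci <- c((m + 1):2, 1:k, (k - 1):(k - m))
  x[ri, ci]
}

# Tile-replicating padding: out-of-range indices map to an in-range pixel
# with the same index modulo `period`, so the mosaic phase continues across
# the border (plain mirror reflection breaks it).
padTilePhase <- function(x, m, period) {
  n <- nrow(x); k <- ncol(x)
  mapIdx <- function(i, len) {
    j <- i
    below <- j < 1; above <- j > len
    j[below] <- j[below] + period * ceiling((1 - j[below]) / period)
    j[above] <- j[above] - period * ceiling((j[above] - len) / period)
    j
  }
  x[mapIdx((1 - m):(n + m), n), mapIdx((1 - m):(k + m), k)]
}

# 2D correlation of `img` with small kernel `k`, output the size of `img`.
# Border: mirror reflection, or phase-preserving tile replication when
# `tilePeriod` is given (appropriate for mosaic-matched kernels). Anchor at
# cell (floor((p+1)/2)) so even-sized mosaic kernels are handled
# deterministically.
convolveReflect <- function(img, k, tilePeriod = NULL) {
  kr <- nrow(k); kc <- ncol(k)
  ar <- (kr + 1L) %/% 2L  # anchor row within kernel
  ac <- (kc + 1L) %/% 2L
  m <- max(kr, kc)
  p <- if (is.null(tilePeriod)) padReflect(img, m)
       else padTilePhase(img, m, tilePeriod)
  n <- nrow(img); w <- ncol(img)
  out <- matrix(0, n, w)
  for (i in seq_len(kr)) {
    for (j in seq_len(kc)) {
      if (k[i, j] == 0) next
      r0 <- m + 1L + (i - ar)
      c0 <- m + 1L + (j - ac)
      out <- out + k[i, j] * p[r0:(r0 + n - 1L), c0:(c0 + w - 1L)]
    }
  }
  out
}

# Separable Gaussian blur with reflective border; kernel truncated at
# ceiling(3*sigma).
gaussianBlur <- function(img, sigma) {
  stopifnot(sigma > 0)
  half <- max(1L, as.integer(ceiling(3 * sigma)))
  g <- exp(-((-half:half)^2) / (2 * sigma^2))
  g <- g / sum(g)
  tmp <- convolveReflect(img, matrix(g, ncol = 1))
  convolveReflect(tmp, matrix(g, nrow = 1))
}

# Bilinear sampling of matrix `img` at fractional (row, col) positions;
# points outside the domain return NA.
bilinearSample <- function(img, r, c) {
  n <- nrow(img); w <- ncol(img)
  out <- rep(NA_real_, length(r))
  ok <- r >= 1 & r <= n & c >= 1 & c <= w & is.finite(r) & is.finite(c)
  if (!any(ok)) return(out)
  r <- r[ok]; c <- c[ok]
  r0 <- pmin(floor(r), n - 1L); c0 <- pmin(floor(c), w - 1L)
  fr <- r - r0; fc <- c - c0
  v <- (1 - fr) * (1 - fc) * img[cbind(r0, c0)] +
       fr * (1 - fc) * img[cbind(r0 + 1, c0)] +
       (1 - fr) * fc * img[cbind(r0, c0 + 1)] +
       fr * fc * img[cbind(r0 + 1, c0 + 1)]
  out[ok] <- v
  out
}

# Linear interpolation of a SpectralCurve at `at` (nm); values outside the
# curve's support are NA unless rule = "error".
interpCurve <- function(curve, at, rule = c("na", "error")) {
  rule <- match.arg(rule)
  rng <- range(curve@wavelengthsNm)
  outside <- at < rng[1] | at > rng[2]
  if (rule == "error" && any(outside))
    stop(sprintf("wavelengths %s nm outside curve support %.0f-%.0f nm",
                 paste(at[outside], collapse = ", "), rng[1], rng[2]))
  v <- stats::approx(curve@wavelengthsNm, curve@values, xout = at,
                     method = "linear", rule = 1)$y
  v
}
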