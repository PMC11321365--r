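# Spatial resolution assessment: Michelson contrast from sine fits over
# bar-target intensity profiles, USAF-1951 geometry, resolution-limit search.

#' @rdname michelsonContrast
#' @export
setMethod("michelsonContrast", signature("numeric", "numeric"),
  function(smax, smin) {
    if (smax < smin) stop("smax must be >= smin")
    if (smax + smin <= 0) stop("Michelson contrast undefined: smax + smin <= 0")
    (smax - smin) / (smax + smin)
  })

#' @rdname michelsonContrast
#' @export
setMethod("michelsonContrast", signature("SineFitResult", "missing"),
  function(smax, smin) {
    michelsonContrast(smax@smax, smax@smin)
  })

#' Construct a USAF element handle
#' @param group target group (integer, may be negative).
#' @param element element within the group, 1..6.
#' @return a [UsafElement-class].
#' @export
usafElement <- function(group, element) {
  new("UsafElement", group = as.integer(group), element = as.integer(element))
}

#' USAF-1951 line width in millimeters
#'
#' The target's resolution at group g, element e is
#' `2^(g + (e - 1)/6)` line pairs per mm; one bar is half a line pair, so
#' the line width is `1 / (2 * 2^(g + (e-1)/6))` mm. Full precision is
#' returned; reports conventionally round to 3 decimals (round-half-even),
#' e.g. group 1 elements 1 and 2 give 0.250 and 0.223 mm.
#'
#' @param group target group, or a [UsafElement-class] (then `element` is
#'   ignored).
#' @param element element 1..6.
#' @return line width in mm (full precision).
#' @examples
#' usafLinewidthMm(1, 1)  # 0.25
#' round(usafLinewidthMm(1, 2), 3)  # 0.223
#' @export
usafLinewidthMm <- function(group, element) {
  if (is(group, "UsafElement")) {
    element <- group@element
    group <- group@group
  }
  if (!all(element %in% 1:6)) stop("element must be in 1..6")
  lpPerMm <- 2^(group + (element - 1) / 6)
  1 / (2 * lpPerMm)
}

#' Fit a sinusoid to a bar-element intensity profile
#'
#' Nonlinear least squares of
#' `offset + amplitude * sin(2*pi*f*x + phase)` (x in pixels, 0-based along
#' the profile) by Levenberg-Marquardt with the amplitude constrained
#' nonnegative. Starting values: `f = expectedFreq` with amplitude, offset
#' and phase from a linear sin/cos regression at that frequency.
#'
#' @param profile numeric intensity vector, length >= 8.
#' @param expectedFreq expected bar frequency in cycles/pixel, in (0, 0.5).
#' @param freqFree logical; if `FALSE` the frequency is held at
#'   `expectedFreq`.
#' @return a [SineFitResult-class].
#' @export
fitSineProfile <- function(profile, expectedFreq, freqFree = TRUE) {
  profile <- as.numeric(profile)
  profile <- profile[is.finite(profile)]
  n <- length(profile)
  if (n < 8) stop("profile too short for a sine fit (need >= 8 samples)")
  if (expectedFreq <= 0 || expectedFreq >= 0.5)
    stop("'expectedFreq' must be in (0, 0.5) cycles/pixel")
  x <- seq_len(n) - 1
  # linear-in-parameters initialization at the expected frequency
  S <- sin(2 * pi * expectedFreq * x)
  C <- cos(2 * pi * expectedFreq * x)
  co <- stats::coef(stats::lm(profile ~ S + C))
  a0 <- sqrt(co[2]^2 + co[3]^2)
  phi0 <- atan2(co[3], co[2])
  off0 <- co[1]
  if (!is.finite(a0) || a0 < 1e-12) {
    # (near-)constant profile: no modulation
    fit <- new("SineFitResult", amplitude = 0, offset = mean(profile),
               frequency = expectedFreq, phase = 0,
               smax = mean(profile), smin = mean(profile),
               rmsResidual = stats::sd(profile) *
                 sqrt(max(n - 1, 1) / n))
    return(fit)
  }
  # if the linear fit at the expected frequency is already (numerically)
  # exact, return it: the LM Jacobian is degenerate at a zero residual
  res0 <- profile - (off0 + co[2] * S + co[3] * C)
  rms0 <- sqrt(mean(res0^2))
  if (rms0 <= 1e-7 * (a0 + abs(off0))) {
    return(new("SineFitResult", amplitude = unname(a0),
               offset = unname(off0), frequency = expectedFreq,
               phase = unname(phi0),
               smax = unname(off0 + a0), smin = unname(off0 - a0),
               rmsResidual = rms0))
  }
  resid <- function(p)
    profile - (p[1] + p[2] * sin(2 * pi * p[3] * x + p[4]))
  lower <- c(-Inf, 0, 1e-6, -Inf)
  upper <- c(Inf, Inf, 0.5, Inf)
  if (!freqFree) lower[3] <- upper[3] <- expectedFreq
  fit <- minpack.lm::nls.lm(
    par = c(unname(off0), unname(a0), expectedFreq, unname(phi0)),
    fn = resid, lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  # info codes 1-3 signal convergence in value, parameters or both
  if (!fit$info %in% 1:3)
    stop("sine fit failed to converge: ", fit$message)
  cf <- fit$par
  new("SineFitResult",
      amplitude = cf[2], offset = cf[1], frequency = cf[3], phase = cf[4],
      smax = cf[1] + cf[2], smin = cf[1] - cf[2],
      rmsResidual = sqrt(mean(resid(cf)^2)))
}

# Sample an intensity profile along a segment (1-based pixel-center
# endpoints), bilinear interpolation, ~1 sample per pixel.
extractProfile <- function(image, r0, c0, r1, c1) {
  len <- sqrt((r1 - r0)^2 + (c1 - c0)^2)
  n <- max(8L, as.integer(round(len)) + 1L)
  t <- seq(0, 1, length.out = n)
  bilinearSample(image, r0 + t * (r1 - r0), c0 + t * (c1 - c0))
}

#' Smallest resolved USAF element at a contrast cutoff
#'
#' For each listed element a pixel profile is extracted along its segment
#' (drawn perpendicular to the bars), a sinusoid is fitted at the element's
#' expected bar frequency, and the Michelson contrast is computed. Within
#' each orientation, elements must be ordered coarse to fine; the finest
#' element whose contrast is `>= threshold` (inclusive) is returned.
#'
#' @param image numeric matrix (e.g. a demosaiced image).
#' @param elements data frame with columns `group`, `element`,
#'   `orientation` (`"vertical"` or `"horizontal"`), and segment endpoints
#'   `r0, c0, r1, c1` (1-based pixel centers), ordered coarse to fine.
#' @param mmPerPixel physical sampling pitch of `image` (mm/pixel).
#' @param threshold Michelson contrast cutoff, default 0.20.
#' @return named list per orientation, each with `resolved` (logical),
#'   `group`, `element`, `widthMm` (finest resolved; `NA` and
#'   `resolved = FALSE` when no element passes, i.e. unresolved at the
#'   coarsest element), and `table` of all per-element contrasts.
#' @export
resolutionLimit <- function(image, elements, mmPerPixel, threshold = 0.20) {
  need <- c("group", "element", "orientation", "r0", "c0", "r1", "c1")
  if (!all(need %in% names(elements)))
    stop("'elements' must have columns ", paste(need, collapse = ", "))
  rows <- lapply(seq_len(nrow(elements)), function(i) {
    e <- elements[i, ]
    widthMm <- usafLinewidthMm(e$group, e$element)
    freq <- mmPerPixel / (2 * widthMm)  # cycles per pixel
    prof <- extractProfile(image, e$r0, e$c0, e$r1, e$c1)
    ctr <- tryCatch({
      fit <- fitSineProfile(prof[is.finite(prof)], expectedFreq = freq)
      michelsonContrast(fit)
    }, error = function(err) NA_real_)
    data.frame(group = e$group, element = e$element,
               orientation = e$orientation, widthMm = widthMm,
               expectedFreq = freq, contrast = ctr)
  })
  tab <- do.call(rbind, rows)
  out <- list()
  for (orient in unique(tab$orientation)) {
    sub <- tab[tab$orientation == orient, , drop = FALSE]
    pass <- which(!is.na(sub$contrast) & sub$contrast >= threshold)
    if (length(pass)) {
      k <- max(pass)  # finest passing element (list is coarse -> fine)
      out[[orient]] <- list(resolved = TRUE, group = sub$group[k],
                            element = sub$element[k],
                            widthMm = sub$widthMm[k],
                            contrast = sub$contrast[k], table = sub)
    } else {
      out[[orient]] <- list(resolved = FALSE, group = NA_integer_,
                            element = NA_integer_, widthMm = NA_real_,
                            contrast = NA_real_, table = sub)
    }
  }
  out
}
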