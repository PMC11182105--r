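# Retinal band detection, virtual flattening and depth-profile extraction.

#' Detect the retinal curve in a posterior-eye image
#'
#' Semi-automated boundary detection: the user (or the phantom generator)
#' supplies at least three seed points on the bright retinal/choroidal band;
#' a circle is fitted through the seeds to estimate the eye centre, intensity
#' ridges are located along radial rays, the inner (vitreal) boundary of the
#' band is found per ray as the innermost crossing of a fraction of the ridge
#' intensity, and a smoothing spline through those boundary points gives a
#' curve parameterised by arc length. When the seeds are (near-)collinear the
#' detection falls back to rays perpendicular to the fitted line and returns
#' the sub-pixel ridge itself. Deterministic given image and seeds.
#'
#' @param image Matrix; the band (e.g. the mean difference image or a BF map)
#'   must be bright relative to its surroundings.
#' @param seeds n x 2 matrix of (x, y) seed coordinates in mm, n >= 3, on the
#'   band.
#' @param pixelMm Pixel size of `image` (mm).
#' @param searchMm Half-width of the radial search window around the seed
#'   radius (mm).
#' @param innerFrac Fraction of the ridge intensity defining the inner
#'   boundary crossing.
#' @param alongSpacingMm Arc-length sampling of the returned curve (mm).
#' @return A [RetinaCurve-class].
#' @export
detectRetinaCurve <- function(image, seeds, pixelMm, searchMm = 0.35,
                              innerFrac = 0.2, alongSpacingMm = 0.007) {
  seeds <- as.matrix(seeds)
  if (nrow(seeds) < 3 || ncol(seeds) != 2) {
    stop("at least 3 seed points (n x 2 matrix, mm) are required")
  }
  imax <- max(image, na.rm = TRUE)
  seedVal <- vapply(seq_len(nrow(seeds)), function(i) {
    dx <- rep(c(-1, 0, 1) * pixelMm, 3)
    dy <- rep(c(-1, 0, 1) * pixelMm, each = 3)
    max(interpImage(image, seeds[i, 1] + dx, seeds[i, 2] + dy, pixelMm,
                    "linear"), na.rm = TRUE)
  }, numeric(1))
  low <- which(!is.finite(seedVal) | seedVal < 0.1 * imax)
  if (length(low)) {
    stop(sprintf(
      "seed(s) %s are not near a detectable band (local intensity below 10%% of image maximum)",
      paste(low, collapse = ", ")
    ))
  }

  fit <- fitCircle(seeds)
  if (is.null(fit) || fit$radius > 50) {
    return(straightBandCurve(image, seeds, pixelMm, searchMm, alongSpacingMm))
  }
  ctr <- fit$center
  ang <- atan2(seeds[, 2] - ctr[2], seeds[, 1] - ctr[1])
  ang0 <- atan2(mean(sin(ang)), mean(cos(ang)))
  rel <- (ang - ang0 + pi) %% (2 * pi) - pi
  r0 <- mean(sqrt((seeds[, 1] - ctr[1])^2 + (seeds[, 2] - ctr[2])^2))
  dtheta <- alongSpacingMm / r0
  thetaRel <- seq(min(rel), max(rel), by = dtheta)
  rstep <- pixelMm / 4
  rr <- seq(max(r0 - searchMm, rstep), r0 + searchMm, by = rstep)
  ridgeR <- ridgeV <- innerR <- rep(NA_real_, length(thetaRel))
  for (k in seq_along(thetaRel)) {
    th <- ang0 + thetaRel[k]
    px <- ctr[1] + rr * cos(th)
    py <- ctr[2] + rr * sin(th)
    v <- interpImage(image, px, py, pixelMm, "linear")
    if (all(is.na(v))) next
    i <- which.max(v)
    ridgeR[k] <- rr[i]
    ridgeV[k] <- v[i]
    thr <- innerFrac * v[i]
    # innermost sustained crossing of the threshold: the inner surface of the
    # retinal vascular layer, not the inner edge of the (brighter) choroid.
    # Two consecutive samples are required so isolated noise spikes in the
    # vitreous cannot pull the boundary inward.
    above <- !is.na(v) & v >= thr
    j <- NA_integer_
    for (q in seq_len(i - 1)) {
      if (above[q] && above[q + 1]) { j <- q; break }
    }
    if (is.na(j)) j <- i
    innerR[k] <- if (j > 1 && !is.na(v[j - 1]) && v[j] > v[j - 1]) {
      # sub-sample linear crossing between rr[j-1] and rr[j]
      rr[j - 1] + (thr - v[j - 1]) / (v[j] - v[j - 1]) * rstep
    } else {
      rr[j]
    }
  }
  ok <- is.finite(innerR) & is.finite(ridgeV) &
    ridgeV >= 0.3 * stats::median(ridgeV, na.rm = TRUE)
  if (sum(ok) < 5) stop("too few rays intersect a detectable band")
  sfit <- stats::smooth.spline(thetaRel[ok], innerR[ok],
                               df = min(10, max(4, sum(ok) / 20)))
  rHat <- stats::predict(sfit, thetaRel)$y
  pts <- cbind(ctr[1] + rHat * cos(ang0 + thetaRel),
               ctr[2] + rHat * sin(ang0 + thetaRel))
  curveFromPoints(pts, center = ctr)
}

# Least-squares (Kasa) circle fit; NULL when the system is near-singular
# (collinear seeds).
fitCircle <- function(p) {
  A <- cbind(2 * p[, 1], 2 * p[, 2], 1)
  b <- p[, 1]^2 + p[, 2]^2
  sol <- tryCatch(qr.solve(A, b, tol = 1e-10), error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  ctr <- sol[1:2]
  r2 <- sol[3] + sum(ctr^2)
  if (!is.finite(r2) || r2 <= 0) return(NULL)
  list(center = ctr, radius = sqrt(r2))
}

straightBandCurve <- function(image, seeds, pixelMm, searchMm,
                              alongSpacingMm) {
  c0 <- colMeans(seeds)
  sv <- svd(sweep(seeds, 2, c0))
  u <- sv$v[, 1]
  v <- c(-u[2], u[1])
  tmin <- min((seeds[, 1] - c0[1]) * u[1] + (seeds[, 2] - c0[2]) * u[2])
  tmax <- max((seeds[, 1] - c0[1]) * u[1] + (seeds[, 2] - c0[2]) * u[2])
  ts <- seq(tmin, tmax, by = alongSpacingMm)
  ostep <- pixelMm / 4
  nOff <- ceiling(searchMm / ostep)
  off <- (-nOff:nOff) * ostep  # symmetric about 0 so an on-axis band is exact
  ridge <- rep(NA_real_, length(ts))
  for (k in seq_along(ts)) {
    px <- c0[1] + ts[k] * u[1] + off * v[1]
    py <- c0[2] + ts[k] * u[2] + off * v[2]
    w <- interpImage(image, px, py, pixelMm, "linear")
    if (all(is.na(w))) next
    i <- which.max(w)
    # parabolic sub-sample refinement of the ridge position
    o <- off[i]
    if (i > 1 && i < length(off) && !anyNA(w[(i - 1):(i + 1)])) {
      den <- w[i - 1] - 2 * w[i] + w[i + 1]
      if (den < 0) o <- off[i] + 0.5 * ostep * (w[i - 1] - w[i + 1]) / den
    }
    ridge[k] <- o
  }
  ok <- is.finite(ridge)
  if (sum(ok) < 5) stop("too few rays intersect a detectable band")
  rid <- ridge
  if (any(!ok)) rid[!ok] <- stats::approx(ts[ok], ridge[ok], ts[!ok],
                                          rule = 2)$y
  pts <- cbind(c0[1] + ts * u[1] + rid * v[1],
               c0[2] + ts * u[2] + rid * v[2])
  curveFromPoints(pts, center = c(NA_real_, NA_real_))
}

#' Analytic circular retina curve
#'
#' Builds a [RetinaCurve-class] directly from circle geometry, bypassing
#' image-based detection. Useful for synthetic data with known geometry and
#' for isolating the flattening step from the detection step.
#'
#' @param centerMm Circle centre (x, y) in mm.
#' @param radiusMm Circle radius (mm); the curve is the circle itself, so
#'   place it on the inner retinal surface.
#' @param angleRangeDeg Angular range `c(from, to)` in degrees.
#' @param spacingMm Approximate arc-length spacing of the returned samples.
#' @return A [RetinaCurve-class] with outward normals.
#' @export
circularCurve <- function(centerMm, radiusMm, angleRangeDeg = c(0, 360),
                          spacingMm = 0.007) {
  dtheta <- spacingMm / radiusMm
  n <- max(2, ceiling(diff(angleRangeDeg) * pi / 180 / dtheta))
  th <- seq(angleRangeDeg[1], angleRangeDeg[2], length.out = n) * pi / 180
  pts <- cbind(centerMm[1] + radiusMm * cos(th),
               centerMm[2] + radiusMm * sin(th))
  curveFromPoints(pts, center = centerMm)
}

# Assemble a RetinaCurve from ordered points: arc length by cumulated
# segment lengths, outward normals from tangents (oriented away from the
# centre when one is known).
curveFromPoints <- function(pts, center) {
  n <- nrow(pts)
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  tx <- c(pts[2, 1] - pts[1, 1],
          pts[3:n, 1] - pts[1:(n - 2), 1],
          pts[n, 1] - pts[n - 1, 1])
  ty <- c(pts[2, 2] - pts[1, 2],
          pts[3:n, 2] - pts[1:(n - 2), 2],
          pts[n, 2] - pts[n - 1, 2])
  nv <- cbind(ty, -tx) / sqrt(tx^2 + ty^2)
  if (all(is.finite(center))) {
    outward <- cbind(pts[, 1] - center[1], pts[, 2] - center[2])
    flip <- rowSums(nv * outward) < 0
    nv[flip, ] <- -nv[flip, ]
  }
  new("RetinaCurve", points = pts, normals = nv, arclength = s,
      center = center)
}

#' Virtually flatten a map along the retinal curve
#'
#' Resamples the map along normals to the retinal curve: each row of the
#' result is a depth profile perpendicular to the retina at one arc-length
#' position. Depth is sampled at native pixel size divided by `interpFactor`
#' (0.007 mm at the 0.042 mm default pixel and 6x interpolation); the
#' along-retina spacing equals the depth spacing by default so the flattened
#' grid is isotropic. Quantitative units are preserved (interpolation weights
#' sum to one). Samples whose normal leaves the image domain are `NA` and
#' flagged in `excluded`, never silently zeroed.
#'
#' @param map A [QuantMap-class], or a plain matrix (then `mapPixelMm` is
#'   required).
#' @param curve A [RetinaCurve-class] from [detectRetinaCurve()].
#' @param interpFactor Depth oversampling factor relative to the native
#'   pixel (>= 1); 6 by default.
#' @param depthRangeMm Depth extent `c(min, max)` in mm around the curve
#'   (negative = vitreous side).
#' @param alongSpacingMm Along-retina spacing (mm); defaults to the depth
#'   spacing.
#' @param method `"cubic"` (Catmull-Rom) or `"linear"` interpolation.
#' @param mapPixelMm Pixel size when `map` is a plain matrix.
#' @return A [LinearizedMap-class].
#' @export
linearizeMap <- function(map, curve, interpFactor = 6,
                         depthRangeMm = c(-0.4, 0.5), alongSpacingMm = NULL,
                         method = c("cubic", "linear"), mapPixelMm = NULL) {
  method <- match.arg(method)
  stopifnot(is(curve, "RetinaCurve"), interpFactor >= 1)
  if (is(map, "QuantMap")) {
    img <- map@bf
    img[!map@mask] <- NA_real_
    px <- map@pixelMm
  } else {
    img <- as.matrix(map)
    if (is.null(mapPixelMm)) stop("mapPixelMm is required for a plain matrix")
    px <- mapPixelMm
  }
  depthSpacing <- px / interpFactor
  if (is.null(alongSpacingMm)) alongSpacingMm <- depthSpacing
  sMax <- max(curve@arclength)
  sGrid <- seq(0, sMax, by = alongSpacingMm)
  cx <- stats::approx(curve@arclength, curve@points[, 1], sGrid)$y
  cy <- stats::approx(curve@arclength, curve@points[, 2], sGrid)$y
  nx <- stats::approx(curve@arclength, curve@normals[, 1], sGrid)$y
  ny <- stats::approx(curve@arclength, curve@normals[, 2], sGrid)$y
  nn <- sqrt(nx^2 + ny^2)
  nx <- nx / nn
  ny <- ny / nn
  dGrid <- seq(depthRangeMm[1], depthRangeMm[2], by = depthSpacing)
  X <- outer(cx, dGrid, function(c0, d) c0) + outer(nx, dGrid)
  Y <- outer(cy, dGrid, function(c0, d) c0) + outer(ny, dGrid)
  v <- interpImage(img, as.vector(X), as.vector(Y), px, method)
  vals <- matrix(v, nrow = length(sGrid), ncol = length(dGrid))
  new("LinearizedMap",
    values = vals, excluded = is.na(vals), positions = sGrid,
    depths = dGrid, alongSpacing = alongSpacingMm,
    depthSpacing = depthSpacing
  )
}

#' Extract depth profiles from a flattened map
#'
#' Returns one [DepthProfile-class] per along-retina position, with signed
#' positions relative to the optic nerve head (negative on one side,
#' positive on the other), plus the length-averaged profile.
#'
#' @param lin A [LinearizedMap-class].
#' @param onhPositionMm Arc-length coordinate of the optic nerve head in
#'   `positions(lin)` (see [locateONH()]).
#' @return List with elements `profiles` (list of [DepthProfile-class]) and
#'   `averaged` (the length-averaged [DepthProfile-class], `position = NA`).
#' @export
extractProfiles <- function(lin, onhPositionMm) {
  stopifnot(is(lin, "LinearizedMap"))
  if (onhPositionMm < min(lin@positions) || onhPositionMm > max(lin@positions)) {
    stop("onhPositionMm lies outside the sampled arc")
  }
  prof <- lapply(seq_along(lin@positions), function(i) {
    new("DepthProfile", values = lin@values[i, ], depths = lin@depths,
        position = lin@positions[i] - onhPositionMm)
  })
  avg <- new("DepthProfile", values = colMeans(lin@values, na.rm = TRUE),
             depths = lin@depths, position = NA_real_)
  list(profiles = prof, averaged = avg)
}

#' Locate the optic nerve head along a flattened map
#'
#' The optic nerve head interrupts the vascular band, so it appears as the
#' along-retina minimum of the depth-summed signal. The profile of row sums
#' is smoothed with a running mean before taking the minimum; positions
#' within `edgeMarginMm` of either end of the arc are not considered.
#'
#' @param lin A [LinearizedMap-class] of a BF or difference map.
#' @param smoothMm Running-mean window (mm).
#' @param edgeMarginMm Excluded margin at the arc ends (mm).
#' @return Arc-length coordinate (mm) of the optic nerve head.
#' @export
locateONH <- function(lin, smoothMm = 0.15, edgeMarginMm = 0.3) {
  stopifnot(is(lin, "LinearizedMap"))
  score <- rowSums(lin@values, na.rm = TRUE)
  w <- max(1L, round(smoothMm / lin@alongSpacing))
  sm <- stats::filter(score, rep(1 / w, w), sides = 2)
  sm[is.na(sm)] <- Inf
  margin <- lin@positions < min(lin@positions) + edgeMarginMm |
    lin@positions > max(lin@positions) - edgeMarginMm
  sm[margin] <- Inf
  lin@positions[which.min(sm)]
}
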