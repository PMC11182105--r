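# Synthetic 2-D eye phantom: concentric-band ground truth rendered at high
# resolution, then pushed through the inverse of the quantification equation
# and degraded by 2-D k-space truncation to acquisition resolution.

#' Specification of the default mouse-eye phantom
#'
#' A 1.5 mm-radius eye centred in a 6 x 6 mm field of view: vitreous disc to
#' 1.2 mm, retinal vascular layer 1.20-1.26 mm at 1.6 mL/mL/min, avascular
#' outer retina 1.26-1.33 mm, choroid 1.33-1.37 mm at 8 mL/mL/min, sclera to
#' 1.5 mm. The band thicknesses mirror the laminar depths of the 1-D
#' resolution simulation. M0 is 1.0 in the vitreous, 0.8 in retina through
#' choroid, 0.5 in the sclera and 0 outside the eye. An optic-nerve-head gap
#' interrupts blood flow over a small angular sector.
#'
#' @param eyeRadiusMm,centerMm,fovMm,gridUm Geometry of the phantom and of
#'   the rendering grid (5 um by default).
#' @param bands Concentric bands (see [EyePhantomSpec-class]).
#' @param vitreousM0,backgroundM0 M0 inside the vitreous / outside the eye.
#' @param onhAngleDeg,onhWidthDeg Position and width of the optic-nerve-head
#'   gap (degrees); 10 degrees wide by default.
#' @return An [EyePhantomSpec-class].
#' @export
eyePhantomSpec <- function(eyeRadiusMm = 1.5, centerMm = c(3, 3),
                           bands = data.frame(
                             name = c("retinal vascular", "outer retina",
                                      "choroid", "sclera"),
                             rInnerMm = c(1.20, 1.26, 1.33, 1.37),
                             rOuterMm = c(1.26, 1.33, 1.37, 1.50),
                             bf = c(1.6, 0, 8, 0),
                             m0 = c(0.8, 0.8, 0.8, 0.5)
                           ),
                           vitreousM0 = 1, backgroundM0 = 0,
                           onhAngleDeg = 270, onhWidthDeg = 10,
                           fovMm = 6, gridUm = 5) {
  new("EyePhantomSpec",
    eyeRadiusMm = eyeRadiusMm, centerMm = centerMm, bands = bands,
    vitreousM0 = vitreousM0, backgroundM0 = backgroundM0,
    onhAngleDeg = onhAngleDeg, onhWidthDeg = onhWidthDeg, fovMm = fovMm,
    gridUm = gridUm
  )
}

#' Render the phantom ground-truth maps
#'
#' @param spec An [EyePhantomSpec-class].
#' @return List with `bf` and `m0` matrices at `gridUm` resolution,
#'   `pixelMm`, and the generating `spec`.
#' @export
makePhantom <- function(spec = eyePhantomSpec()) {
  stopifnot(is(spec, "EyePhantomSpec"))
  px <- spec@gridUm / 1000
  n <- round(spec@fovMm / px)
  cc <- seq(px / 2, spec@fovMm - px / 2, length.out = n)
  X <- matrix(cc, n, n)
  Y <- matrix(cc, n, n, byrow = TRUE)
  dx <- X - spec@centerMm[1]
  dy <- Y - spec@centerMm[2]
  r <- sqrt(dx^2 + dy^2)
  b <- spec@bands
  # area-accurate rendering: band edges are anti-aliased over one rendering
  # pixel (linear coverage ramp), so the rendered bands carry the analytic
  # band mass and do not imprint a radial staircase on the flattened maps.
  soft <- function(x) pmin(pmax(x / px + 0.5, 0), 1)
  bf <- matrix(0, n, n)
  rIn1 <- if (nrow(b)) b$rInnerMm[1] else spec@eyeRadiusMm
  m0 <- soft(rIn1 - r) * spec@vitreousM0
  for (i in seq_len(nrow(b))) {
    w <- soft(r - b$rInnerMm[i]) * soft(b$rOuterMm[i] - r)
    bf <- bf + w * b$bf[i]
    m0 <- m0 + w * b$m0[i]
  }
  rOut <- if (nrow(b)) max(b$rOuterMm) else spec@eyeRadiusMm
  m0 <- m0 + soft(r - rOut) * spec@backgroundM0
  if (spec@onhWidthDeg > 0 && nrow(b)) {
    theta <- atan2(dy, dx) * 180 / pi
    dAng <- abs((theta - spec@onhAngleDeg + 180) %% 360 - 180)
    gap <- dAng <= spec@onhWidthDeg / 2 & r >= min(b$rInnerMm)
    bf[gap] <- 0
  }
  list(bf = bf, m0 = m0, pixelMm = px, spec = spec)
}

#' Seed points on the phantom's vascular band
#'
#' Convenience for driving the semi-automated curve detection on phantom
#' data: exact points at the centre of the choroidal band at the requested
#' angles.
#'
#' @param spec An [EyePhantomSpec-class].
#' @param anglesDeg Angles (degrees) of the seed points.
#' @return n x 2 matrix of (x, y) coordinates in mm.
#' @export
phantomSeeds <- function(spec, anglesDeg) {
  b <- spec@bands
  i <- which(b$bf == max(b$bf))[1]
  r <- (b$rInnerMm[i] + b$rOuterMm[i]) / 2
  th <- anglesDeg * pi / 180
  cbind(spec@centerMm[1] + r * cos(th), spec@centerMm[2] + r * sin(th))
}

#' Synthesise an ASL acquisition from phantom truth
#'
#' Inverts the quantification equation to produce the noiseless
#' control-label difference (`deltaM = BF x K x M0vit / 60`, with `K` the
#' equation's denominator factor and `M0vit` the vitreous M0 the analysis
#' normalises by), forms control (= tissue M0 field) and label (= control -
#' deltaM) images, degrades control, label and M0 to the acquisition matrix
#' by 2-D k-space truncation (hard cutoff, same convention as
#' [fourierDownsample()]), and adds independent Gaussian noise to every
#' repetition.
#'
#' @param truth Output of [makePhantom()].
#' @param params An [AcquisitionParams-class]; the pixel size of the series
#'   is set to `fovMm / matrixSize`.
#' @param nReps Number of control/label repetitions.
#' @param noiseSd Per-repetition Gaussian noise SD relative to the vitreous
#'   M0. The default 0.06 leaves the 75-repetition averaged difference image
#'   with noise SD of about 1% of the vitreous M0, matching averaged in vivo
#'   map quality. The M0 image receives `noiseSd/sqrt(2)` (it is acquired as
#'   2 repetitions).
#' @param seed Integer seed; the same seed reproduces the acquisition
#'   bit-for-bit. The caller's RNG state is left untouched.
#' @param degrade If `FALSE`, the series stays on the truth grid (no k-space
#'   truncation) -- useful for algebraic round-trip checks.
#' @param matrixSize Acquisition matrix (144 gives 6/144 mm = 41.7 um
#'   pixels).
#' @return A [PhantomAcquisition-class].
#' @export
synthesizeAcquisition <- function(truth, params, nReps = 75, noiseSd = 0.06,
                                  seed = NULL, degrade = TRUE,
                                  matrixSize = 144) {
  stopifnot(is(params, "AcquisitionParams"))
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  spec <- truth$spec
  K <- quantDenominator(params)
  m0vit <- spec@vitreousM0
  dmHi <- truth$bf * K * m0vit / 60
  ctlHi <- truth$m0
  lblHi <- ctlHi - dmHi
  if (degrade) {
    L <- spec@fovMm
    nHi <- nrow(ctlHi)
    xin <- seq(L / (2 * nHi), L - L / (2 * nHi), length.out = nHi)
    xout <- seq(L / (2 * matrixSize), L - L / (2 * matrixSize),
                length.out = matrixSize)
    P <- dirichletOperator(xin, xout, L, mMax = matrixSize / 2)
    ctl <- P %*% ctlHi %*% t(P)
    lbl <- P %*% lblHi %*% t(P)
    m0 <- P %*% truth$m0 %*% t(P)
    px <- L / matrixSize
  } else {
    ctl <- ctlHi
    lbl <- lblHi
    m0 <- truth$m0
    px <- truth$pixelMm
  }
  params <- initialize(params, pixelMm = px)
  d <- dim(ctl)
  series <- withSeed(seed, {
    noisify <- function(img, sd) {
      arr <- array(rep(img, nReps), c(d, nReps))
      if (sd > 0) arr <- arr + array(stats::rnorm(length(arr), 0, sd),
                                     c(d, nReps))
      arr
    }
    ctlArr <- noisify(ctl, noiseSd * m0vit)
    lblArr <- noisify(lbl, noiseSd * m0vit)
    m0Img <- m0
    if (noiseSd > 0) {
      m0Img <- m0 + matrix(stats::rnorm(length(m0), 0,
                                        noiseSd * m0vit / sqrt(2)), d[1], d[2])
    }
    aslSeries(ctlArr, lblArr, m0Img, params)
  })
  new("PhantomAcquisition", series = series, truthBf = truth$bf,
      truthM0 = truth$m0, truthPixelMm = truth$pixelMm, spec = spec)
}

#' Run the full quantification pipeline on an ASL series
#'
#' Difference map, retinal-curve detection, virtual flattening of the
#' difference and M0 images, per-profile vitreous M0, blood-flow profiles,
#' layer segmentation and the peak / integrated metrics averaged along the
#' retina.
#'
#' @param series An [ASLSeries-class].
#' @param seeds Seed points on the vascular band (n x 2, mm); see
#'   [detectRetinaCurve()].
#' @param vitreousDepthMm Depth interval for the per-profile M0, see
#'   [m0FromVitreous()].
#' @param depthRangeMm,interpFactor,method Flattening options, see
#'   [linearizeMap()].
#' @param onhPositionMm Optic-nerve-head arc position; located automatically
#'   with [locateONH()] when `NULL`.
#' @param spanMm,onhExclusionMm Along-retina averaging, see
#'   [averageAlongRetina()].
#' @return List with `deltaM`, `curve`, `linBF` (flattened BF map),
#'   `m0PerProfile`, `onhPositionMm`, `measurement`
#'   ([LayerMeasurement-class]) and `map` (whole-image [QuantMap-class]
#'   normalised by the median vitreous M0, masked to M0 > 10% vitreous M0).
#' @export
runBFPipeline <- function(series, seeds, vitreousDepthMm = c(-0.3, -0.1),
                          depthRangeMm = c(-0.4, 0.5), interpFactor = 6,
                          method = "cubic", onhPositionMm = NULL,
                          spanMm = 1, onhExclusionMm = 0.2) {
  stopifnot(is(series, "ASLSeries"))
  params <- series@params
  px <- params@pixelMm
  dm <- computeDeltaM(series)
  curve <- detectRetinaCurve(dm, seeds, px)
  linDM <- linearizeMap(dm, curve, interpFactor = interpFactor,
                        depthRangeMm = depthRangeMm, method = method,
                        mapPixelMm = px)
  linM0 <- linearizeMap(series@m0, curve, interpFactor = interpFactor,
                        depthRangeMm = depthRangeMm, method = method,
                        mapPixelMm = px)
  m0v <- m0FromVitreous(linM0, vitreousDepthMm)
  K <- quantDenominator(params)
  bfVals <- 60 * linDM@values / (K * m0v)
  linBF <- initialize(linDM, values = bfVals, excluded = is.na(bfVals))
  if (is.null(onhPositionMm)) onhPositionMm <- locateONH(linBF)
  meas <- measureLayers(linBF, onhPositionMm, spanMm = spanMm,
                        onhExclusionMm = onhExclusionMm)
  vitM0 <- stats::median(m0v)
  qmap <- quantifyBF(dm, vitM0, params, mask = series@m0 > 0.1 * vitM0)
  list(deltaM = dm, curve = curve, linBF = linBF, m0PerProfile = m0v,
       onhPositionMm = onhPositionMm, measurement = meas, map = qmap)
}
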