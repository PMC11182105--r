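#' @import methods
NULL

#' Acquisition parameters for one ASL eye scan
#'
#' Holds the constants of the single-compartment ASL blood-flow equation and
#' the in-plane geometry of one scan. Defaults are the values used for mouse
#' eye imaging at 7 T: labeling efficiency 0.75, arterial blood T1 of 1.8 s,
#' arterial blood T2* of 35 ms, blood-water partition factor 0.85, echo time
#' 9 ms, and post-labeling delays of 325 ms (left eye) and 381 ms (right eye).
#'
#' @slot te Echo time in seconds.
#' @slot pld Post-labeling delay in seconds (eye-dependent).
#' @slot labelDuration Labeling pulse duration in seconds.
#' @slot alpha Labeling efficiency (dimensionless, in (0, 1]).
#' @slot t1Blood Longitudinal relaxation time of arterial blood in seconds.
#' @slot t2starBlood Effective transverse relaxation time of arterial blood
#'   in seconds.
#' @slot lambdaA Water volume per volume of arterial blood (mL/g, used as a
#'   dimensionless partition factor).
#' @slot pixelMm In-plane pixel size in millimetres.
#' @slot eye `"left"` or `"right"`.
#' @seealso [acquisitionParams()], [quantifyBF()]
#' @export
setClass("AcquisitionParams",
  representation(
    te = "numeric", pld = "numeric", labelDuration = "numeric",
    alpha = "numeric", t1Blood = "numeric", t2starBlood = "numeric",
    lambdaA = "numeric", pixelMm = "numeric", eye = "character"
  )
)

setValidity("AcquisitionParams", function(object) {
  msg <- character()
  tms <- c(
    te = object@te, pld = object@pld, labelDuration = object@labelDuration,
    t1Blood = object@t1Blood, t2starBlood = object@t2starBlood,
    lambdaA = object@lambdaA, pixelMm = object@pixelMm
  )
  bad <- names(tms)[!is.finite(tms) | tms <= 0]
  if (length(bad)) {
    msg <- c(msg, paste0(
      "time/geometry constants must be strictly positive: ",
      paste(bad, collapse = ", ")
    ))
  }
  if (!is.finite(object@alpha) || object@alpha <= 0 || object@alpha > 1) {
    msg <- c(msg, "alpha (labeling efficiency) must lie in (0, 1]")
  }
  if (!object@eye %in% c("left", "right")) {
    msg <- c(msg, "eye must be \"left\" or \"right\"")
  }
  if (length(msg)) msg else TRUE
})

#' Construct acquisition parameters
#'
#' @param eye `"left"` or `"right"`; selects the default post-labeling delay
#'   (0.325 s left, 0.381 s right) when `pld` is not given.
#' @param te Echo time (s).
#' @param pld Post-labeling delay (s); default depends on `eye`.
#' @param labelDuration Labeling pulse duration (s).
#' @param alpha Labeling efficiency.
#' @param t1Blood Arterial blood T1 (s).
#' @param t2starBlood Arterial blood T2* (s).
#' @param lambdaA Blood-water partition factor.
#' @param pixelMm In-plane pixel size (mm).
#' @return An [AcquisitionParams-class] object.
#' @examples
#' acquisitionParams("left")
#' acquisitionParams("right")@pld
#' @export
acquisitionParams <- function(eye = c("left", "right"), te = 0.009,
                              pld = NULL, labelDuration = 2.542,
                              alpha = 0.75, t1Blood = 1.8,
                              t2starBlood = 0.035, lambdaA = 0.85,
                              pixelMm = 0.042) {
  eye <- match.arg(eye)
  if (is.null(pld)) pld <- if (eye == "left") 0.325 else 0.381
  new("AcquisitionParams",
    te = te, pld = pld, labelDuration = labelDuration, alpha = alpha,
    t1Blood = t1Blood, t2starBlood = t2starBlood, lambdaA = lambdaA,
    pixelMm = pixelMm, eye = eye
  )
}

#' ASL image series (control/label repetitions plus M0)
#'
#' @slot control 3-D array (x, y, repetition) of non-labeled images.
#' @slot label 3-D array of labeled images; same shape as `control`.
#' @slot m0 2-D equilibrium-magnetization image; same in-plane shape.
#' @slot params The [AcquisitionParams-class] of the scan.
#' @export
setClass("ASLSeries",
  representation(
    control = "array", label = "array", m0 = "matrix",
    params = "AcquisitionParams"
  )
)

setValidity("ASLSeries", function(object) {
  msg <- character()
  dc <- dim(object@control)
  dl <- dim(object@label)
  if (length(dc) != 3 || length(dl) != 3) {
    msg <- c(msg, "control and label must be 3-D arrays (x, y, repetition)")
  } else {
    if (!identical(dc, dl)) {
      msg <- c(msg, sprintf(
        "control %s and label %s stacks differ in shape",
        paste(dc, collapse = "x"), paste(dl, collapse = "x")
      ))
    }
    if (dc[3] < 1) msg <- c(msg, "at least one repetition is required")
    if (!identical(dim(object@m0), dc[1:2])) {
      msg <- c(msg, sprintf(
        "m0 image %s does not match in-plane shape %s",
        paste(dim(object@m0), collapse = "x"), paste(dc[1:2], collapse = "x")
      ))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct an ASL series
#'
#' @param control,label 3-D arrays (x, y, repetition) or matrices (single
#'   repetition) of non-labeled / labeled images.
#' @param m0 Equilibrium-magnetization image (matrix).
#' @param params [AcquisitionParams-class].
#' @return An [ASLSeries-class] object.
#' @export
aslSeries <- function(control, label, m0, params) {
  if (is.matrix(control)) control <- array(control, c(dim(control), 1L))
  if (is.matrix(label)) label <- array(label, c(dim(label), 1L))
  new("ASLSeries", control = control, label = label, m0 = as.matrix(m0),
      params = params)
}

#' Quantitative blood-flow map
#'
#' 2-D blood-flow image in mL/mL/min with its pixel size, eye label and a
#' valid-region mask. Negative values are retained (zero-mean noise must not
#' be clipped, or depth integrals would be biased upward).
#'
#' @slot bf Matrix of blood-flow values (mL/mL/min).
#' @slot pixelMm In-plane pixel size (mm).
#' @slot eye `"left"` or `"right"`.
#' @slot mask Logical matrix, `TRUE` where quantification is valid.
#' @export
setClass("QuantMap",
  representation(bf = "matrix", pixelMm = "numeric", eye = "character",
                 mask = "matrix")
)

setValidity("QuantMap", function(object) {
  msg <- character()
  if (!identical(dim(object@bf), dim(object@mask))) {
    msg <- c(msg, "bf and mask must have identical shape")
  } else if (any(!is.finite(object@bf[object@mask]))) {
    msg <- c(msg, "bf must be finite inside the mask")
  }
  if (object@pixelMm <= 0) msg <- c(msg, "pixelMm must be > 0")
  if (length(msg)) msg else TRUE
})

#' Fitted retinal curve
#'
#' Smooth curve along the inner retinal surface, parameterised by arc length,
#' with outward (vitreous-to-sclera) unit normals at each sample.
#'
#' @slot points n x 2 matrix of (x, y) curve samples in mm.
#' @slot normals n x 2 matrix of outward unit normals.
#' @slot arclength Cumulative arc length (mm), strictly increasing, 0 at the
#'   first sample.
#' @slot center Estimated eye-centre (mm); `NA` for a straight band.
#' @export
setClass("RetinaCurve",
  representation(points = "matrix", normals = "matrix",
                 arclength = "numeric", center = "numeric")
)

setValidity("RetinaCurve", function(object) {
  msg <- character()
  n <- nrow(object@points)
  if (ncol(object@points) != 2) msg <- c(msg, "points must be n x 2")
  if (!identical(dim(object@normals), dim(object@points))) {
    msg <- c(msg, "normals must match points in shape")
  }
  if (length(object@arclength) != n || any(diff(object@arclength) <= 0)) {
    msg <- c(msg, "arclength must be strictly increasing with one value per point")
  }
  if (length(msg)) msg else TRUE
})

#' Virtually flattened (linearized) retina
#'
#' A 2-D resampling of a map along normals to the retinal curve. Rows index
#' position along the retina, columns index depth; depth increases from the
#' vitreous toward the sclera and is 0 on the fitted curve.
#'
#' @slot values Matrix (position x depth).
#' @slot excluded Logical matrix flagging samples whose normal left the image
#'   domain (those values are `NA`, never silently zeroed).
#' @slot positions Arc-length coordinate of each row (mm).
#' @slot depths Depth coordinate of each column (mm); 0 at the fitted curve.
#' @slot alongSpacing Row spacing (mm).
#' @slot depthSpacing Column spacing (mm) = native pixel / interpolation
#'   factor (0.007 mm at defaults).
#' @export
setClass("LinearizedMap",
  representation(values = "matrix", excluded = "matrix",
                 positions = "numeric", depths = "numeric",
                 alongSpacing = "numeric", depthSpacing = "numeric")
)

setValidity("LinearizedMap", function(object) {
  msg <- character()
  if (nrow(object@values) != length(object@positions) ||
      ncol(object@values) != length(object@depths)) {
    msg <- c(msg, "values shape must match positions x depths")
  }
  if (!identical(dim(object@excluded), dim(object@values))) {
    msg <- c(msg, "excluded must match values in shape")
  }
  if (object@depthSpacing <= 0 || object@alongSpacing <= 0) {
    msg <- c(msg, "spacings must be > 0")
  }
  if (length(msg)) msg else TRUE
})

#' Single depth profile across the retina
#'
#' @slot values Blood flow across depth (mL/mL/min).
#' @slot depths Depth coordinates (mm), evenly spaced, increasing from
#'   vitreous to sclera.
#' @slot position Signed position along the retina relative to the optic
#'   nerve head (mm); `NA` for a length-averaged profile.
#' @export
setClass("DepthProfile",
  representation(values = "numeric", depths = "numeric", position = "numeric")
)

setValidity("DepthProfile", function(object) {
  msg <- character()
  if (length(object@values) != length(object@depths)) {
    msg <- c(msg, "values and depths must have equal length")
  }
  if (length(object@depths) > 1) {
    sp <- diff(object@depths)
    if (any(sp <= 0) || diff(range(sp)) > 1e-8 * mean(sp)) {
      msg <- c(msg, "depths must be evenly spaced and increasing")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Depth windows of the retinal and choroidal vascular layers
#'
#' When the two layers are separable (`resolved = TRUE`), carries one depth
#' interval per layer, ordered retina-then-choroid along increasing depth and
#' split at the inter-peak minimum. When not separable, carries a single
#' combined window instead.
#'
#' @slot retina `[start, end]` depth interval (mm), or `NA` when unresolved.
#' @slot choroid `[start, end]` depth interval (mm), or `NA` when unresolved.
#' @slot combined `[start, end]` of the combined vascular window.
#' @slot resolved Logical flag.
#' @export
setClass("LayerWindows",
  representation(retina = "numeric", choroid = "numeric",
                 combined = "numeric", resolved = "logical")
)

setValidity("LayerWindows", function(object) {
  msg <- character()
  if (object@resolved) {
    if (any(is.na(object@retina)) || any(is.na(object@choroid))) {
      msg <- c(msg, "resolved windows must carry retina and choroid intervals")
    } else if (object@retina[2] > object@choroid[1] + 1e-12) {
      msg <- c(msg, "retina and choroid windows must be ordered and non-overlapping")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Per-layer blood-flow measurement along the retina
#'
#' @slot perPosition `data.frame` with one row per along-retina position:
#'   `position` (signed mm from the optic nerve head), `peakRetina`,
#'   `peakChoroid` (mL/mL/min), `intRetina`, `intChoroid` (uL/mm^2/min);
#'   when the layers are unresolved the columns carry the combined peak and
#'   combined integral in `peakChoroid`/`intChoroid` and `NA` elsewhere.
#' @slot averaged Named numeric of retina-length averages of the four metrics.
#' @slot windows The [LayerWindows-class] used.
#' @slot resolved Logical, from the segmentation.
#' @export
setClass("LayerMeasurement",
  representation(perPosition = "data.frame", averaged = "numeric",
                 windows = "LayerWindows", resolved = "logical")
)

#' Laminar specification for the 1-D resolution simulation
#'
#' Ordered, non-overlapping layers of a piecewise-constant blood-flow profile
#' across retinal depth, sampled at `baseResUm` (0.1 um by default).
#'
#' @slot layers `data.frame` with columns `name`, `startUm`, `endUm`, `bf`
#'   (mL/mL/min).
#' @slot domainUm Total simulated depth (um).
#' @slot baseResUm Base sampling interval (um).
#' @export
setClass("SimLayerSpec",
  representation(layers = "data.frame", domainUm = "numeric",
                 baseResUm = "numeric")
)

setValidity("SimLayerSpec", function(object) {
  msg <- character()
  ly <- object@layers
  need <- c("name", "startUm", "endUm", "bf")
  if (!all(need %in% names(ly))) {
    msg <- c(msg, paste("layers must have columns", paste(need, collapse = ", ")))
  } else if (nrow(ly)) {
    if (any(ly$bf < 0)) msg <- c(msg, "bf values must be >= 0")
    if (any(ly$endUm <= ly$startUm)) msg <- c(msg, "each layer needs endUm > startUm")
    if (any(ly$startUm < 0) || any(ly$endUm > object@domainUm)) {
      msg <- c(msg, "layers must lie within the domain")
    }
    o <- order(ly$startUm)
    if (any(ly$startUm[o][-1] < ly$endUm[o][-nrow(ly)])) {
      msg <- c(msg, "layers must not overlap")
    }
  }
  if (object@baseResUm <= 0 || object@domainUm <= 0) {
    msg <- c(msg, "domainUm and baseResUm must be > 0")
  }
  if (length(msg)) msg else TRUE
})

#' Simulated 1-D laminar blood-flow profile
#'
#' @slot values Profile values (mL/mL/min), sampled at cell centres.
#' @slot spacingUm Sample spacing (um).
#' @slot domainUm Domain length (um).
#' @slot provenance `"base"` or `"downsampled-to-<R>"`.
#' @export
setClass("SimProfile",
  representation(values = "numeric", spacingUm = "numeric",
                 domainUm = "numeric", provenance = "character")
)

setValidity("SimProfile", function(object) {
  n <- length(object@values)
  if (abs(n * object@spacingUm - object@domainUm) > object@spacingUm) {
    return("length x spacing must equal the domain length (within one sample)")
  }
  TRUE
})

#' Specification of a 2-D synthetic eye phantom
#'
#' A coronal slice through a mouse eye: a disc of vitreous surrounded by
#' concentric bands (retinal vascular layer, avascular outer retina, choroid,
#' sclera), interrupted by an optic-nerve-head gap over a small angular
#' sector.
#'
#' @slot eyeRadiusMm Outer (scleral) radius in mm.
#' @slot centerMm Eye centre (x, y) in mm within the field of view.
#' @slot bands `data.frame` with columns `name`, `rInnerMm`, `rOuterMm`,
#'   `bf` (mL/mL/min), `m0` (relative to vitreous M0 = 1).
#' @slot vitreousM0,backgroundM0 M0 of the vitreous disc and of the region
#'   outside the eye.
#' @slot onhAngleDeg Angular position of the optic nerve head gap (degrees).
#' @slot onhWidthDeg Angular width of the gap (degrees).
#' @slot fovMm Field of view (mm, square).
#' @slot gridUm Rendering resolution of the truth maps (um).
#' @export
setClass("EyePhantomSpec",
  representation(eyeRadiusMm = "numeric", centerMm = "numeric",
                 bands = "data.frame", vitreousM0 = "numeric",
                 backgroundM0 = "numeric", onhAngleDeg = "numeric",
                 onhWidthDeg = "numeric", fovMm = "numeric", gridUm = "numeric")
)

setValidity("EyePhantomSpec", function(object) {
  msg <- character()
  b <- object@bands
  need <- c("name", "rInnerMm", "rOuterMm", "bf", "m0")
  if (!all(need %in% names(b))) {
    msg <- c(msg, paste("bands must have columns", paste(need, collapse = ", ")))
  } else if (nrow(b)) {
    if (any(diff(c(t(b[, c("rInnerMm", "rOuterMm")]))) < -1e-12)) {
      msg <- c(msg, "band radii must be ordered and non-overlapping")
    }
    if (any(b$rOuterMm > object@eyeRadiusMm + 1e-12)) {
      msg <- c(msg, "bands must not exceed the eye radius")
    }
  }
  if (length(object@centerMm) != 2) msg <- c(msg, "centerMm must be length 2")
  if (length(msg)) msg else TRUE
})

#' Synthetic phantom acquisition with its ground truth
#'
#' @slot series The simulated [ASLSeries-class] at acquisition resolution.
#' @slot truthBf High-resolution ground-truth blood-flow field (mL/mL/min).
#' @slot truthM0 High-resolution ground-truth M0 field.
#' @slot truthPixelMm Pixel size of the truth grids (mm).
#' @slot spec The generating [EyePhantomSpec-class].
#' @export
setClass("PhantomAcquisition",
  representation(series = "ASLSeries", truthBf = "matrix", truthM0 = "matrix",
                 truthPixelMm = "numeric", spec = "EyePhantomSpec")
)
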