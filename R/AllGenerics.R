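#' Extract the numeric values of a map or profile
#'
#' @param x A [QuantMap-class], [LinearizedMap-class], [DepthProfile-class]
#'   or [SimProfile-class].
#' @return For 2-D containers a matrix, for profiles a numeric vector.
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' @rdname mapValues
#' @export
setMethod("mapValues", "QuantMap", function(x) x@bf)
#' @rdname mapValues
#' @export
setMethod("mapValues", "LinearizedMap", function(x) x@values)
#' @rdname mapValues
#' @export
setMethod("mapValues", "DepthProfile", function(x) x@values)
#' @rdname mapValues
#' @export
setMethod("mapValues", "SimProfile", function(x) x@values)

#' Pixel size accessor
#' @param x A [QuantMap-class] or [AcquisitionParams-class].
#' @return Pixel size in mm.
#' @export
setGeneric("pixelMm", function(x) standardGeneric("pixelMm"))
#' @rdname pixelMm
#' @export
setMethod("pixelMm", "QuantMap", function(x) x@pixelMm)
#' @rdname pixelMm
#' @export
setMethod("pixelMm", "AcquisitionParams", function(x) x@pixelMm)

#' Depth coordinates of a flattened map or profile
#' @param x A [LinearizedMap-class] or [DepthProfile-class].
#' @return Numeric vector of depths (mm, 0 at the fitted retinal curve).
#' @export
setGeneric("depths", function(x) standardGeneric("depths"))
#' @rdname depths
#' @export
setMethod("depths", "LinearizedMap", function(x) x@depths)
#' @rdname depths
#' @export
setMethod("depths", "DepthProfile", function(x) x@depths)

#' Along-retina position coordinates
#' @param x A [LinearizedMap-class].
#' @return Numeric vector of arc-length positions (mm).
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))
#' @rdname positions
#' @export
setMethod("positions", "LinearizedMap", function(x) x@positions)

#' Per-position measurement table
#' @param x A [LayerMeasurement-class].
#' @return The per-position `data.frame`.
#' @export
setGeneric("perPosition", function(x) standardGeneric("perPosition"))
#' @rdname perPosition
#' @export
setMethod("perPosition", "LayerMeasurement", function(x) x@perPosition)

#' Retina-length-averaged metrics
#' @param x A [LayerMeasurement-class].
#' @return Named numeric: `peakRetina`, `peakChoroid` (mL/mL/min),
#'   `intRetina`, `intChoroid` (uL/mm^2/min); combined metrics when the
#'   layers were unresolved.
#' @export
setGeneric("averagedBF", function(x) standardGeneric("averagedBF"))
#' @rdname averagedBF
#' @export
setMethod("averagedBF", "LayerMeasurement", function(x) x@averaged)

#' Were the two vascular layers separable?
#' @param x A [LayerWindows-class] or [LayerMeasurement-class].
#' @return Logical.
#' @export
setGeneric("isResolved", function(x) standardGeneric("isResolved"))
#' @rdname isResolved
#' @export
setMethod("isResolved", "LayerWindows", function(x) x@resolved)
#' @rdname isResolved
#' @export
setMethod("isResolved", "LayerMeasurement", function(x) x@resolved)

setMethod("show", "AcquisitionParams", function(object) {
  cat(sprintf(
    "AcquisitionParams (%s eye): TE=%.3fs PLD=%.3fs alpha=%.2f T1b=%.2fs T2b*=%.3fs lambda=%.2f pixel=%.3fmm\n",
    object@eye, object@te, object@pld, object@alpha, object@t1Blood,
    object@t2starBlood, object@lambdaA, object@pixelMm
  ))
})

setMethod("show", "ASLSeries", function(object) {
  d <- dim(object@control)
  cat(sprintf("ASLSeries: %dx%d in-plane, %d repetitions (%s eye)\n",
              d[1], d[2], d[3], object@params@eye))
})

setMethod("show", "QuantMap", function(object) {
  v <- object@bf[object@mask]
  cat(sprintf(
    "QuantMap (%s eye): %dx%d @ %.3f mm; BF in mask: %.2f..%.2f mL/mL/min (%d px)\n",
    object@eye, nrow(object@bf), ncol(object@bf), object@pixelMm,
    if (length(v)) min(v) else NA, if (length(v)) max(v) else NA, sum(object@mask)
  ))
})

setMethod("show", "RetinaCurve", function(object) {
  cat(sprintf("RetinaCurve: %d points, arc length %.2f mm\n",
              nrow(object@points), max(object@arclength)))
})

setMethod("show", "LinearizedMap", function(object) {
  cat(sprintf(
    "LinearizedMap: %d positions x %d depths (along %.4f mm, depth %.4f mm; depth 0 at the retinal surface)\n",
    nrow(object@values), ncol(object@values), object@alongSpacing,
    object@depthSpacing
  ))
})

setMethod("show", "DepthProfile", function(object) {
  cat(sprintf("DepthProfile at position %s mm: %d samples, depth %.3f..%.3f mm\n",
              format(object@position), length(object@values),
              min(object@depths), max(object@depths)))
})

setMethod("show", "LayerWindows", function(object) {
  if (object@resolved) {
    cat(sprintf("LayerWindows (resolved): retina [%.3f, %.3f] mm, choroid [%.3f, %.3f] mm\n",
                object@retina[1], object@retina[2],
                object@choroid[1], object@choroid[2]))
  } else {
    cat(sprintf("LayerWindows (unresolved): combined [%.3f, %.3f] mm\n",
                object@combined[1], object@combined[2]))
  }
})

setMethod("show", "LayerMeasurement", function(object) {
  cat(sprintf("LayerMeasurement: %d positions, layers %s\n",
              nrow(object@perPosition),
              if (object@resolved) "resolved" else "unresolved"))
  print(round(object@averaged, 4))
})

setMethod("show", "SimLayerSpec", function(object) {
  cat(sprintf("SimLayerSpec: %d layers over %g um @ %g um\n",
              nrow(object@layers), object@domainUm, object@baseResUm))
  print(object@layers)
})

setMethod("show", "SimProfile", function(object) {
  cat(sprintf("SimProfile (%s): %d samples @ %g um\n",
              object@provenance, length(object@values), object@spacingUm))
})

setMethod("show", "EyePhantomSpec", function(object) {
  cat(sprintf(
    "EyePhantomSpec: radius %.2f mm in %g mm FOV, ONH gap %g deg at %g deg\n",
    object@eyeRadiusMm, object@fovMm, object@onhWidthDeg, object@onhAngleDeg
  ))
})

setMethod("show", "PhantomAcquisition", function(object) {
  cat("PhantomAcquisition:\n  ")
  show(object@series)
  cat(sprintf("  truth: %dx%d @ %.4f mm\n", nrow(object@truthBf),
              ncol(object@truthBf), object@truthPixelMm))
})
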