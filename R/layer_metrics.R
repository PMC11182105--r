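# Layer segmentation and the two blood-flow summary metrics: per-layer peak
# BF (mL/mL/min) and depth-integrated BF per retinal surface area
# (uL/mm^2/min).

#' Segment the retinal and choroidal vascular layers along depth
#'
#' Finds the dominant blood-flow peak, then the largest local maximum outside
#' its 10%-of-peak window. The two layers are called resolved when that
#' secondary peak (i) reaches at least `secondaryFrac` of the dominant peak,
#' (ii) is at least two samples away, (iii) is separated by an interior
#' minimum lower than both peaks, and (iv) that minimum does not plunge below
#' minus the secondary peak (deeply negative troughs are the signature of
#' truncation-ringing side lobes, not of a vascular layer). When resolved,
#' the windows split at the inter-peak minimum and extend outward to the
#' first sample below `edgeFrac` of the respective peak; the window closer to
#' the vitreous is the retinal layer, the deeper one the choroid. When not
#' resolved a single combined window around the dominant peak is returned.
#'
#' @param profile A [DepthProfile-class] spanning vitreous through sclera.
#' @param edgeFrac Window-edge threshold as a fraction of the layer peak.
#' @param secondaryFrac Minimum secondary-to-dominant peak ratio for the
#'   layers to count as resolved.
#' @param combinedTailMm Outward extension (mm) applied to each edge of the
#'   combined window when unresolved; used by the resolution simulation to
#'   span the blurred tails of the merged layers.
#' @return A [LayerWindows-class].
#' @export
segmentLayers <- function(profile, edgeFrac = 0.1, secondaryFrac = 0.125,
                          combinedTailMm = 0) {
  stopifnot(is(profile, "DepthProfile"))
  v <- profile@values
  d <- profile@depths
  v[is.na(v)] <- 0
  if (max(v) <= 0) stop("no vascular signal: profile is non-positive everywhere")
  ig <- which.max(v)
  wg <- expandWindow(v, ig, edgeFrac)
  spd <- if (length(d) > 1) d[2] - d[1] else 1
  unresolvedWindows <- function() {
    lo <- max(d[wg[1]] - spd / 2 - combinedTailMm, d[1] - spd / 2)
    hi <- min(d[wg[2]] + spd / 2 + combinedTailMm, d[length(d)] + spd / 2)
    new("LayerWindows", retina = c(NA_real_, NA_real_),
        choroid = c(NA_real_, NA_real_), combined = c(lo, hi),
        resolved = FALSE)
  }
  lm <- localMaxima(v)
  lm <- lm[lm < wg[1] | lm > wg[2]]
  if (!length(lm)) return(unresolvedWindows())
  i2 <- lm[which.max(v[lm])]
  if (v[i2] < secondaryFrac * v[ig]) return(unresolvedWindows())
  a <- min(ig, i2)
  b <- max(ig, i2)
  if (b - a < 2) return(unresolvedWindows())
  trough <- a - 1L + which.min(v[a:b])
  if (v[trough] >= min(v[a], v[b])) return(unresolvedWindows())
  if (v[trough] < -abs(v[i2])) return(unresolvedWindows())
  iRet <- a
  iCho <- b
  wRet <- expandWindow(v, iRet, edgeFrac, hiLim = trough)
  wCho <- expandWindow(v, iCho, edgeFrac, loLim = trough)
  # windows are reported as cell-boundary intervals [start, end): each
  # sample's cell is [d - sp/2, d + sp/2), the trough cell belongs to the
  # choroid window, and the retina/choroid windows tile the combined window
  # without double-counting a sample
  new("LayerWindows",
    retina = c(d[wRet[1]] - spd / 2, d[trough] - spd / 2),
    choroid = c(d[trough] - spd / 2, d[wCho[2]] + spd / 2),
    combined = c(d[wRet[1]] - spd / 2, d[wCho[2]] + spd / 2), resolved = TRUE
  )
}

# Indices of profile samples whose cell centre falls in the half-open depth
# window [w1, w2) (mm).
windowIndices <- function(profile, w) {
  d <- profile@depths
  sp <- if (length(d) > 1) d[2] - d[1] else 1
  if (w[1] < d[1] - sp / 2 - 1e-9 || w[2] > d[length(d)] + sp / 2 + 1e-9) {
    stop(sprintf("window [%.3f, %.3f] mm lies outside the profile extent [%.3f, %.3f]",
                 w[1], w[2], d[1], d[length(d)]))
  }
  which(d >= w[1] & d < w[2])
}

#' Per-layer peak blood flow
#'
#' Maximum profile value within each layer window (mL/mL/min); ties are
#' broken toward the smallest depth. For unresolved windows only the combined
#' peak is returned, flagged by `resolved = FALSE`.
#'
#' @param profile A [DepthProfile-class].
#' @param windows A [LayerWindows-class] from [segmentLayers()].
#' @return List with elements `retina`, `choroid` (NA when unresolved),
#'   `combined`, `resolved`, and the peak depths `depthRetina`,
#'   `depthChoroid` (mm).
#' @export
peakBF <- function(profile, windows) {
  stopifnot(is(profile, "DepthProfile"), is(windows, "LayerWindows"))
  v <- profile@values
  pk <- function(w) {
    i <- windowIndices(profile, w)
    j <- i[which.max(v[i])]
    c(v[j], profile@depths[j])
  }
  comb <- pk(windows@combined)
  if (!windows@resolved) {
    return(list(retina = NA_real_, choroid = NA_real_, combined = comb[1],
                resolved = FALSE, depthRetina = NA_real_,
                depthChoroid = comb[2]))
  }
  r <- pk(windows@retina)
  ch <- pk(windows@choroid)
  list(retina = r[1], choroid = ch[1], combined = comb[1], resolved = TRUE,
       depthRetina = r[2], depthChoroid = ch[2])
}

#' Depth-integrated blood flow per retinal surface area
#'
#' Rectangle-rule integral of the profile over each layer window:
#' sum(values) x depth spacing. Units: mL/mL/min integrated over mm of depth
#' gives mm^3 blood per mm^2 of retinal surface per minute, and 1 mm^3 =
#' 1 uL, so the result is in uL/mm^2/min directly. At 6x interpolation this
#' equals (sum of interpolated samples)/6 x 0.042 mm, i.e. the native-pixel
#' scaling applied per native sample.
#'
#' @param profile A [DepthProfile-class].
#' @param windows A [LayerWindows-class].
#' @return List with elements `retina`, `choroid` (NA when unresolved),
#'   `combined` and `resolved`; values in uL/mm^2/min.
#' @export
integratedBF <- function(profile, windows) {
  stopifnot(is(profile, "DepthProfile"), is(windows, "LayerWindows"))
  sp <- profile@depths[2] - profile@depths[1]
  v <- profile@values
  v[is.na(v)] <- 0
  integ <- function(w) sum(v[windowIndices(profile, w)]) * sp
  comb <- integ(windows@combined)
  if (!windows@resolved) {
    return(list(retina = NA_real_, choroid = NA_real_, combined = comb,
                resolved = FALSE))
  }
  list(retina = integ(windows@retina), choroid = integ(windows@choroid),
       combined = comb, resolved = TRUE)
}

#' Measure layer metrics along the whole retina
#'
#' Segments the layers on the profile averaged over the analysis span (the
#' averaged profile is far less noisy than any single position), then applies
#' the same depth windows at every along-retina position to obtain per-
#' position peak and integrated values, and finally averages them along
#' ~1 mm of retina on both sides of the optic nerve head.
#'
#' @param linBF A [LinearizedMap-class] of blood flow (mL/mL/min).
#' @param onhPositionMm Arc-length coordinate of the optic nerve head
#'   (e.g. from [locateONH()]).
#' @param spanMm,onhExclusionMm Averaging span and optic-nerve-head exclusion
#'   passed to [averageAlongRetina()].
#' @param edgeFrac,secondaryFrac Segmentation parameters, see
#'   [segmentLayers()].
#' @return A [LayerMeasurement-class].
#' @export
measureLayers <- function(linBF, onhPositionMm, spanMm = 1,
                          onhExclusionMm = 0.2, edgeFrac = 0.1,
                          secondaryFrac = 0.125) {
  stopifnot(is(linBF, "LinearizedMap"))
  pos <- linBF@positions - onhPositionMm
  inSpan <- abs(pos) >= onhExclusionMm & abs(pos) <= onhExclusionMm + spanMm
  if (!any(inSpan)) inSpan <- rep(TRUE, length(pos))
  avgVals <- colMeans(linBF@values[inSpan, , drop = FALSE], na.rm = TRUE)
  avgProf <- new("DepthProfile", values = avgVals, depths = linBF@depths,
                 position = NA_real_)
  win <- segmentLayers(avgProf, edgeFrac = edgeFrac,
                       secondaryFrac = secondaryFrac)
  rows <- lapply(seq_along(pos), function(i) {
    pr <- new("DepthProfile", values = linBF@values[i, ],
              depths = linBF@depths, position = pos[i])
    pk <- peakBF(pr, win)
    it <- integratedBF(pr, win)
    if (win@resolved) {
      data.frame(position = pos[i], peakRetina = pk$retina,
                 peakChoroid = pk$choroid, intRetina = it$retina,
                 intChoroid = it$choroid)
    } else {
      data.frame(position = pos[i], peakRetina = NA_real_,
                 peakChoroid = pk$combined, intRetina = NA_real_,
                 intChoroid = it$combined)
    }
  })
  per <- do.call(rbind, rows)
  avg <- averageAlongRetina(per, spanMm = spanMm,
                            onhExclusionMm = onhExclusionMm)
  new("LayerMeasurement", perPosition = per, averaged = avg, windows = win,
      resolved = win@resolved)
}

#' Average per-position metrics along the retina
#'
#' Arithmetic mean of each metric over the positions
#' `onhExclusionMm <= |position| <= onhExclusionMm + spanMm` on each side of
#' the optic nerve head, then the mean of the two sides. A side covering less
#' than half the requested span is dropped with a warning; if both sides are
#' missing an error is raised.
#'
#' @param perPosition `data.frame` with a `position` column (signed mm
#'   relative to the optic nerve head) and one column per metric.
#' @param onhPositionMm Offset subtracted from `position` first (0 when the
#'   positions are already ONH-relative).
#' @param spanMm Length of retina averaged on each side (mm).
#' @param onhExclusionMm Half-width of the excluded zone around the optic
#'   nerve head (mm).
#' @return Named numeric vector of averaged metrics.
#' @export
averageAlongRetina <- function(perPosition, onhPositionMm = 0, spanMm = 1,
                               onhExclusionMm = 0.2) {
  pos <- perPosition$position - onhPositionMm
  metricCols <- setdiff(names(perPosition), "position")
  sp <- stats::median(diff(sort(unique(pos))))
  sideMean <- function(sel, label) {
    if (sum(sel) * sp < spanMm / 2) {
      warning(sprintf("%s side covers %.2f mm < half the %.2f mm span; dropped",
                      label, sum(sel) * sp, spanMm))
      return(NULL)
    }
    colMeans(perPosition[sel, metricCols, drop = FALSE], na.rm = TRUE)
  }
  nasal <- sideMean(pos <= -onhExclusionMm & pos >= -(onhExclusionMm + spanMm),
                    "nasal")
  temporal <- sideMean(pos >= onhExclusionMm & pos <= onhExclusionMm + spanMm,
                       "temporal")
  sides <- Filter(Negate(is.null), list(nasal, temporal))
  if (!length(sides)) stop("no retina coverage on either side of the optic nerve head")
  colMeans(do.call(rbind, sides))
}
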