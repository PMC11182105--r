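# ASL quantification: control-label subtraction and the single-compartment
# blood-flow equation.

#' Control-minus-label difference map
#'
#' Averages the control and label repetition stacks separately and subtracts
#' (mean control minus mean label). Averaging before subtraction is exactly
#' equivalent to subtracting repetition-wise and averaging afterwards;
#' averaging first is cheaper. No outlier-repetition rejection is applied.
#'
#' @param series An [ASLSeries-class].
#' @return Matrix of mean signal difference, same in-plane shape as the
#'   input.
#' @examples
#' p <- acquisitionParams("left")
#' s <- aslSeries(array(1, c(4, 4, 3)), array(0.99, c(4, 4, 3)),
#'                matrix(1, 4, 4), p)
#' computeDeltaM(s)[1, 1]  # 0.01
#' @export
computeDeltaM <- function(series) {
  stopifnot(is(series, "ASLSeries"))
  nrep <- dim(series@control)[3]
  ctl <- rowMeans(series@control, dims = 2)
  lbl <- rowMeans(series@label, dims = 2)
  ctl - lbl
}

#' Denominator factor of the blood-flow equation
#'
#' The factor \eqn{K = 2 \alpha T_{1B} e^{-PLD/T_{1B}} e^{-TE/T_{2B}^*}
#' \lambda_a} such that \eqn{BF = 60\,\Delta M / (K\,M_0)}.
#'
#' @param params An [AcquisitionParams-class].
#' @return Scalar factor (seconds).
#' @export
quantDenominator <- function(params) {
  stopifnot(is(params, "AcquisitionParams"))
  2 * params@alpha * params@t1Blood *
    exp(-params@pld / params@t1Blood) *
    exp(-params@te / params@t2starBlood) *
    params@lambdaA
}

#' Quantify blood flow from a difference map
#'
#' Applies the single-compartment ASL equation
#' \deqn{BF = \frac{60\,\Delta M}{2\,\alpha\,T_{1B}\,e^{-PLD/T_{1B}}\,
#' e^{-TE/T_{2B}^*}\,\lambda_a\,M_0}}
#' yielding mL blood / mL tissue / min. The result is linear in
#' \eqn{\Delta M} and inversely proportional to \eqn{M_0}. Negative values
#' (noise) are retained; clipping is a display concern only.
#'
#' @param deltaM Difference map (matrix) or vector/scalar.
#' @param m0 Equilibrium-magnetization reference: a scalar (typically the
#'   pre-retinal vitreous signal), or a matrix/vector conformable with
#'   `deltaM`. Must be strictly positive wherever `mask` is set.
#' @param params An [AcquisitionParams-class].
#' @param mask Logical matrix marking valid pixels; defaults to `m0 > 0`
#'   evaluated elementwise. Values outside the mask are set to `NA`.
#' @return A [QuantMap-class] when `deltaM` is a matrix, otherwise a numeric
#'   vector of BF values.
#' @examples
#' p <- acquisitionParams("left")
#' quantifyBF(0.01, 1, p)  # ~0.405 mL/mL/min
#' @export
quantifyBF <- function(deltaM, m0, params, mask = NULL) {
  stopifnot(is(params, "AcquisitionParams"))
  K <- quantDenominator(params)
  if (!is.matrix(deltaM)) {
    if (any(m0 <= 0)) stop("m0 must be strictly positive")
    return(60 * deltaM / (K * m0))
  }
  m0m <- if (length(m0) == 1L) {
    matrix(m0, nrow(deltaM), ncol(deltaM))
  } else {
    as.matrix(m0)
  }
  if (!identical(dim(m0m), dim(deltaM))) {
    stop(sprintf(
      "m0 shape %s does not match deltaM shape %s",
      paste(dim(m0m), collapse = "x"), paste(dim(deltaM), collapse = "x")
    ))
  }
  if (is.null(mask)) mask <- m0m > 0
  if (any(m0m[mask] <= 0)) {
    stop("non-positive M0 inside the mask; quantification would diverge")
  }
  bf <- matrix(NA_real_, nrow(deltaM), ncol(deltaM))
  bf[mask] <- 60 * deltaM[mask] / (K * m0m[mask])
  new("QuantMap", bf = bf, pixelMm = params@pixelMm, eye = params@eye,
      mask = mask)
}

#' Per-profile M0 from the pre-retinal vitreous
#'
#' For each along-retina position of a flattened M0 map, averages the M0
#' signal over a depth segment lying in the pre-retinal vitreous (negative
#' depths, vitreal side of the retinal surface).
#'
#' @param linM0 A [LinearizedMap-class] of the M0 image (flattened with the
#'   same retinal curve as the difference map).
#' @param vitreousDepthMm Depth interval (mm) of the vitreous segment;
#'   default `c(-0.3, -0.1)`, i.e. 0.1-0.3 mm vitreal of the inner retinal
#'   surface.
#' @return Numeric vector of strictly positive M0 values, one per position.
#' @export
m0FromVitreous <- function(linM0, vitreousDepthMm = c(-0.3, -0.1)) {
  stopifnot(is(linM0, "LinearizedMap"))
  sel <- linM0@depths >= vitreousDepthMm[1] & linM0@depths <= vitreousDepthMm[2]
  if (!any(sel)) {
    stop(sprintf(
      "empty vitreous segment: no depth samples in [%.3f, %.3f] mm (map spans %.3f..%.3f)",
      vitreousDepthMm[1], vitreousDepthMm[2], min(linM0@depths), max(linM0@depths)
    ))
  }
  m0 <- rowMeans(linM0@values[, sel, drop = FALSE], na.rm = TRUE)
  if (any(!is.finite(m0)) || any(m0 <= 0)) {
    stop("non-positive or undefined vitreous M0 for some profiles; check the vitreous segment")
  }
  m0
}
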