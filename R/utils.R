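# Internal numerical helpers: image interpolation, band-limited resampling,
# local-maximum detection.

# Sample a matrix at continuous (x, y) positions given in mm, with pixel
# centres at (i - 0.5) * pixelMm. Returns NA outside the image domain.
# method "cubic" is separable Catmull-Rom (kernel weights sum to 1, so a
# constant image is reproduced exactly); "linear" is bilinear.
interpImage <- function(img, x, y, pixelMm, method = c("cubic", "linear")) {
  method <- match.arg(method)
  nx <- nrow(img)
  ny <- ncol(img)
  fx <- x / pixelMm + 0.5
  fy <- y / pixelMm + 0.5
  out <- rep(NA_real_, length(fx))
  inside <- fx >= 0.5 & fx <= nx + 0.5 & fy >= 0.5 & fy <= ny + 0.5
  if (!any(inside)) return(out)
  fx <- fx[inside]
  fy <- fy[inside]
  if (method == "linear") {
    i0 <- pmin(pmax(floor(fx), 1L), nx - 1L)
    j0 <- pmin(pmax(floor(fy), 1L), ny - 1L)
    tx <- pmin(pmax(fx - i0, 0), 1)
    ty <- pmin(pmax(fy - j0, 0), 1)
    v <- img[cbind(i0, j0)] * (1 - tx) * (1 - ty) +
      img[cbind(i0 + 1L, j0)] * tx * (1 - ty) +
      img[cbind(i0, j0 + 1L)] * (1 - tx) * ty +
      img[cbind(i0 + 1L, j0 + 1L)] * tx * ty
  } else {
    i0 <- floor(fx)
    j0 <- floor(fy)
    tx <- fx - i0
    ty <- fy - j0
    wx <- catmullRomWeights(tx)
    wy <- catmullRomWeights(ty)
    v <- numeric(length(fx))
    for (a in 0:3) {
      ia <- pmin(pmax(i0 - 1L + a, 1L), nx)
      rowacc <- numeric(length(fx))
      for (b in 0:3) {
        jb <- pmin(pmax(j0 - 1L + b, 1L), ny)
        rowacc <- rowacc + wy[, b + 1L] * img[cbind(ia, jb)]
      }
      v <- v + wx[, a + 1L] * rowacc
    }
  }
  out[inside] <- v
  out
}

catmullRomWeights <- function(t) {
  t2 <- t * t
  t3 <- t2 * t
  cbind(
    0.5 * (-t3 + 2 * t2 - t),
    0.5 * (3 * t3 - 5 * t2 + 2),
    0.5 * (-3 * t3 + 4 * t2 + t),
    0.5 * (t3 - t2)
  )
}

# Band-limited resampling operator: P[j, i] maps samples at xin (cell
# centres on a domain of length L, treated as periodic) to exact values of
# the Fourier series truncated at |m| <= mMax, evaluated at xout.
# P is the (normalised) Dirichlet kernel; it is real.
dirichletOperator <- function(xin, xout, L, mMax) {
  n <- length(xin)
  mMax <- min(mMax, floor((n - 1) / 2))
  d <- outer(xout, xin, "-") * (2 * pi / L)
  P <- matrix(1, nrow(d), ncol(d))
  for (m in seq_len(mMax)) P <- P + 2 * cos(m * d)
  P / n
}

# Indices of interior local maxima of a vector, with plateau handling: a
# maximal run of equal values higher than both neighbouring runs reports its
# first index (smallest depth on ties).
localMaxima <- function(v) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  if (k < 3) return(integer())
  idx <- which(
    seq_len(k) > 1L & seq_len(k) < k &
      r$values > c(-Inf, r$values[-k]) &
      r$values > c(r$values[-1], -Inf)
  )
  starts[idx]
}

# Grow a window around index i to the first samples on either side that drop
# below frac * v[i], within [loLim, hiLim].
expandWindow <- function(v, i, frac, loLim = 1L, hiLim = length(v)) {
  thr <- frac * v[i]
  lo <- i
  while (lo > loLim && v[lo - 1L] >= thr) lo <- lo - 1L
  hi <- i
  while (hi < hiLim && v[hi + 1L] >= thr) hi <- hi + 1L
  c(lo, hi)
}

# Evaluate the RNG state-preserving seeded call used by the generators.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
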