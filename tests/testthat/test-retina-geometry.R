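test_that("curve detection recovers the phantom's circular inner surface", {
  fx <- phantomFixture()
  dm <- computeDeltaM(fx$acq@series)
  curve <- detectRetinaCurve(dm, fx$seeds, fx$acq@series@params@pixelMm)
  r <- sqrt((curve@points[, 1] - 3)^2 + (curve@points[, 2] - 3)^2)
  # inner retinal surface lies at 1.2 mm; within one 0.042 mm pixel
  expect_lt(max(abs(r - 1.2)), 0.042)
  # deterministic
  curve2 <- detectRetinaCurve(dm, fx$seeds, fx$acq@series@params@pixelMm)
  expect_identical(curve@points, curve2@points)
})

test_that("collinear seeds on a straight band give a collinear curve", {
  img <- matrix(0, 60, 80)
  img[, 30] <- 8
  px <- 0.042
  y0 <- (30 - 0.5) * px
  seeds <- cbind(c(0.3, 1.2, 2.2), rep(y0, 3))
  curve <- detectRetinaCurve(img, seeds, px)
  expect_lt(max(abs(curve@points[, 2] - y0)), 0.007)
  expect_true(all(diff(curve@arclength) > 0))
})

test_that("seeds away from any band are rejected and named", {
  img <- matrix(0, 60, 60)
  img[, 30] <- 8
  seeds <- cbind(c(0.3, 1.2, 2.2), c(0.1, 0.1, (30 - 0.5) * 0.042))
  expect_error(detectRetinaCurve(img, seeds, 0.042), "1, 2")
})

test_that("flattening a constant image is constant to interpolation precision", {
  curve <- circularCurve(c(3, 3), 1.2, c(200, 340))
  lin <- linearizeMap(matrix(5, 144, 144), curve, mapPixelMm = 6 / 144)
  v <- lin@values[!lin@excluded]
  expect_lt(max(abs(v - 5)), 5e-6)
  expect_equal(lin@depthSpacing, 6 / 144 / 6)
})

test_that("a thin bright ring flattens to a horizontal band", {
  n <- 144
  px <- 6 / n
  cc <- seq(px / 2, by = px, length.out = n)
  rr <- sqrt(outer(cc - 3, rep(1, n))^2 + outer(rep(1, n), cc - 3)^2)
  ring <- matrix(8 * pmax(1 - abs(rr - 1.2) / px, 0), n, n)
  th <- c(210, 270, 330) * pi / 180
  seeds <- cbind(3 + 1.2 * cos(th), 3 + 1.2 * sin(th))
  curve <- detectRetinaCurve(ring, seeds, px)
  lin <- linearizeMap(ring, curve, mapPixelMm = px,
                      depthRangeMm = c(-0.2, 0.2))
  com <- apply(lin@values, 1, function(w) {
    sum(w * lin@depths, na.rm = TRUE) / sum(w, na.rm = TRUE)
  })
  k <- length(com)
  interior <- seq(ceiling(k * 0.05), floor(k * 0.95))
  # band-centre depth varies by less than one interpolated sample
  expect_lt(diff(range(com[interior])), 2 * 0.007)
  expect_lt(sd(com[interior]), 0.007)
})

test_that("interp factor 1 on an axis-aligned band reads pixels directly", {
  img <- matrix(0, 60, 80)
  img[, 30] <- 8
  img[, 27] <- 2
  px <- 0.042
  y0 <- (30 - 0.5) * px
  seeds <- cbind(c(0.3, 1.2, 2.2), rep(y0, 3))
  curve <- detectRetinaCurve(img, seeds, px)
  lin <- linearizeMap(img, curve, mapPixelMm = px, interpFactor = 1,
                      depthRangeMm = c(-0.21, 0.21))
  i <- which.min(abs(lin@depths))
  expect_equal(lin@depths[i], 0)
  expect_equal(unname(lin@values[10, i]), 8)
  # the dimmer reference band sits exactly three pixels to one side; the
  # normal's sign is a convention, so check both offsets
  j <- which.min(abs(lin@depths + 3 * px))
  k <- which.min(abs(lin@depths - 3 * px))
  expect_setequal(unname(c(lin@values[10, j], lin@values[10, k])), c(0, 2))
})

test_that("flattening a rotationally symmetric phantom is translation invariant", {
  spec <- eyePhantomSpec(onhWidthDeg = 0)
  truth <- makePhantom(spec)
  curve <- circularCurve(c(3, 3), 1.2, c(200, 340))
  lin <- linearizeMap(truth$bf, curve, mapPixelMm = truth$pixelMm)
  win <- lin@depths >= 0.11 & lin@depths <= 0.19
  v <- rowSums(lin@values[, win]) * lin@depthSpacing
  v <- v[!is.na(v)]
  expect_lt(sd(v) / mean(v), 0.02)
})

test_that("flattening preserves mean BF inside the retinal band within 3%", {
  spec <- eyePhantomSpec(onhWidthDeg = 0)
  truth <- makePhantom(spec)
  acq <- synthesizeAcquisition(truth, leftParams(), nReps = 1, noiseSd = 0)
  dm <- computeDeltaM(acq@series)
  qm <- quantifyBF(dm, 1, acq@series@params,
                   mask = acq@series@m0 > 0.1)
  curve <- circularCurve(c(3, 3), 1.2, c(200, 340))
  lin <- linearizeMap(qm, curve)
  n <- nrow(qm@bf)
  cc <- seq(qm@pixelMm / 2, by = qm@pixelMm, length.out = n)
  X <- matrix(cc, n, n)
  Y <- matrix(cc, n, n, byrow = TRUE)
  rr <- sqrt((X - 3)^2 + (Y - 3)^2)
  th <- (atan2(Y - 3, X - 3) * 180 / pi) %% 360
  band <- rr >= 1.2 & rr < 1.37 & th >= 200 & th <= 340
  natMean <- mean(qm@bf[band])
  dep <- which(lin@depths >= 0 & lin@depths < 0.17)
  # the native mean weights pixels by area; weight the flattened samples by
  # the polar Jacobian (r0 + depth) so the two means are comparable
  w <- 1.2 + lin@depths[dep]
  vals <- lin@values[, dep]
  nPos <- sum(stats::complete.cases(vals))
  linMean <- sum(sweep(vals, 2, w, "*"), na.rm = TRUE) / (nPos * sum(w))
  expect_lt(abs(linMean / natMean - 1), 0.03)
})

test_that("profiles carry signed positions about the optic nerve head", {
  lin <- new("LinearizedMap", values = matrix(rep(1:4, 5), 5, 4, byrow = TRUE),
             excluded = matrix(FALSE, 5, 4),
             positions = seq(0, by = 0.007, length.out = 5),
             depths = seq(0.007, by = 0.007, length.out = 4),
             alongSpacing = 0.007, depthSpacing = 0.007)
  out <- extractProfiles(lin, onhPositionMm = 0.014)
  expect_length(out$profiles, 5)
  expect_equal(out$profiles[[1]]@position, -0.014)
  expect_equal(out$profiles[[5]]@position, 0.014)
  # identical rows average to the common row
  expect_equal(out$averaged@values, 1:4)
  expect_error(extractProfiles(lin, 1), "outside the sampled arc")

  # averaging two known profiles
  lin2 <- new("LinearizedMap", values = rbind(c(1, 2, 3), c(3, 4, 5)),
              excluded = matrix(FALSE, 2, 3),
              positions = c(0, 0.007), depths = c(0.007, 0.014, 0.021),
              alongSpacing = 0.007, depthSpacing = 0.007)
  expect_equal(extractProfiles(lin2, 0)$averaged@values, c(2, 3, 4))
})

test_that("the optic nerve head is located at the vascular gap", {
  fx <- phantomFixture()
  res <- runBFPipeline(fx$acq@series, fx$seeds)
  # the gap is at 270 deg; the curve spans about [203, 337] deg at ~1.2 mm
  # radius, so the ONH should sit near the middle of the arc
  sMax <- max(res$linBF@positions)
  expect_gt(res$onhPositionMm, sMax / 2 - 0.25)
  expect_lt(res$onhPositionMm, sMax / 2 + 0.25)
})
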