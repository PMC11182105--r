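test_that("well-separated peaks are segmented at the trough between them", {
  # retinal bump peaking at ~0.05 mm (1.6) and choroidal bump at ~0.2 mm (8)
  d <- seq(0.007, 0.3, by = 0.007)
  v <- 1.6 * exp(-((d - 0.05) / 0.02)^2) + 8 * exp(-((d - 0.2) / 0.02)^2)
  win <- segmentLayers(profileFrom(v))
  expect_true(isResolved(win))
  expect_lt(win@retina[2], 0.2)
  expect_gt(win@retina[2], 0.05)
  expect_equal(win@retina[2], win@choroid[1])  # split at the trough
  # peaks recovered in the right windows
  pk <- peakBF(profileFrom(v), win)
  expect_equal(pk$retina, max(v[d < 0.12]))
  expect_equal(pk$choroid, max(v))
})

test_that("a unimodal profile is unresolved with one combined window", {
  d <- seq(0.007, 0.3, by = 0.007)
  v <- 5 * exp(-((d - 0.15) / 0.05)^2)
  win <- segmentLayers(profileFrom(v))
  expect_false(isResolved(win))
  expect_true(all(is.na(win@retina)))
  pk <- peakBF(profileFrom(v), win)
  expect_false(pk$resolved)
  expect_equal(pk$combined, max(v))
})

test_that("an all-zero profile raises the no-signal error", {
  expect_error(segmentLayers(profileFrom(rep(0, 50))), "no vascular signal")
})

test_that("peak values use the window maximum with smallest-depth ties", {
  v <- c(0, 0, 1.2, 1.6, 1.4, 0, 0, 5, 5, 5, 0)
  prof <- profileFrom(v)
  win <- segmentLayers(prof)
  expect_true(isResolved(win))
  pk <- peakBF(prof, win)
  expect_equal(pk$retina, 1.6)
  expect_equal(pk$choroid, 5)
  # constant plateau: reported at its first (shallowest) depth
  expect_equal(pk$depthChoroid, prof@depths[8])
})

test_that("integrated BF is the rectangle-rule integral in uL/mm^2/min", {
  # value 8 over exactly 0.042 mm (6 samples at 0.007 mm), zero elsewhere;
  # windows are half-open cell-boundary intervals
  v <- c(rep(0, 10), rep(8, 6), rep(0, 10))
  prof <- profileFrom(v)
  d <- prof@depths
  hw <- 0.0035
  win <- new("LayerWindows", retina = c(d[2] - hw, d[11] - hw),
             choroid = c(d[11] - hw, d[16] + hw),
             combined = c(d[2] - hw, d[16] + hw), resolved = TRUE)
  it <- integratedBF(prof, win)
  expect_equal(it$choroid, 0.336)
  expect_equal(it$retina, 0)
  expect_equal(it$combined, 0.336)
  # all-zero window integrates to zero
  z <- integratedBF(prof, new("LayerWindows", retina = c(0.007, 0.021),
                              choroid = c(0.028, 0.042),
                              combined = c(0.007, 0.042), resolved = TRUE))
  expect_equal(z$retina, 0)
  # window outside the profile extent errors
  bad <- new("LayerWindows", retina = c(0.007, 0.021), choroid = c(1, 2),
             combined = c(0.007, 2), resolved = TRUE)
  expect_error(integratedBF(prof, bad), "outside the profile extent")
})

test_that("integrated BF never exceeds peak times window width", {
  set.seed(11)
  for (i in 1:20) {
    v <- abs(rnorm(60, 1, 2)) * rbinom(60, 1, 0.7)
    v[25:30] <- v[25:30] + 6  # ensure some signal
    prof <- profileFrom(v)
    win <- segmentLayers(prof)
    it <- integratedBF(prof, win)
    pk <- peakBF(prof, win)
    if (isResolved(win)) {
      expect_lte(it$retina, pk$retina * diff(win@retina) + 1e-12)
      expect_lte(it$choroid, pk$choroid * diff(win@choroid) + 1e-12)
    } else {
      expect_lte(it$combined, pk$combined * diff(win@combined) + 1e-12)
    }
  }
})

test_that("doubling the interpolation factor moves integrals by under 1%", {
  fx <- phantomFixture()
  dm <- computeDeltaM(fx$acq@series)
  qm <- quantifyBF(dm, 1, fx$acq@series@params,
                   mask = matrix(TRUE, 144, 144))
  curve <- circularCurve(c(3, 3), 1.2, c(200, 340))
  get <- function(f) {
    lin <- linearizeMap(qm, curve, interpFactor = f)
    onh <- locateONH(lin)
    m <- measureLayers(lin, onh)
    averagedBF(m)[c("intRetina", "intChoroid")]
  }
  i6 <- get(6)
  i12 <- get(12)
  expect_lt(max(abs(i12 / i6 - 1)), 0.01)
})

test_that("along-retina averaging combines the two sides symmetrically", {
  pos <- seq(-1.3, 1.3, by = 0.01)
  constant <- data.frame(position = pos, m = rep(0.9, length(pos)))
  expect_equal(unname(averageAlongRetina(constant)["m"]), 0.9)

  sided <- data.frame(position = pos, m = ifelse(pos < 0, 0.8, 1.0))
  expect_equal(unname(averageAlongRetina(sided)["m"]), 0.9)

  # linear ramp from the centre: analytic mean over [0.2, 1.2] on each side
  ramp <- data.frame(position = pos, m = 2 - abs(pos))
  got <- unname(averageAlongRetina(ramp)["m"])
  expect_lt(abs(got - (2 - 0.7)) / (2 - 0.7), 0.02)
})

test_that("a side with insufficient coverage is dropped with a warning", {
  pos <- seq(-0.5, 1.3, by = 0.01)  # nasal side covers only 0.3 mm of span
  df <- data.frame(position = pos, m = ifelse(pos < 0, 100, 1))
  expect_warning(avg <- averageAlongRetina(df), "nasal")
  expect_equal(unname(avg["m"]), 1)
  onlyCentre <- data.frame(position = seq(-0.1, 0.1, 0.01), m = 1)
  expect_error(suppressWarnings(averageAlongRetina(onlyCentre)),
               "no retina coverage")
})

test_that("layer peak is never below the in-window mean", {
  set.seed(12)
  for (i in 1:10) {
    v <- abs(rnorm(60, 1, 2))
    v[15:20] <- v[15:20] + 4
    v[40:45] <- v[40:45] + 8
    prof <- profileFrom(v)
    win <- segmentLayers(prof)
    pk <- peakBF(prof, win)
    it <- integratedBF(prof, win)
    if (isResolved(win)) {
      expect_gte(pk$retina, it$retina / diff(win@retina) - 1e-12)
      expect_gte(pk$choroid, it$choroid / diff(win@choroid) - 1e-12)
    }
  }
})
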