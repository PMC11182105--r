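test_that("the pooled t-test matches its hand-computed closed form", {
  tt <- ttestTwoSample(c(1, 2, 3), c(4, 5, 6))
  # pooled sd 1, se = sqrt(2/3), t = -3/se with 4 df
  expect_equal(tt$t, -3 / sqrt(2 / 3), tolerance = 1e-6)
  expect_equal(tt$df, 4)
  expect_equal(tt$p, 0.0213, tolerance = 1e-2)
  # two-tailed p is twice the upper tail at |t|
  expect_equal(tt$p, 2 * pt(-abs(tt$t), tt$df), tolerance = 1e-10)

  ident <- ttestTwoSample(c(2, 2, 2), c(2, 2, 2))
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)
  expect_error(ttestTwoSample(c(2, 2), c(3, 3)), "degenerate variance")
})

test_that("eye averaging combines per-eye summaries as simple means", {
  tab <- data.frame(group = "DBA2J", eye = c("right", "left"),
                    mean = c(1.29, 1.25), sd = c(0.32, 0.26))
  avg <- eyeAveragedFromTable(tab)
  expect_equal(avg$mean, 1.27)
  expect_equal(avg$sd, 0.29)

  rec <- data.frame(subject = rep(1:4, each = 2), group = "G",
                    eye = rep(c("left", "right"), 4),
                    value = rep(c(1, 2, 3, 4), each = 2))
  s <- eyeAveragedSummary(rec)
  # identical eyes: averaged equals per-eye, correlation is 1
  expect_equal(s$mean, s$meanLeft)
  expect_equal(s$sd, s$sdLeft)
  expect_equal(s$rBetweenEyes, 1)

  # zero-variance eyes: correlation undefined, reported as NA
  recc <- data.frame(subject = rep(1:3, each = 2), group = "G",
                     eye = rep(c("left", "right"), 3), value = 5)
  expect_true(is.na(eyeAveragedSummary(recc)$rBetweenEyes))

  expect_error(eyeAveragedSummary(rec[c(1, 1, 3), ]), "one record per")
})

test_that("the between-eye correlation estimate recovers a known r", {
  set.seed(21)
  n <- 200
  u <- rnorm(n)
  le <- sqrt(0.6) * u + sqrt(0.4) * rnorm(n)
  re <- sqrt(0.6) * u + sqrt(0.4) * rnorm(n)
  rec <- data.frame(subject = rep(1:n, 2), group = "G",
                    eye = rep(c("left", "right"), each = n),
                    value = c(le, re))
  expect_lt(abs(eyeAveragedSummary(rec)$rBetweenEyes - 0.6), 0.1)
})

test_that("Cohen's d uses equal-weight RMS pooling and is scale invariant", {
  expect_equal(cohensD(0, 1, 1, 1), 1)
  expect_equal(cohensD(3, 2, 3, 1), 0)
  # affine rescaling of both groups leaves d unchanged
  d0 <- cohensD(1.27, 0.29, 1.59, 0.18)
  expect_equal(cohensD(10 * 1.27 + 5, 10 * 0.29, 10 * 1.59 + 5, 10 * 0.18), d0)
  expect_error(cohensD(0, 0, 1, 0), "SDs are zero")
})

test_that("noncentral-t sample sizes satisfy the minimality contract", {
  expect_equal(sampleSizeTTest(0.5), 86L)
  for (d in c(0.5, 1.33, 2.08)) {
    n <- sampleSizeTTest(d)
    expect_gte(powerTTest(n, d), 0.9)
    expect_lt(powerTTest(n - 1, d), 0.9)
  }
  # monotone: larger effects and looser alpha need fewer animals
  expect_gte(sampleSizeTTest(0.8), sampleSizeTTest(1.2))
  expect_gte(sampleSizeTTest(0.8, alpha = 0.01), sampleSizeTTest(0.8))
  expect_gte(sampleSizeTTest(0.8, power = 0.95), sampleSizeTTest(0.8))
  expect_error(sampleSizeTTest(1e-6, cap = 1000), "cap")
})

test_that("repeated-measures sizes shrink with lower between-eye correlation", {
  nLow <- sampleSizeRmAnova(1.33, 0)
  nHigh <- sampleSizeRmAnova(1.33, 0.9)
  expect_lt(nLow, nHigh)
  # minimality at the returned (even) N
  N <- sampleSizeRmAnova(1.33, 0.40)
  pw <- function(N, d = 1.33, r = 0.40) {
    lam <- (d / 2)^2 * N * 2 / (1 + r)
    1 - pf(qf(0.95, 1, N - 2), 1, N - 2, lam)
  }
  expect_gte(pw(N), 0.9)
  expect_lt(pw(N - 2), 0.9)
  # published both-eye design: d = 1.33, r = 0.40 gives 10 mice per group
  expect_equal(N %/% 2L, 10L)
})

test_that("the mixed model holds its nominal type-I error rate", {
  set.seed(31)
  nSim <- 300
  rejections <- 0
  for (i in seq_len(nSim)) {
    rec <- simulateEyeRecords(8, groupOffset = 0)
    p <- suppressMessages(compareGroupsTwoEyes(rec))$p
    if (p < 0.05) rejections <- rejections + 1
  }
  rate <- rejections / nSim
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.08)
})

test_that("the mixed model separates eye effects from group effects", {
  set.seed(32)
  groupRej <- 0
  eyeEst <- numeric(30)
  for (i in 1:30) {
    rec <- simulateEyeRecords(10, groupOffset = 0, eyeOffset = 1,
                              residSd = 0.5)
    fit <- suppressMessages(compareGroupsTwoEyes(rec))
    if (fit$p < 0.05) groupRej <- groupRej + 1
    co <- coef(summary(fit$model))
    eyeEst[i] <- co[grep("^eye", rownames(co)), "Estimate"]
  }
  expect_lte(groupRej, 4)                 # ~5% nominal
  expect_lt(abs(mean(eyeEst) - 1), 0.15)  # eye offset recovered
})

test_that("duplicated single eyes reproduce the t-test group estimate", {
  set.seed(33)
  one <- data.frame(subject = 1:12, group = rep(c("A", "B"), each = 6),
                    value = rnorm(12) + rep(c(0, 0.8), each = 6))
  both <- rbind(transform(one, eye = "left"), transform(one, eye = "right"))
  fit <- suppressWarnings(suppressMessages(compareGroupsTwoEyes(both)))
  tEst <- mean(one$value[one$group == "B"]) - mean(one$value[one$group == "A"])
  expect_equal(unname(fit$estimate), tEst, tolerance = 1e-6)

  expect_warning(single <- compareGroupsTwoEyes(transform(one, eye = "left")),
                 "single-eye")
  expect_equal(single$method, "t-test")
})

test_that("the IOP association recovers a known negative slope", {
  set.seed(42)
  n <- 24
  rec <- data.frame(subject = rep(1:n, each = 2),
                    eye = rep(c("left", "right"), n),
                    iop = rnorm(2 * n, 14, 2.5))
  rec$value <- 6 - 0.25 * rec$iop + rep(rnorm(n, 0, 0.2), each = 2) +
    rnorm(2 * n, 0, 0.2)
  a <- iopBfAssociation(rec)
  expect_lt(a$slope, 0)
  expect_lt(abs(a$slope - (-0.25)), 2 * a$se)
  expect_true(all(a$perEye$r < 0))

  # noise-free linear data: r is exactly -1
  recLin <- rec
  recLin$value <- 6 - 0.25 * recLin$iop
  aLin <- suppressWarnings(iopBfAssociation(recLin))
  expect_equal(unname(aLin$perEye$r), c(-1, -1))

  recConst <- rec
  recConst$iop <- 14
  expect_error(iopBfAssociation(recConst), "constant")
})

test_that("shuffled IOP shows no association in most permutations", {
  set.seed(42)
  n <- 24
  base <- data.frame(subject = rep(1:n, each = 2),
                     eye = rep(c("left", "right"), n),
                     value = rnorm(2 * n, 1.4, 0.3))
  ok <- 0
  nShuffle <- 100
  for (i in seq_len(nShuffle)) {
    rec <- base
    rec$iop <- sample(rnorm(2 * n, 14, 2))
    pe <- suppressMessages(iopBfAssociation(rec))$perEye
    if (all(pe$p > 0.05)) ok <- ok + 1
  }
  expect_gte(ok / nShuffle, 0.85)
  # |r| stays small on shuffled data
  set.seed(43)
  rec <- base
  rec$iop <- rnorm(2 * n, 14, 2)
  expect_lt(max(abs(suppressMessages(iopBfAssociation(rec))$perEye$r)), 0.5)
})

test_that("the report reproduces the published effect-size table", {
  tab <- readGroupSummaryTable(table3Path())
  cors <- read.csv(system.file("extdata", "between_eye_correlations.csv",
                               package = "ocuflow"))
  rep <- bfStatsReport(tab, cors)
  expect_equal(nrow(rep), 4)
  expect_equal(round(rep$d[rep$metric == "retina_peak"], 2), 1.33)
  expect_equal(rep$nOneEye[rep$metric == "retina_peak"], 13L)
  # integrated metrics give larger effects, hence fewer animals
  expect_gt(rep$d[rep$metric == "retina_integrated"],
            rep$d[rep$metric == "retina_peak"])
  expect_lte(rep$nOneEye[rep$metric == "retina_integrated"],
             rep$nOneEye[rep$metric == "retina_peak"])
})
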