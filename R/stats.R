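# Group statistics: pooled t-tests, eye-averaged summaries, Cohen's d,
# noncentral-t / noncentral-F sample-size estimation, mixed models over both
# eyes, and the blood-flow / intraocular-pressure association.

#' Two-sample t-test (pooled variance by default)
#'
#' Thin wrapper around [stats::t.test()] with the degenerate-variance
#' contract made explicit: when both groups have zero variance and equal
#' means the test is vacuous and `p = 1` is returned by convention; zero
#' variance with unequal means is an error rather than `p = 0`.
#'
#' @param x,y Numeric vectors (n >= 2 each).
#' @param tails 1 or 2.
#' @param welch Use the Welch (unequal-variance) variant instead of the
#'   pooled-variance Student t.
#' @return List with `t`, `df`, `p`.
#' @export
ttestTwoSample <- function(x, y, tails = 2, welch = FALSE) {
  stopifnot(length(x) >= 2, length(y) >= 2, tails %in% c(1, 2))
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(t = 0, df = length(x) + length(y) - 2, p = 1))
    }
    stop("degenerate variance: both groups constant with unequal means")
  }
  tt <- stats::t.test(x, y, var.equal = !welch)
  p <- if (tails == 2) tt$p.value else tt$p.value / 2
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = p)
}

#' Eye-averaged group summary
#'
#' Per-eye mean, SD and n for each group, then the eye-averaged summary used
#' for effect sizes: the overall mean is the mean of the two per-eye means
#' and the overall SD is the mean of the two per-eye SDs. The between-eye
#' Pearson correlation is computed over subjects with both eyes present.
#'
#' @param records `data.frame` with columns `subject`, `group`, `eye`
#'   (`"left"`/`"right"`) and `value`; at most one record per subject x eye.
#' @return `data.frame` with one row per group: per-eye `meanLeft`/`sdLeft`/
#'   `nLeft` and right-eye counterparts, eye-averaged `mean` and `sd`, and
#'   `rBetweenEyes` (NA when undefined, e.g. zero variance or no complete
#'   pairs).
#' @export
eyeAveragedSummary <- function(records) {
  need <- c("subject", "group", "eye", "value")
  if (!all(need %in% names(records))) {
    stop("records must have columns ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(records[, c("subject", "eye")])) {
    stop("at most one record per subject x eye is allowed")
  }
  do.call(rbind, lapply(split(records, records$group), function(g) {
    eyeStats <- function(side) {
      v <- g$value[g$eye == side]
      c(mean = mean(v), sd = if (length(v) >= 2) stats::sd(v) else NA_real_,
        n = length(v))
    }
    le <- eyeStats("left")
    re <- eyeStats("right")
    present <- c(le["n"], re["n"]) > 0
    if (!any(present)) stop("group without any eye data: ", g$group[1])
    if (!all(present)) {
      warning(sprintf("group %s has data for one eye only; averaged values equal that eye's",
                      g$group[1]))
    }
    wide <- merge(g[g$eye == "left", c("subject", "value")],
                  g[g$eye == "right", c("subject", "value")],
                  by = "subject")
    r <- if (nrow(wide) >= 3 && stats::sd(wide$value.x) > 0 &&
               stats::sd(wide$value.y) > 0) {
      stats::cor(wide$value.x, wide$value.y)
    } else {
      NA_real_
    }
    data.frame(
      group = g$group[1],
      meanLeft = le["mean"], sdLeft = le["sd"], nLeft = le["n"],
      meanRight = re["mean"], sdRight = re["sd"], nRight = re["n"],
      mean = mean(c(le["mean"], re["mean"]), na.rm = TRUE),
      sd = mean(c(le["sd"], re["sd"]), na.rm = TRUE),
      rBetweenEyes = r, row.names = NULL
    )
  }))
}

#' Eye-averaged summary from a printed group table
#'
#' Builds the same eye-averaged summary as [eyeAveragedSummary()] from
#' published per-eye means and SDs (when raw per-animal values are not
#' available).
#'
#' @param tab `data.frame` with columns `group`, `eye`, `mean`, `sd` and
#'   optionally `n`.
#' @return `data.frame` with one row per group: `group`, eye-averaged `mean`
#'   and `sd`.
#' @export
eyeAveragedFromTable <- function(tab) {
  need <- c("group", "eye", "mean", "sd")
  if (!all(need %in% names(tab))) {
    stop("table must have columns ", paste(need, collapse = ", "))
  }
  do.call(rbind, lapply(split(tab, tab$group), function(g) {
    data.frame(group = g$group[1], mean = mean(g$mean), sd = mean(g$sd),
               row.names = NULL)
  }))
}

#' Cohen's d from eye-averaged summaries
#'
#' Standardised mean difference `|meanB - meanA| / sqrt((sdA^2 + sdB^2)/2)`:
#' group mean difference over the equal-weight root-mean-square pooling of
#' the two (eye-averaged) SDs.
#'
#' @param meanA,sdA,meanB,sdB Eye-averaged group means and SDs (vectorised).
#' @return Cohen's d (>= 0).
#' @export
cohensD <- function(meanA, sdA, meanB, sdB) {
  pooled <- sqrt((sdA^2 + sdB^2) / 2)
  if (any(pooled == 0)) stop("both SDs are zero; d is undefined")
  abs(meanB - meanA) / pooled
}

#' Power of the two-sample t-test from the noncentral t distribution
#'
#' @param n Per-group sample size (1:1 allocation).
#' @param d Effect size (Cohen's d).
#' @param alpha Significance level.
#' @param tails 1 or 2.
#' @return Power at noncentrality `d * sqrt(n/2)` with `2n - 2` degrees of
#'   freedom.
#' @export
powerTTest <- function(n, d, alpha = 0.05, tails = 2) {
  ncp <- d * sqrt(n / 2)
  df <- 2 * n - 2
  if (tails == 2) {
    tc <- stats::qt(1 - alpha / 2, df)
    1 - stats::pt(tc, df, ncp) + stats::pt(-tc, df, ncp)
  } else {
    tc <- stats::qt(1 - alpha, df)
    1 - stats::pt(tc, df, ncp)
  }
}

#' Per-group sample size for a two-sample t-test
#'
#' Smallest integer n per group such that the exact noncentral-t power
#' reaches the target.
#'
#' @param d Effect size (> 0).
#' @param alpha Significance level.
#' @param power Target power.
#' @param tails 1 or 2.
#' @param cap Upper bound on n (guards against vanishing effect sizes).
#' @return Integer n per group.
#' @examples
#' sampleSizeTTest(0.5)  # 86 per group at alpha 0.05, power 0.9
#' @export
sampleSizeTTest <- function(d, alpha = 0.05, power = 0.9, tails = 2,
                            cap = 1e6) {
  stopifnot(d > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  n <- 2
  while (powerTTest(n, d, alpha, tails) < power) {
    n <- n + 1
    if (n > cap) stop("required sample size exceeds the cap (", cap, ")")
  }
  as.integer(n)
}

#' Sample size for a two-group repeated-measures (two-eye) design
#'
#' Between-factors repeated-measures ANOVA with m correlated measurements
#' per subject (two eyes): effect size `f = d/2`, noncentrality
#' `lambda = f^2 N m / (1 + (m-1) r)` with `N` the total sample size,
#' and power from the noncentral F with `df1 = 1`, `df2 = N - 2`. Returns
#' the smallest total N (balanced across the two groups, so N is even) whose
#' power reaches the target. Correlated eyes help less the larger `r`.
#'
#' @param d Between-group effect size (Cohen's d).
#' @param rBetweenEyes Between-eye Pearson correlation (|r| < 1).
#' @param m Measurements per subject (2 eyes).
#' @param alpha Significance level.
#' @param power Target power.
#' @param cap Upper bound on N.
#' @return Total N across both groups (even); divide by 2 for the per-group
#'   size.
#' @export
sampleSizeRmAnova <- function(d, rBetweenEyes, m = 2, alpha = 0.05,
                              power = 0.9, cap = 1e6) {
  stopifnot(d > 0, abs(rBetweenEyes) < 1)
  f <- d / 2
  pw <- function(N) {
    lambda <- f^2 * N * m / (1 + (m - 1) * rBetweenEyes)
    df2 <- N - 2
    1 - stats::pf(stats::qf(1 - alpha, 1, df2), 1, df2, lambda)
  }
  N <- 4
  while (pw(N) < power) {
    N <- N + 2
    if (N > cap) stop("required sample size exceeds the cap (", cap, ")")
  }
  as.integer(N)
}

#' Group comparison using both eyes (mixed model)
#'
#' Fits `value ~ group + eye + (1 | subject)` -- group and eye as fixed
#' factors with a subject-level random intercept (compound-symmetry
#' covariance between eyes) -- and returns the group fixed effect with its
#' Satterthwaite p-value. Falls back to the pooled t-test with a warning
#' when only one eye is present.
#'
#' @param records `data.frame` with columns `subject`, `group`, `eye`,
#'   `value`.
#' @return List with `estimate` (group effect, second level minus first),
#'   `se`, `p`, `method`, and the fitted `model` (when mixed).
#' @export
compareGroupsTwoEyes <- function(records) {
  records$group <- factor(records$group)
  if (nlevels(records$group) != 2) stop("exactly two groups are required")
  tFallback <- function(why) {
    warning(why, "; falling back to a pooled t-test")
    sp <- split(records$value, records$group)
    tt <- ttestTwoSample(sp[[1]], sp[[2]])
    est <- mean(sp[[2]]) - mean(sp[[1]])
    list(estimate = est, se = NA_real_, p = tt$p, method = "t-test")
  }
  if (length(unique(records$eye)) < 2) {
    return(tFallback("single-eye data"))
  }
  fit <- tryCatch(
    lmerTest::lmer(value ~ group + eye + (1 | subject), data = records),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    # happens for degenerate covariance, e.g. two identical eyes per subject
    return(tFallback("mixed model did not converge"))
  }
  co <- stats::coef(summary(fit))
  i <- grep("^group", rownames(co))[1]
  list(estimate = co[i, "Estimate"], se = co[i, "Std. Error"],
       p = co[i, "Pr(>|t|)"], method = "mixed", model = fit)
}

#' Association between blood flow and intraocular pressure
#'
#' Mixed-model slope of BF on IOP with a subject random intercept (both eyes
#' as repeated measures), plus per-eye Pearson correlation and ordinary
#' least-squares regression with 95% confidence intervals.
#'
#' @param records `data.frame` with columns `subject`, `eye`, `value` (BF)
#'   and `iop` (mmHg).
#' @return List with `slope`, `se`, `p` (mixed model) and `perEye`, a
#'   `data.frame` with one row per eye: `r`, `slope`, `intercept`,
#'   `slopeLo`, `slopeHi` (95% CI) and `p` of the correlation.
#' @export
iopBfAssociation <- function(records) {
  need <- c("subject", "eye", "value", "iop")
  if (!all(need %in% names(records))) {
    stop("records must have columns ", paste(need, collapse = ", "))
  }
  if (stats::sd(records$iop) == 0) stop("IOP is constant; association undefined")
  fit <- lmerTest::lmer(value ~ iop + (1 | subject), data = records)
  co <- stats::coef(summary(fit))
  perEye <- do.call(rbind, lapply(split(records, records$eye), function(g) {
    lmfit <- stats::lm(value ~ iop, data = g)
    ci <- stats::confint(lmfit)["iop", ]
    ct <- stats::cor.test(g$iop, g$value)
    data.frame(eye = g$eye[1], r = unname(ct$estimate),
               slope = stats::coef(lmfit)[["iop"]],
               intercept = stats::coef(lmfit)[[1]],
               slopeLo = ci[1], slopeHi = ci[2], p = ct$p.value,
               row.names = NULL)
  }))
  list(slope = co["iop", "Estimate"], se = co["iop", "Std. Error"],
       p = co["iop", "Pr(>|t|)"], perEye = perEye, model = fit)
}

#' Effect-size and sample-size report from a printed group table
#'
#' For each metric in a per-eye group summary table, computes the
#' eye-averaged group means and SDs, Cohen's d, the one-eye per-group sample
#' size (noncentral-t, alpha 0.05 two-sided, power 0.9) and -- when a
#' between-eye correlation is supplied -- the per-group size of the two-eye
#' repeated-measures design.
#'
#' @param tab `data.frame` with columns `metric`, `group`, `eye`, `mean`,
#'   `sd` (two groups; the first group sorted alphabetically is the
#'   reference).
#' @param correlations Optional `data.frame` with columns `metric`, `r`.
#' @param alpha,power Test level and target power.
#' @return `data.frame` with one row per metric: `d`, `nOneEye` and
#'   `nBothEyes` (NA without a correlation).
#' @export
bfStatsReport <- function(tab, correlations = NULL, alpha = 0.05,
                          power = 0.9) {
  need <- c("metric", "group", "eye", "mean", "sd")
  if (!all(need %in% names(tab))) {
    stop("table must have columns ", paste(need, collapse = ", "))
  }
  metrics <- unique(tab$metric)
  do.call(rbind, lapply(metrics, function(m) {
    sub <- tab[tab$metric == m, ]
    avg <- eyeAveragedFromTable(sub)
    avg <- avg[order(avg$group), ]
    if (nrow(avg) != 2) stop("metric ", m, " does not have exactly two groups")
    d <- cohensD(avg$mean[1], avg$sd[1], avg$mean[2], avg$sd[2])
    n1 <- sampleSizeTTest(d, alpha = alpha, power = power)
    n2 <- NA_integer_
    if (!is.null(correlations) && m %in% correlations$metric) {
      r <- correlations$r[match(m, correlations$metric)]
      n2 <- sampleSizeRmAnova(d, r, alpha = alpha, power = power) %/% 2L
    }
    data.frame(metric = m, d = d, nOneEye = n1, nBothEyes = n2,
               row.names = NULL)
  }))
}
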