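# Shared fixtures, all generated in code.

leftParams <- function(...) acquisitionParams("left", ...)
rightParams <- function(...) acquisitionParams("right", ...)

# Hand-evaluated denominator of the BF equation (independent of the package
# implementation): 2 a T1b exp(-PLD/T1b) exp(-TE/T2b) lambda.
handDenominator <- function(pld, te = 0.009, alpha = 0.75, t1b = 1.8,
                            t2b = 0.035, lambda = 0.85) {
  2 * alpha * t1b * exp(-pld / t1b) * exp(-te / t2b) * lambda
}

# A depth profile from raw numbers at 7 um spacing.
profileFrom <- function(values, spacingMm = 0.007, startMm = spacingMm) {
  new("DepthProfile", values = values,
      depths = seq(startMm, by = spacingMm, length.out = length(values)),
      position = NA_real_)
}

# The default phantom truth and one noiseless degraded acquisition, computed
# once per test run.
phantomFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- eyePhantomSpec()
      truth <- makePhantom(spec)
      acq <- synthesizeAcquisition(truth, leftParams(), nReps = 1,
                                   noiseSd = 0, seed = 1)
      cache <<- list(spec = spec, truth = truth, acq = acq,
                     seeds = phantomSeeds(spec, c(205, 240, 300, 335)))
    }
    cache
  }
})

# Per-eye records with a known group offset, both eyes correlated within
# subject.
simulateEyeRecords <- function(nPerGroup, groupOffset = 0, eyeOffset = 0,
                               subjectSd = 1, residSd = 1) {
  n <- 2 * nPerGroup
  subj <- seq_len(n)
  grp <- rep(c("A", "B"), each = nPerGroup)
  u <- rnorm(n, 0, subjectSd)
  do.call(rbind, lapply(subj, function(i) {
    data.frame(
      subject = i, group = grp[i], eye = c("left", "right"),
      value = u[i] + (grp[i] == "B") * groupOffset +
        c(0, eyeOffset) + rnorm(2, 0, residSd)
    )
  }))
}

table3Path <- function() {
  system.file("extdata", "group_bf_summary.csv", package = "ocuflow")
}
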