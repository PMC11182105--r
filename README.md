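# ocuflow

Layer-specific retinal and choroidal blood flow from arterial spin
labeling (ASL) MRI of the posterior eye.

## What it does, and for whom

ASL MRI can measure absolute blood flow (BF) in the retina *and* the
choroid — the vascular layer hidden behind the retinal pigment epithelium
that optical methods cannot reach. The obstacle is scale: the mouse choroid
is ~25–45 µm thick while affordable acquisitions give ~42 µm pixels, so
conventional per-voxel ("peak") BF values are biased downward by partial
volume. `ocuflow` is for researchers quantifying ocular perfusion in small
animals (e.g. DBA/2J glaucoma models against C57BL/6J controls) who need
that bias understood and mitigated.

The package implements the full chain:

1. **Quantification** — single-compartment ASL model,

   `BF = 60 ΔM / (2 α T1B e^(−PLD/T1B) e^(−TE/T2B*) λa M0)`  (mL/mL/min),

   with ΔM the control-minus-label difference, M0 the vitreous water
   signal per profile, and defaults α = 0.75, T1B = 1.8 s, T2B* = 35 ms,
   λa = 0.85, TE = 9 ms, PLD = 325/381 ms (left/right eye), 42 µm pixels.
2. **Retina flattening** — semi-automated curve detection from seed
   points, resampling along normals at 6× depth interpolation, depth
   profiles with signed positions about the optic nerve head.
3. **Two layer metrics** — peak BF (mL/mL/min) per vascular layer, and
   depth-integrated BF per retinal surface area (µL/mm²/min), which is
   robust to partial volume because avascular tissue bounds both layers.
4. **Resolution simulation** — 1-D laminar profiles degraded by k-space
   truncation (10–250 µm) quantify how the peak metric collapses while the
   integrated metric stays within 10% of truth.
5. **Eye phantom** — synthetic 2-D acquisitions with known ground truth
   for end-to-end validation.
6. **Statistics** — eye-averaged Cohen's d (RMS pooling), exact
   noncentral-t and noncentral-F sample sizes, mixed models over both
   eyes, BF–IOP association.

## Worked example

Synthesise a noisy phantom acquisition (75 repetitions, ~1% noise on the
averaged difference) and run the full pipeline:

```r
library(ocuflow)
spec  <- eyePhantomSpec()                      # mouse eye, choroid 40 um @ 8 mL/mL/min
truth <- makePhantom(spec)
acq   <- synthesizeAcquisition(truth, acquisitionParams("left"),
                               nReps = 75, noiseSd = 0.06, seed = 7)
res   <- runBFPipeline(acq@series, phantomSeeds(spec, c(205, 240, 300, 335)))
round(averagedBF(res$measurement), 4)
#>  peakRetina peakChoroid   intRetina  intChoroid
#>      1.7570      6.6443      0.0958      0.3293
```

Read against the ground truth: the choroidal *peak* comes back as 6.64
against a true 8 mL/mL/min — a 17% partial-volume loss, because the 40 µm
choroid is thinner than the 42 µm pixel. The *integrated* choroidal BF
comes back as 0.329 against a true 8 × 0.040 = 0.320 µL/mm²/min — within
3%. Same data, same layers; the integral simply does not lose the signal
that blurring moves into the tails.

The resolution sweep makes the mechanism explicit (values normalised to
truth; `resolved = 0` means the two vascular layers have merged):

```r
evaluateMethods()[c(1, 4, 9, 10, 25), ]
#>    resolutionUm resolved peakRetina peakChoroid intRetina intChoroid intTotal
#> 1            10        1      1.130       1.122     1.013      0.995    0.999
#> 4            40        1      1.289       0.884     1.022      1.038    1.035
#> 9            90        1      0.334       0.423     0.451      1.272    1.083
#> 10          100        0         NA       0.393        NA         NA    0.968
#> 25          250        0         NA       0.215        NA         NA    0.922
```

The choroid peak falls from 1.12 to 0.22 of truth across the sweep; the
total integrated BF never leaves the 0.92–1.09 band.

Effect sizes and sample sizes from published per-eye group summaries
(means ± SD per eye, shipped as a transcribed CSV):

```r
tab  <- readGroupSummaryTable(system.file("extdata", "group_bf_summary.csv",
                                          package = "ocuflow"))
cors <- read.csv(system.file("extdata", "between_eye_correlations.csv",
                             package = "ocuflow"))
bfStatsReport(tab, cors)
#>               metric        d nOneEye nBothEyes
#> 1        retina_peak 1.325873      13        10
#> 2  retina_integrated 1.541493      10         9
#> 3       choroid_peak 1.971177       7         6
#> 4 choroid_integrated 2.074176       7         6
```

`d` is the eye-averaged Cohen's d; `nOneEye` is mice per group for 0.9
power with a single-eye t-test (exact noncentral-t); `nBothEyes` uses both
eyes with the between-eye correlation. The integrated metric yields larger
effects and smaller required samples than the peak metric for the same
underlying data.

A thin CLI wraps the same functions
(`inst/cli/ocuflow quantify|simulate-resolution|phantom|stats`).

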