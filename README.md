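# boldcvr

Cerebrovascular reactivity (CVR) mapping from BOLD fMRI, with a synthetic
test–retest cohort generator for validating every processing choice by
parameter recovery.

CVR quantifies how much the cerebral vasculature dilates in response to a
vasoactive stimulus — CO2 inhalation, breath-holding, or the spontaneous
CO2 fluctuations of rest — and is measured as the percent BOLD signal change
per unit change of a model regressor (end-tidal CO2 in mmHg, or the global
signal). The map one obtains depends heavily on processing choices: spatial
smoothing, temporal filtering, motion-confound regression, and voxel-wise
delay alignment interact in ways that can silently destroy test–retest
repeatability or manufacture artifacts such as "fake steal" (sign-inverted
CVR produced by regressor misalignment rather than by vascular physiology).
`boldcvr` implements the full processing chain, the repeatability metrics
used to evaluate it, and a ground-truth phantom cohort on which each
mechanism can be demonstrated and quantified. It is aimed at researchers
developing or auditing CVR pipelines.

## The model

For each voxel the conditioned, percent-signal-change-scaled BOLD series
`y(t)` is regressed on the prepared stimulus regressor `x(t)`:

    y(t) = beta0 + beta * x(t - delta) + gamma' c(t) + e(t)

* `beta` is the CVR estimate (%BOLD per mmHg ET-CO2, or %/% for a
  global-signal regressor);
* `delta` is an optional voxel-wise hemodynamic delay, chosen within a
  bound ±D as the lag maximizing the absolute Pearson correlation between
  `y` and the shifted regressor;
* `c(t)` are up to 24 motion confounds (6 rigid-body parameters, their
  backward-difference derivatives, and the squares of those 12), retained
  only when their absolute correlation with `x` is below a screening
  threshold.

Conditioning follows the order: EPI masking → Gaussian smoothing (FWHM in
mm) → 2× temporal upsampling → polynomial detrending → zero-phase low-pass
filtering → PSC scaling → ET-CO2 baseline subtraction and alignment to the
global signal (±15 s) → 15 s initial trim → voxel-wise delay alignment →
downsampling back to the acquisition rate → OLS. Maps are refined with a
median-absolute-deviation outlier filter (modified z > 10), optional
quality-quantile and delay-median filters, and optional tissue
normalization.

Test–retest repeatability is summarized spatially with the consistency
intraclass correlation for single measurements,

    ICC(C,1) = (MS_voxel - MS_error) / (MS_voxel + MS_error)

from a two-way decomposition with voxels as targets and sessions as
measurements, plus Fisher-z transforms, within/between-subject map
correlations ("differential correlation"), coefficient-of-variation and
scaled absolute-difference maps.

## Worked example

Generate a two-subject synthetic CO2-inhalation cohort (5-min runs at a
0.878 s repetition interval, 24×24×12 grid of 3 mm voxels, 1 Hz ET-CO2,
known ground truth), fit both sessions of the first subject with the
default configuration, and measure recovery and repeatability:

```r
library(boldcvr)

cohort <- generateCohort(2, paradigms = "CO2", seed = 1)
pair <- cohort$subjects$CO2[["sub-01"]]

fitTest <- fitRun(pair$test@bold, pipelineConfig(),
                  etco2 = pair$test@etco2, motion = pair$test@motion)
fitRetest <- fitRun(pair$retest@bold, pipelineConfig(),
                    etco2 = pair$retest@etco2, motion = pair$retest@motion)
fitTest
#> CVRResult sub-01 [CO2/test]: 2608/6912 valid voxels, regressor = etco2
#>   CVR median 0.2863, delay range [0, 0] s

truth <- groundTruth(pair$test)
gm <- validMask(fitTest) & tissueLabels(truth) == 1
sprintf("GM mean CVR: estimated %.3f, truth %.3f %%BOLD/mmHg",
        mean(cvrMap(fitTest)[gm]), mean(cvrMap(truth)[gm]))
#> "GM mean CVR: estimated 0.290, truth 0.298 %BOLD/mmHg"

common <- validMask(fitTest) & validMask(fitRetest)
icc <- iccC1(cvrMap(fitTest)[common], cvrMap(fitRetest)[common])
sprintf("spatial ICC(C,1) test vs retest: %.3f (Fisher z %.2f)", icc, fisherZ(icc))
#> "spatial ICC(C,1) test vs retest: 0.991 (Fisher z 2.68)"
```

The median CVR of 0.29 %BOLD/mmHg sits between the generator's gray-matter
(0.30) and white-matter (0.10) means, the gray-matter mean is recovered
within ~3% (the default 5 mm smoothing mixes a little white matter into the
gray-matter average), and the near-noise-free default cohort is highly
repeatable. Experiment drivers (`univariateSweep`, `interactionGrid`,
`optimizedPerturbation`, `smoothingTradeoff`, `fakeStealAnalysis`) run the
same machinery across parameter levels and cohorts; the methods vignette
(`vignettes/boldcvr-methods.Rmd`) explains the science and every default.

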