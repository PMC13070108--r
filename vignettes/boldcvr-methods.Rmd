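---
title: "Methods: CVR estimation, repeatability metrics, and the synthetic cohort"
author: "boldcvr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CVR estimation, repeatability metrics, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`boldcvr` estimates cerebrovascular reactivity (CVR) from BOLD fMRI runs
acquired under three vascular paradigms — fixed CO2 inhalation, breath-hold
(BH), and resting state (RS) — and quantifies how processing choices affect
the test–retest repeatability of the resulting maps. Because real
acquisitions have no accessible ground truth, the package ships a
synthetic-cohort generator whose latent maps (reactivity amplitude,
hemodynamic delay, drift, motion coupling, noise) are recorded, so the
whole chain can be validated by parameter recovery.

# The estimation model

Each voxel's signal is modeled as an affine response to a stimulus
regressor plus nuisance terms:

$$ y(t) = \beta_0 + \beta\, x(t-\delta) + \gamma^\top c(t) + \varepsilon(t). $$

`beta` is the CVR estimate in percent BOLD per regressor unit. With the
end-tidal CO2 (ET-CO2) regressor the unit is %/mmHg and physiologically
interpretable; with the global-signal regressor (the default choice for RS,
where no controlled stimulus exists) the estimate is unitless (%/%) and
describes covariation with the whole-brain signal rather than an absolute
vascular gain. The result object records which regressor produced it.

Assumptions worth stating explicitly:

* the response is linear in the regressor and instantaneous once the
  voxel-wise delay is removed — no hemodynamic response function is fitted
  (deliberately out of scope);
* noise is independent across time after low-pass filtering, which OLS
  requires only for its standard errors, not for unbiasedness;
* motion enters additively through the 24-term confound expansion, not as
  geometric displacement (motion correction is assumed done upstream).

## Processing order

`fitRun()` fixes the stage order:

mask → spatial smoothing → temporal upsampling → polynomial detrending →
low-pass filtering → PSC scaling → regressor preparation → 15 s trim →
voxel-wise delay alignment → downsampling to the acquisition rate →
confound screening → OLS → refinement filters.

Delay alignment happens on the upsampled grid (half the repetition
interval by default) so that sub-TR delays are representable; the series
are then downsampled back to the acquisition rate before fitting, and the
first retained sample is aligned to the acquisition grid so that
downsampling returns true frames rather than interpolated midpoints. The
15 s steady-state trim is applied once, after alignment, to every model
series (BOLD, regressor, confounds) so the design matrix stays coherent.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `fwhm_mm` | 5 | mm | Gaussian smoothing kernel; 0 disables. |
| `detrend_order` | 1 | – | polynomial degree 0–3; 0 disables. |
| `lowpass_mhz` | 116.4 | mHz | zero-phase Butterworth cutoff; `Inf` disables. |
| `upsample_factor` | 2 | – | temporal upsampling 1–4. |
| `baseline_strategy` | overall_mean | – | PSC baseline; `initial_window` uses the first `trim_initial_s` seconds. |
| `regressor_kind` | etco2 | – | `etco2` or `global_signal`. |
| `max_delay_s` | 0 | s | voxel-wise delay bound; 0 = no alignment, `Inf` = unbounded. |
| `confound_corr_threshold` | 0 | – | strict screening bound; 0 retains no confounds, 1 retains all with \|r\| < 1. |
| `mad_z_threshold` | 10 | – | modified-z outlier exclusion (≈ 10 SD under normality). |
| `quality_metric`, `quality_quantile` | none, 0.10 | – | optional removal of the lowest-metric fraction (R², t-value, tSNR, or a supplied covariate volume). |
| `normalization` | none | – | rescale CVR to a GM/WM/CSF/WB reference mean. |
| `tissue_restrict` | WB | – | restrict the analysis mask to one tissue. |
| `mask_kind` | epi | – | intensity-heuristic EPI mask or a provided mask. |
| `trim_initial_s` | 15 | s | initial steady-state discard. |
| `delay_median_filter` | FALSE | – | 3×3×3 median filter on delays, then re-fit. |

## Numerical choices

* **Low-pass filter**: order-5 Butterworth coefficients, applied
  forward–backward (zero phase). Odd end-reflection plus steady-state
  initial conditions make constants pass exactly (DC gain 1, no startup
  transient). Idempotence holds for in-band content away from the padded
  edges; the edge transient is a property of any finite-length zero-phase
  recursive filter.
* **Delay search**: exhaustive integer lags on the upsampled grid,
  maximizing \|Pearson r\| on the overlapping support (≥ 10 samples per
  candidate lag). Ties break toward the smallest absolute lag, then toward
  positive lag, minimizing artifactual shifts. Positive delay means the
  regressor moves later in time. Voxel delays are relative to the
  GS-aligned regressor; the recorded `regressorShift` converts them back to
  absolute delays.
* **Rank deficiency**: pivoted QR drops collinear confound columns; if the
  regressor column itself is eliminated the voxel is invalid.
* **PSC baseline**: the temporal mean of the acquisition-rate frames. A
  non-positive baseline flags the voxel invalid rather than erroring, so a
  single bad voxel cannot abort a run.
* **MAD filter**: modified z with the 1.4826 consistency constant; a zero
  MAD (constant map) excludes nothing and is logged.
* **Quantile filter**: strictly-below-threshold exclusion, ties kept; a
  second pass removes ~q of the remainder because the quantile is
  recomputed.
* **EPI mask**: voxels whose temporal mean exceeds the 2nd percentile plus
  20% of the 2–98 percentile span, then the largest 6-connected component.
* **Autocorrelation first minimum**: first sign change of the discrete
  derivative from − to +, or a plateau (\|Δacf\| < 0.005 per lag for ≥ 3
  lags) *after* a real descent — without the descent condition the flat
  top of a smooth autocorrelation triggers a spurious minimum at lag 0.
* **Spectra**: mean-removed, zero-padded to 4096 s so protocol peaks
  localize off the coarse 1/300 Hz grid, normalized to the maximum.
* **ICC(C,1)**: explicit two-way sums of squares; zero target variance
  returns NA. Fisher z clamps \|r\| ≥ 1 to 1 − 1e−12 with a warning.

# The synthetic cohort

`generateCohort()` draws test–retest pairs on a nested-ellipsoid phantom
(GM shell, deep WM core, central CSF "ventricles") in a 24×24×12 grid of
3 mm voxels — small enough for desk-scale sweeps, large enough for
smoothing kernels up to 9 mm. Each run spans 300 s at a 0.878 s repetition
interval; ET-CO2 is emitted at 1 Hz.

The voxel signal is

$$ s(t) = b\,\bigl(1 + \tfrac{\mathrm{cvr}}{100}\,\tilde x(t-\delta)
   + d(t) + w^\top m(t)\bigr) + \eta(t), $$

with `b` the tissue baseline intensity (GM 1000, WM 900, CSF 700),
`cvr` the per-voxel amplitude (tissue means GM 0.30, WM 0.10,
CSF 0.05 %/mmHg with 10% smooth spatial jitter), `x̃` the mean-centred
ET-CO2 excursion evaluated at delayed frame times (tissue-mean delays GM
1 s, WM 4 s, CSF 2 s plus 1 s smooth jitter), `d` a random linear/quadratic
drift (0.5% scale), `m` the six motion traces (integrated white noise
scaled to paradigm-typical mean framewise displacement: CO2 0.12, BH 0.14,
RS 0.11 mm) mixed through per-voxel couplings, and `η` white noise
(default SD 10 raw units, i.e. tSNR ≈ 100 in GM). The retest run re-draws
noise and motion and scales amplitudes by 0.95, emulating the small
test-to-retest CVR decrease. The excursion is mean-centred so that the
baseline intensity equals the temporal mean of the signal — the same
overall-mean convention the PSC stage uses — which is what makes noiseless
runs exact fixed points of the pipeline.

Regressor construction: the CO2 protocol (30 s baseline, two 60 s stimulus
blocks each followed by 75 s of room air) is a boxcar; BH (60 s paced
breathing, three 15 s end-expiratory holds separated by 45 s paced
breathing, closing 60 s paced) uses a linear ET-CO2 rise over each hold
with exponential return (time constant 6 s — end-tidal CO2 renormalizes
within one to two paced breaths, and a slower return would bury the
1/60 Hz hold-cycle component under the run envelope); RS is a smoothed
random walk plus a respiratory oscillation with cycle length drawn in
5–8 s. CO2 and BH traces are smoothed by a causal single-exponential
response kernel (time constant 8 s), a minimal stand-in for
neurovascular dynamics; the ET-CO2 stimulus amplitude has no claimed
physiological default and is a parameter (8 mmHg under 5% CO2, 5 mmHg per
hold, 2 mmHg resting fluctuation).

What the generator does **not** emulate: realistic anatomy, field
inhomogeneity and susceptibility distortion, cardiac/respiratory aliasing,
geometric motion displacement, k-space physics, and any hemodynamic
response shape beyond the single-exponential kernel. Passing tests
therefore demonstrate the correctness and internal mechanics of the
processing chain, not its behaviour on real scanner data.

# Experiment designs

* `univariateSweep()` varies one parameter with the others at their
  defaults and reports per-subject spatial ICC(C,1) with Fisher z.
* `interactionGrid()` crosses detrend order × low-pass cutoff × confound
  threshold (the three interacting stages) and emits the long-format table
  an external repeated-measures analysis would consume; the package
  deliberately does not compute that inference.
* `optimizedPerturbation()` fixes two parameters at the empirically best
  cell (ties broken toward the defaults, logged) and reports each
  parameter's curve; a reference-map variant swaps ICC for correlation
  with a designated reference result.
* `smoothingTradeoff()` tracks within-subject correlation, differential
  correlation (within − between, a subject-identifiability index) and
  tissue means of the group-average map across smoothing levels.
* `fakeStealAnalysis()` classifies common valid voxels of a delay-aligned
  test–retest pair: sign-flipped voxels with similar amplitude
  (\|\,\|a\|−\|b\|\,\|/max < 0.5, a configurable tolerance) are
  "anti-correlated"; the analysis reports their fraction, the 2 s-binned
  histogram and mode of absolute delay differences, and the
  regressor–BOLD correlation distributions per class.

## Problem sizes

The shipped tests and the acceptance script run on the default 24×24×12
grid with 2–4 subjects per cohort and four smoothing or cutoff levels per
sweep; unit tests of the experiment drivers use a 12×12×8 grid. These
sizes were chosen as the smallest at which the spatial metrics (ICC over
~2600 brain voxels, tissue means, connected components) are stable.

# Design choices that were genuinely open

* **Confound screening strictness**: "below the threshold" is read as a
  strict inequality, so threshold 0 retains nothing and threshold 1
  retains everything short of exact collinearity — matching both stated
  endpoints.
* **Derivative convention**: backward differences with a leading zero,
  the convention of standard fMRI confound tables.
* **Delay search grid**: the upsampled grid, since alignment precedes the
  documented downsampling step.
* **MAD filtering scope**: per-run maps (pooling across a cohort would let
  one bad run shift every threshold).
* **Between-subject correlation pairs**: all ordered cross-subject pairs
  over all four session combinations, the most symmetric reading of
  "all pairs of subjects".
* **15 s discard scope**: applied on the common fine grid after alignment,
  to BOLD, regressor and confounds alike.
* **ET-CO2/motion sidecars**: separate TSV files per run because the two
  sampling rates (1 Hz vs the repetition interval) cannot share rows.

# Known limitations

* The delay-difference clustering among anti-correlated ("fake steal")
  voxels is blurred relative to what a sharp, breath-sampled regressor
  would give: with the 8 s response kernel inside the regressor (required
  for exact noiseless identifiability), the regressor autocorrelation peak
  is flat over ±4–5 s, so delay locks jitter by that much and the
  histogram mass spreads over roughly 11–19 s around a ±15 s bound.
* The delay median filter removes essentially all *alignment-induced*
  sign flips (the post-filter fraction matches the fraction observed with
  alignment disabled), but the unconditional anti-correlated fraction
  retains a noise floor from low-amplitude deep-WM voxels whose fitted
  sign flips between sessions regardless of alignment.
* ICC(C,1) is a consistency coefficient: it ignores constant session
  offsets by construction, so a global amplitude drift between sessions is
  invisible to it (the scaled absolute-difference map is the complementary
  metric).
* The EPI-mask heuristic assumes background ≈ 0, which holds for the
  phantom and for skull-stripped normalized data but not for raw scanner
  images.
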