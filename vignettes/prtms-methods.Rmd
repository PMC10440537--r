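---
title: "EEG alpha-band biomarkers and personalized rTMS planning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG alpha-band biomarkers and personalized rTMS planning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prtms)
```

## Scope and model

`prtms` implements a resting-EEG spectral-biomarker pipeline for
EEG-guided personalized repetitive transcranial magnetic stimulation
(PrTMS) in PTSD, together with the cohort statistics used to evaluate such
a treatment course and a synthetic-cohort generator that makes every stage
testable without patient data.

The spectral model underlying both analysis and simulation is the standard
decomposition of the resting power spectrum into an aperiodic 1/f
background and a periodic alpha-band peak:

$$S(f) = 10^{o}\, f^{-e} \;+\; A\, e^{-(f - c)^2 / 2\sigma^2},
  \qquad f \in [2, 20]\ \mathrm{Hz},$$

with offset $o$ (log10 power at 1 Hz), exponent $e$ (the fitted log–log
slope is $-e$), and an alpha peak with center $c \in [8, 13]$ Hz, amplitude
$A$ (µV²/Hz above background) and Gaussian width $\sigma$
(FWHM $= 2\sqrt{2\ln 2}\,\sigma \approx 2.355\,\sigma$).

## The montage and its four regions

Analysis uses the 19-lead 10–20 montage partitioned into frontal (7
leads: Fp1, Fp2, F7, F3, Fz, F4, F8), central (T3, C3, Cz, C4, T4),
parietal (P3, Pz, P4) and occipital (T5, T6, O1, O2). The published
region descriptions give only endpoint pairs ("Fp1 to F8", "Cz to T4",
"Pz to P4", "P7 to O2"), which cannot all be literal contiguous 10–20
ranges: a literal "P7 to O2" would swallow the parietal row. The partition
above is the unique exhaustive reading consistent with every stated
endpoint and with the frontal region containing exactly 7 leads; the
modern temporal labels (T7/T8/P7/P8) are accepted as synonyms of
T3/T4/T5/T6 on input.

## Spectral estimation

`welch_psd()` computes an averaged modified periodogram: Hann taper,
10-second segments, 50% overlap. Ten seconds is the minimum segment
yielding the required 0.1 Hz native resolution; taper and overlap are
conventional choices, exposed as arguments, since only the resolution and
the 2–20 Hz band restriction are fixed requirements. When the native bin
grid does not land exactly on the 0.1 Hz analysis grid the periodogram is
linearly interpolated onto it. Segments whose amplitude exceeds a clip
threshold (default 200 µV) on any lead are dropped whole — a deterministic
stand-in for manual inspection of artifactual stretches — and no filtering
is applied anywhere.

`alpha_peak()` takes the 8–13 Hz grid argmax (ties broken toward the lower
frequency), refined by three-point parabolic interpolation. Sub-bin
refinement matters because the clinically interesting shifts are fractions
of a hertz. A band with no interior maximum is flagged `low_prominence`.

`alpha_fwhm()` measures the width between the two half-maximum crossings,
each located by linear interpolation between grid points. When an
aperiodic fit is supplied, the half-maximum is taken on peak height above
that 1/f baseline; the raw half-maximum of a small peak sits mostly in the
background and badly overestimates the width. Whether the original
analysis baselined its FWHM is not stated; both routes are available, with
the baselined one used by the pipeline. A crossing falling outside the
band returns `NA` (band-clipped) rather than a fabricated width.

## The aperiodic fit

`fit_aperiodic()` fits log10 power against log10 frequency over all 181
bins by iteratively reweighted least squares with a Tukey bisquare loss
(tuning constant 4.685) and an MAD residual scale re-estimated every
iteration. Bisquare fully rejects gross outliers, which is exactly the
behaviour wanted here: the oscillatory alpha bins are outliers with
respect to the aperiodic line and end up with zero weight, so the fitted
slope reflects the background alone. The published analysis states only
"robust regression"; the bisquare variant, the convergence rule (weight
change < 1e-8 or 100 iterations, with a short-circuit when the fit is
numerically exact) and the straight-line form (no knee) are declared
choices. An OLS method is provided as the non-robust baseline, and the
test suite checks both against a masked-band oracle (OLS with the alpha
band removed) and against an independent M-estimator.

One calibration note: the robust-versus-OLS superiority property is tested
at multiplicative log-normal spectral noise of σ = 0.02. At σ = 0.05 —
the level used for the slope-recovery simulations — sampling luck alone
lets plain OLS beat even the masked-band oracle in several percent of
realizations, so a win-rate criterion there would measure noise, not
outlier resistance. The recovery simulations themselves stay at σ = 0.05.

## Treatment planning

The planner implements the disclosed rule set. The intrinsic alpha
frequency is the amplitude-weighted mean of the occipital-lead centers
(visual cortex is taken as the preserved reference), clamped to 8–13 Hz.
Leads deviating from it by more than 0.5 Hz are targeted, all at the
intrinsic frequency; occipital leads are never targeted because they
define the reference. The 0.5 Hz default (five grid bins, above
peak-localization error) quantifies a deviation criterion the source
leaves qualitative, and is configurable. The session schedule ramps
intensity linearly 25→60% of resting motor threshold and the inter-train
interval 30→10 s across the planned weeks, with 12 s trains (midpoint of
the 10–15 s protocol range) and ~40 min sessions. Weekly updates recompute
intrinsic frequency and targets from the new EEG; a PCL-5 worsening of
more than 5 points holds the ramp for one week — the one concrete reading
we adopt of "adjusted by clinical response", isolated so alternatives can
be substituted. A published intensity range of 20–60% of machine power
appears alongside the 25–60% motor-threshold range; the motor-threshold
figures are used.

## Psychometrics and statistics

PCL-5 totals are sums of 20 items scored 0–4; screening positivity is
total ≥ 33. Responders drop strictly more than 5 points from baseline to
final, clinically meaningful responses strictly more than 10; the strict
inequalities follow the figure conventions (">5" / "≤5") where the text is
ambiguous. HAM-A/HAM-D are banded at the published cutpoints; a total of
exactly 24 falls in a gap between "15–23"/"17–23" and "greater than 24"
and is assigned to the severe band.

The group statistics are implemented from their definitions — CFB t-tests
(`t = \bar{x}/(s/\sqrt{n})`), paired t-tests on differences, a binned sign
test (0.5 Hz bins anchored at 8 Hz, ties dropped, exact two-sided binomial
p), a two-way mixed repeated-measures ANOVA from explicit sums of squares
(between = group, within = week, listwise deletion, no sphericity
correction; the exact design used originally is unstated), strict
threshold-exceedance proportions, and a Fisher exact test by
hypergeometric enumeration — each cross-checked in the tests against the
corresponding base-R routine. No multiple-testing correction is applied
anywhere, matching the source analysis; interpret families of p-values
accordingly. The prior-study comparison proportions (47.9/31.9% at >5
points, 33.8/27.5% at >10) enter only as fixed printed constants.

## The synthetic cohort

The generator's defaults are the study conditions, not tuning knobs:

* **Baseline PCL-5**: normal, doubly truncated to [33, 80], with the
  underlying mean/SD calibrated numerically so the post-truncation moments
  are 53.3 and 11.46. Totals are rounded to integers.
* **Groups**: responders with probability 0.85. Responder final drops are
  drawn from a truncated normal centred at 35.6 points (bounded below at
  6), so the responder week-4 mean lands near the published 17.7;
  nonresponder drops centre at 1 point, bounded above at 5. A shared
  baseline distribution cannot simultaneously reproduce the published
  47.2-point nonresponder week-4 mean — that figure describes a week-4
  score split (>32), not the drop-based group — so the drop-based
  definition wins.
* **Score dynamics**: weekly total = baseline − drop × ramp(week), the
  ramp rising linearly to a plateau at week 4, plus integer-rounded
  observation noise (SD 1.5 points, a modest test–retest jitter).
* **Spectral dynamics** (per lead, linearly interpolated week 0 → 6):
  responders start with centers ~0.9 Hz above their intrinsic frequency
  (occipital leads stay at it) and converge fully by week 6; width narrows
  σ 1.0 → 0.6 Hz; exponent steepens 0.61 → 0.95; the alpha peak grows 4 →
  18 µV²/Hz. The amplitude endpoint is deliberately large: with the
  exponent steepening, background power in 8–13 Hz falls by more than a
  modest peak rise could offset, and the band-mean amplitude is required
  to rise — a sharper and substantially stronger peak is the only
  parameterization consistent with all three reported directions.
  Nonresponders keep their deviations and width, and their exponent
  flattens 0.73 → 0.34.
* **Intrinsic frequency**: N(9.6, 0.2²) Hz, the post-treatment responder
  region average.
* **Dropout**: every subject completes the 4-week analysis window; a 0.31
  probability mass leaves right after week 5 (≈27 treatments) and the
  remainder leave with a geometric hazard of 0.119/week, reaching 92% by
  week 22. A single geometric rate cannot hit both published attrition
  points, hence the two-phase form; the attrition acceptance checks use
  the printed counts, not this simulator.

Signal realization is separate from parameter generation. Spectra are
realized directly on the analysis grid with multiplicative log-normal
noise (σ = 0.05), mimicking Welch sampling variability; time series are
realized by inverse-FFT spectral shaping — the target PSD imposed on the
DFT amplitudes with uniformly random phases — which gives exact control of
the expected spectrum the estimators must recover. All randomness flows
from one seed through a per-subject/per-week stream splitter, so extending
a cohort never perturbs existing subjects. The generator emulates
spectral shape and symptom trajectories only: there is no volume
conduction, no inter-lead correlation, no non-stationarity, and no
realistic artifact structure beyond optional amplitude clips — so passing
tests demonstrate estimator correctness under the assumed model, not
performance on real recordings.

## Numerical choices and degenerate inputs

Zero-variance t-tests error rather than return NaN; an all-tie sign test
returns p = 1 with a flag; a zero-margin Fisher table returns p = 1 with a
flag; a single-subject summary row reports SD 0 with `sd_undefined`;
spectra with non-positive bins refuse the log-log fit; a robust fit that
rejects more than half its bins warns. Peak ties break toward the lower
frequency, deterministically. The problem sizes used by the test suite
(50-seed recovery runs, 20-cohort direction checks at n = 50, a 10,000
subject calibration draw) were chosen to keep Monte-Carlo error well below
each asserted tolerance.

## Known limitations

The proprietary frequency-selection algorithm used clinically is not
public; only the disclosed deviation/intrinsic-frequency rule is
implemented, and the score-based ramp hold is one conservative reading of
a qualitatively described feedback loop. The aperiodic model is a straight
line in log-log space (no knee), adequate over 2–20 Hz but not beyond.
Responder/nonresponder labels in reports derive from observed scores, so
simulated subjects near the 5-point boundary can be classified against
their generating group — as real subjects would be.
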