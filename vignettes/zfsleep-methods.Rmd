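---
title: "Methods: sleep scoring, arousal psychometrics and calcium-trial analysis in zfsleep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sleep scoring, arousal psychometrics and calcium-trial analysis in zfsleep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zfsleep)
```

# Scope and models

zfsleep quantifies sleep and arousal in larval zebrafish from three kinds of
data: per-minute videotracker activity, mechano-acoustic tap-response trials,
and trial-structured calcium-imaging fluorescence. Every analysis stage is
paired with a synthetic-data generator holding known ground truth, so the
full pipeline is testable without recordings. This vignette explains the
models, the tunable parameters, the numerical choices, and what the
synthetic data do and do not establish about real recordings.

## Sleep scoring

The operational definitions are the standard larval-zebrafish ones:

* a **movement** in high-rate (15 Hz) displacement data is a maximal run of
  nonzero pixel displacement flanked by at least 67 ms of stillness
  (`detect_movement_events()`). At 15 Hz one still frame spans 66.7 ms,
  which does *not* reach 67 ms, so a single still frame never separates two
  events while two still frames (133 ms) always do. This boundary case is
  resolved explicitly because the frame interval and the stillness
  criterion are numerically adjacent.
* a **sleep minute** is a 1-min bin with no movement (`score_sleep()`);
  numerically, activity at or below `zero_tol = 1e-9` s, i.e. exact zero up
  to float noise.
* a **sleep bout** is a maximal run of sleep minutes (`extract_bouts()`),
  and **latency** is the time from a reference (lights on/off, heat shock)
  to the first bout at or after it (`sleep_latency()`). A bout ongoing at
  the reference gives latency 0. When no bout occurs before the epoch ends,
  the latency is reported as the epoch length and flagged censored rather
  than dropped; dropping non-sleepers would bias group means toward short
  latencies.
* **average activity** (s/h) includes sleep minutes; **wake activity**
  excludes them, so wake activity is never below average activity and they
  are equal only when the epoch holds no sleep.

Bouts spanning a lights transition are split at the boundary for per-epoch
totals and counted once in each epoch they touch (`epoch_metrics()`);
splitting is the only convention that conserves total sleep across epochs.
Minute bins are anchored to the recording start, and lights events snap to
bin boundaries.

For trend plots, `smooth_series()` applies a 1-h (6-point) centered moving
mean on a 10-min grid. A 6-point window has no exact center; it spans
offsets −3..+2 bins, and edges shrink to the available points rather than
padding.

`light_pulse_response()` follows the optogenetic-assay convention: activity
in 10-s bins, the minute before and after light onset excluded, the 30-min
pulse total divided by the group-mean 30-min baseline total (both windows
effectively 29 min, so identical activity gives exactly 1), and everything
after pulse offset excluded.

## Arousal-threshold psychometrics

Tap-response data are reduced to per-power response fractions
(`response_table()`); the group's background movement probability — the
fraction of trials with movement in the 5 s before the stimulus — is
subtracted and the result clamped at 0 (`background_probability()`,
`adjust_fractions()`), since fractions are probabilities.

`fit_psychometric()` fits the variable-slope log-dose model

$$y(P) = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}
{1 + 10^{(\log_{10}\mathrm{ETP_{50}} - \log_{10} P)\cdot h}}$$

by bounded least squares (Levenberg–Marquardt via minpack.lm, with
$0 \le \mathrm{bottom}$, $\mathrm{top} \le 1$ and the Hill slope $h$
unconstrained in sign). Initialization is data-driven (bottom = min y,
top = max y, midpoint log-power, $h = 1$) plus eight deterministic jittered
restarts; the lowest residual sum of squares wins, ties to the first found.
The restarts use a fixed offset table rather than random draws so that
fitting never touches the caller's random-number stream. Constant response
fractions are returned as a flagged degenerate fit (no threshold exists).
ETP50 — the half-maximal tap power, the arousal-threshold readout — is
$10^{\log_{10}\mathrm{ETP_{50}}}$ (`etp50()`); by construction the fitted
curve evaluated there is the bottom/top midpoint.

Fits default to *unweighted* least squares on per-power mean fractions,
mirroring the common desktop workflow. A binomial weighting option
(`weighting = "binomial"` in `compare_fits_extra_ss()`) divides each
point's squared residual by its shrunken binomial variance
$\hat p(1-\hat p)/n$; the Jeffreys-style shrinkage $(x + 0.5)/(n + 1)$
keeps weights finite when a fraction is exactly 0 or 1.

Group differences in ETP50 are tested by the extra sum-of-squares F test:
the null model shares all four parameters across both groups; the
alternative shares bottom, top and hill but frees $\log_{10}\mathrm{ETP_{50}}$
per group, so the numerator has 1 degree of freedom and the denominator
$n - 5$. Because both models are fitted numerically, the null is re-polished
from the alternative's solution before computing F, so a nested model can
never appear worse than its own special case through a convergence artifact.

Two calibration facts matter when the fractions come from many Bernoulli
trials:

* with asymptotes well inside (0, 1) — which is what background movement
  and non-saturating taps produce in practice — the binomially weighted F
  test holds its 5% level and yields uniform null p-values;
* with the true bottom at 0 and top at 1, extreme-power fractions have
  collapsing variance and parameter estimates pin at the bounds; the F test
  is then anticonservative regardless of weighting. This is a property of
  the classical test, and users comparing saturated curves should prefer
  the weighted form and treat borderline p-values with caution.

`percent_change()` reports $100(\mathrm{treated}-\mathrm{ref})/\mathrm{ref}$
with the fractional part truncated toward zero — the convention that
reproduces standard reported caption arithmetic (e.g. 20.3 vs 6.2 → +227).

## Calcium-trial analysis

Trials are 2 min of fluorescence at 1 Hz (120 samples, $t = 0..119$ s):
intrinsic activity for the first 31 s, a perturbing light on at 32 s and
off at 93 s. Phase-window statistics (`trial_window_means()`) average the
5–25, 32–37 and 93–98 s windows — intrinsic, on-evoked, off-evoked — with
inclusive integer-second boundaries (so 5–25 s holds 21 samples); the
open/closed choice is stated and tested because it is otherwise ambiguous.

Baselines (`delta_f()`): `global_min` (lowest signal of the whole
recording, so $\min \Delta F = 0$), `first5_mean` (mean of the first five
trials, for stimulation sessions), and `smoothed_min_5s` (minimum of the
5-s boxcar-smoothed trace, the per-neuron convention). Normalizations
(`normalize_trace()`) divide by the subjective-day intrinsic mean, the
per-animal post-light peak (`post_light_peak()`, making that peak exactly
1), or the per-animal day mean (making the day value exactly 1 in
`day_night_activity()`, whose day level is the mean of the two day periods
flanking the night). Per-trial series are smoothed over a 5-trial centered
window (`sliding_trial_smooth()`), and the post-stimulation steady state is
the mean of trials 10–15 (`steady_state()`).

`segment_neurons()` implements PCA/ICA segmentation: per-pixel mean
centering (which makes the output invariant to constant intensity offsets),
truncated SVD to `n_pcs` components (default 15; an explained-variance
target can override the count — the default aims at the ~75% variance
regime typical of these movies), then FastICA (`ica::icafast`) on the
component spatial maps. Each independent filter is sign-aligned to positive
skewness — genuine cells are sparse bright structures, noise components are
symmetric — z-scored robustly (median/MAD), thresholded at $z > 3$, and its
connected components refined to their half-maximum support, so a Gaussian
nucleus yields a filter whose diameter is its FWHM. Components whose
equivalent diameter falls outside $[0.5, 2]\times$ the nominal cell
diameter (default 5 px, the pixel stand-in for ~5 µm nuclei) are rejected,
which suppresses skin-autofluorescence-like false positives; near-duplicate
masks from different components (Jaccard > 0.5) are merged. ROI traces are
mask means per frame with the smoothed-min baseline. Retaining components
by an explained-variance rule replaces the visual inspection a human
analyst would use; that substitution is deliberate and is the main known
divergence from interactive practice. Per-neuron averages weight neurons
equally (not by size).

## Statistics

Standard machinery is called, not re-derived: `t_test()` wraps the pooled
(Student) form of `stats::t.test` — matching the named test; Welch's form is
an option — with the convention that zero-variance, equal-mean input gives
$p = 1$; `anova_test()` uses `stats::aov`, with a warning and Type-II sums
of squares for unbalanced two-way designs (96-well experiments are normally
balanced). `holm_sidak()` is the closed-form step-down Šidák adjustment.
`dunnett()` computes many-to-one comparisons with the familywise adjustment
evaluated from the exact equicorrelated multivariate-t distribution
(`mvtnorm::pmvt`); a Monte-Carlo evaluation of the max-|t| null was
considered and rejected because the exact computation is available and
faster at equal accuracy. `ddct()` implements relative qPCR quantification
with the calibrator taken per target gene as the sample with the highest
target Ct (lowest expression = 1.0), so the calibrator's relative
expression is exactly 1.

# The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions the analyses are validated against.

**Behavior.** Each larva is a two-state (wake/sleep) first-order Markov
chain on 1-min bins with epoch-specific transition probabilities.
Defaults: 48 larvae per group on a 14:10 LD schedule (lights on 09:00);
day $p_{w\to s} = 0.02$, $p_{s\to w} = 0.35$ (stationary sleep fraction
~5%, short fragmented daytime naps); night $p_{w\to s} = p_{s\to w} = 0.12$
(~50% of night minutes asleep, mean bout $1/p_{s\to w} \approx 8$ min) —
values a larval sleep lab would call typical. Wake-minute activity is
gamma-distributed (shape 1.5, scale 4 s; positive and right-skewed like
real actigraphy) clamped to [0, 60] s and scaled by a per-group activity
multiplier. Sleep minutes are exactly 0. Heat shock multiplies both
transition probabilities by factors that decay geometrically from onset
with a configurable half-life, emulating transient transgene
overexpression; a per-group `latency_shift` suppresses sleep entry for its
duration after each lights transition, shifting expected latency by that
amount (attenuated by the fraction of larvae already asleep at the
reference). Sleep-bout lengths are geometric with mean $1/p_{s\to w}$ by
construction, which the test suite verifies by chi-square goodness of fit.

**Taps.** For each larva × power × trial the response is Bernoulli with
probability $\psi(P) + b(1-\psi(P))$ — the psychometric curve OR-combined
with background movement $b$, consistent with subtracting background from
response fractions downstream. Defaults: 14 powers log-spaced over 1–36.31
on the 0.01–40.95 solenoid scale, 30 trials per power (420 per larva),
bottom 0, top 1, ETP50 6.2, Hill 1.8, background 0.07. Presentation order
is randomized per larva.

**Calcium.** Trials are built from a phase baseline (day 1.0, night 0.75 —
a 25% night decrease, the suppressed-night regime), plus on/off evoked
transients: exponentials (τ = 3 s) truncated at the next light switch and
normalized so the kernel's mean over its 6-sample evoked window is exactly
1 — a configured amplitude therefore raises that window's mean by exactly
the amplitude in the noiseless limit, making the generator its own exact
oracle. The optogenetic mode applies, after trial 5, an initial transient
followed by decay toward `suppression_target` (default 0.32, i.e. a 68%
steady-state reduction). Movies plant Gaussian-blob nuclei (FWHM 5 px) at
non-overlapping positions with independent spike-convolution traces (every
planted "active neuron" is guaranteed at least three events, since a cell
with no temporal variance is invisible to any activity-based segmentation),
over constant background with Gaussian noise.

**Reproducibility.** All randomness comes from base R's Mersenne-Twister.
Per-larva (and per-trial, per-movie) seeds are the first $n$ draws of a
stream seeded from the master seed and a module label, so a fixed seed
reproduces datasets exactly and enlarging a cohort never perturbs existing
larvae.

**What passing tests do and do not show.** The generator emulates the
*structure* of the study's data — epoch-dependent sleep architecture,
background-contaminated psychometric responses, trial-locked transients,
blob-shaped active nuclei — under exactly the distributional assumptions
the scoring rules invert. Recovery of planted effects therefore validates
the pipeline's correctness, not the biology: real recordings have
non-Markov bout structure, circadian drift within epochs, correlated
background movement, motion artifacts and autofluorescence that the
generator does not model, so quantitative agreement on synthetic cohorts
does not by itself guarantee the same accuracy on tracker exports.

# Problem sizes and numerical notes

The validation suite runs at deliberately moderate sizes chosen to give
tight statistical checks at interactive runtimes: ~10^5-minute traces for
oracle equivalence and goodness of fit, 48 larvae/group for round-trip
recovery, 200 replicates for ETP50 bias, 400–500 replicates for test
calibration, and 64×64×200 movies with 20 planted cells for segmentation
(unit tests use 48×48×120 with 12 cells). Twenty sources cannot fit in 15
principal components, so the 20-cell recovery uses the component-count
override (25); the default of 15 remains the sensible choice for real
movies where a variance target governs retention.

Degenerate inputs are handled by stated convention rather than error where
a convention is scientifically defensible: constant psychometric fractions
give a flagged degenerate fit; zero-variance t-test input with equal means
gives $p = 1$; all-equal ANOVA data give $F = 0$; a perfect alternative fit
in the F test reports $p$ at the machine floor with a flag; wake activity
with no wake minutes is NaN-flagged rather than silently zero.

This package is used from R; the exported functions documented here are the
interface, and the repository's `scripts/acceptance.R` reproduces the
headline numbers end to end (see the README).
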