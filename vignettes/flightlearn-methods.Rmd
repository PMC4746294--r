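---
title: "Methods: simulating and analysing flight-simulator skill learning with EEG and fNIRS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing flight-simulator skill learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flightlearn)
```

# Overview

`flightlearn` re-implements, as a tested pipeline, the analysis of a
four-group flight-simulator training experiment in which participants
received anodal high-definition tDCS over right DLPFC or left M1 (or sham)
across four consecutive daily sessions, while performing an adaptive n-back
task and repeated "easy landing" approaches under EEG and fNIRS recording.
The original data were collected in-house and never deposited, so the
package is organised around a synthetic-data generator that reproduces the
study's design (groups of 7/7/10/8 subjects, 4 days, 6 n-back blocks and 5
landings per day) with known ground truth, and an analysis stack that must
recover that ground truth. This vignette documents the models, the
parameters that matter, the numerical choices, and what the passing tests
do and do not establish.

# Behavioural layer

## Adaptive n-back scoring

Raw percent accuracy of a 20-trial block is scaled by the information
content of its difficulty level: weights 0.33, 0.66, 1.0 for 1-, 2-, and
3-back (`scale_accuracy()`). Difficulty moves by the adaptive rule
(`adaptive_update()`): one level up after a block strictly above 80%
accuracy, one level down below 20%, clamped to [1, 3]. Each trial carries a
position decision and an image decision; "combined" accuracy pools the two
streams with equal weight (the pooling rule is not fixed by the source
material; equal weighting is the natural choice for two decisions of equal
information). Alternative normalisations can be passed through
`nback_config(weights = ...)`; they are off by default because they do not
change the qualitative results.

Two readings of the task protocol were open:

* **Daily reset of difficulty.** We read "began at the 1-back level" as the
  starting condition of the adaptive procedure, so the level carries over
  between days rather than resetting each morning. This matters for
  estimation: with carry-over, days 2-4 run almost entirely at 3-back,
  where the scaling weight is 1 and block accuracies are unbiased estimates
  of latent ability.

## The subject model of the generator

The generator parameterises a subject by an *ability* expressed directly in
expected scaled-accuracy points. Each decision is correct with probability
`clamp(ability, 0, 100) / (100 * w(N))`, clamped to [0, 1] — a saturating
ramp rather than a logistic. The choice is deliberate: the package's
central closure property is that every injected effect must be recoverable
by the downstream stage, and under the ramp model the injected online rate
(scaled points per block) is *exactly* the expectation of the measured
scaled-accuracy slope whenever the block is below its ceiling. A logistic
in (N - ability) would make the expected slope a nonlinear functional of
the injected rate and leave the recovery target ill-defined. The ramp keeps
the monotonicity the adaptive rule needs and the saturation/floor behaviour
(ability at or above 100 makes every trial correct; at or below 0 the level
never leaves 1-back).

Ability evolves linearly: `online_rate` points per block within a day
(drawn per subject from the group's Normal distribution) and
`offline_gain` points per day (N(3, 1) by default). Baseline ability is
N(45, 8): mid-scale, so that days 2-4 operate in the unbiased interior of
the ramp. Group means of the online rate are equal by default (2
points/block) because group differences were found in the *variance*, not
the mean: the DLPFC-stim group's between-subject rate variance is
multiplied by `variance_shrink_factor` (default 0.25, i.e. half the SD).

## Learning-rate decomposition

`learning_rates()` computes, for any day-by-trial metric series: the
overall OLS slope across the concatenated trial index; per-day online OLS
slopes (`slope ± standard error`); offline rates as the first trial of day
n minus the last trial of day n-1, treated as a slope over unit trial
spacing (the source calls this difference a slope without defining the
spacing); and the meta rate, the OLS slope over the interleaved sequence
online(1), offline(1-2), online(2), ..., online(4). Rates can be computed
per subject (supporting variance analysis) or on group-averaged series;
for an OLS line the group-average slope equals the mean of per-subject
slopes, so the two modes differ only in their uncertainty bookkeeping.
`rate_tests()` supplies the one-sample and paired two-tailed t-tests
(alpha 0.05) with an explicit degenerate branch (a constant sample equal
to the null gives t = 0, p = 1, where `t.test()` would error).

# Flight telemetry layer

## Reference and subject traces

The autopilot reference descends at a constant -600 ft/min, changes
vertical speed only in the final 5 s (the flare ramp, crossing zero once),
and touches down at the runway threshold; it contains exactly one
vertical-speed sign change. Subject traces perturb the reference with AR(1)
vertical-speed noise (coefficient 0.95, innovation scale 60 ft/min divided
by the subject's skill), a smooth cross-track drift, and re-integrated
altitude, so the touchdown time is an emergent property; if the aircraft is
still airborne at the end of the reference window it continues a final
-300 ft/min descent. Missed landings are Bernoulli events (default rate
0.03/trial, matching the low single-digit percentages reported) simulated
as a balloon over the threshold; no mechanism for missed landings is given
in the source, so a mechanism-free flag plus plausible telemetry is the
honest option.

## Landing metrics

* **Impact g-force** — backward finite difference of vertical speed across
  the touchdown sample, converted to m/s^2 and divided by 9.8, returned as
  a magnitude ("minimise landing force" is about magnitude). A backward
  difference is used because touchdown ends the approach; the worked
  example (-600 to 0 ft/min over 0.1 s = 3.11 g) anchors the units.
* **Flight-path deviation** — both traces are transformed to a local
  East-North-Up frame on a spherical Earth (R = 6,371,000 m, origin at the
  runway threshold; sub-metre adequacy at landing scale, and no datum is
  named by the source), resampled by non-overlapping moving-window
  averages onto `floor(min(n_a, n_b)/window)` aligned points (window = 10
  samples = 1 s by default; the source names the windowing but not its
  size), and the per-sample Euclidean distances are summed. With window 1
  and equal lengths this reduces to the naive pointwise sum, which is the
  oracle the tests use.
* **Vertical-speed deviation** — same alignment, sum of *absolute*
  differences: signed sums could cancel and contradict "lower deviation is
  better". Whether the original summed raw samples or window means is
  ambiguous; both are exposed (`window = 1` gives raw), windowed is the
  default.
* **Vertical-speed variance** — sample variance from the start of the
  recording to touchdown.
* **Control inputs** — count of vertical-speed sign changes, with zero
  samples inheriting the previous non-zero sign so a noise-free hold at
  0 ft/min counts nothing; invariant to positive rescaling.
* **Missed classification** — no touchdown within the runway extent, with
  an inclusive boundary (touchdown exactly at the terminal end counts as
  landed) guarded by a small numerical tolerance. Missed attempts have
  undefined deviation metrics (`NA`) and are aggregated separately as
  percentages.

# Group statistics

Outlier rejection is a single pass at 3 pooled standard deviations over
the trial distribution across subjects and groups; iteration is not
described in the source and is not performed. Note an arithmetic
consequence of the rule as printed: in a sample of n values the maximum
|z| is (n-1)/sqrt(n), so no point can be rejected from a sample of five —
the property tests therefore use larger fixtures.

The two-sample variance F-test reports F = s_a^2/s_b^2 with its
asymmetric-tail two-sided p (2 * min of the tail probabilities, capped at
1), the distance of F from 1, and the direction; Bartlett's test is run on
per-subject day averages to preserve independence. Both are computed by
the standard library routines and cross-checked in the tests against the
textbook formulas to 1e-10. Pearson correlations use the study's two-tier
convention: significant below 0.001, trend below 0.05.

# EEG layer

Synthetic EEG is generated as a continuous 500 Hz signal — pink (1/f)
noise at 1 uV plus band-limited oscillations: a 6 Hz theta component with
a Gaussian topography centred between Fz and FC1 and a 10 Hz alpha
component centred at Pz — rather than band power directly, so the spectral
stage is genuinely exercised. The packaged 31-channel layout uses standard
10-10 labels (the study's custom cap geometry is unpublished).

The spectral pipeline applies a second-order (12 dB/octave) Butterworth
high-pass at 0.5 Hz, forward and backward. Zero-phase application is a
choice: band power is phase-insensitive and zero phase avoids group delay
across epoch boundaries; the cost is that the end-to-end magnitude at the
cutoff is -6 dB rather than the single-pass -3 dB. Each task segment is
cut into sequential non-overlapping 1-s epochs, Hann-windowed, and
Fourier-transformed; band power is the mean one-sided
window-power-normalised PSD over the band's integer-frequency bins (theta
4-7 Hz, alpha 8-12 Hz; 1-s epochs give exactly 1 Hz bin spacing). The
normalisation satisfies Parseval against the windowed signal energy to
1e-6 relative, which the tests assert. Epochs whose channel-average band
power exceeds the across-epoch mean by more than 2 SDs are rejected —
one-sided high, since artifacts inflate power. Missing subject-day cells
are imputed by the group/day/channel/band mean and flagged. Midline-frontal
theta is the mean theta power over Fz and FC1.

With the default noise, a doubling of theta amplitude from day 1 to day 4
is recovered as a power ratio of ~4 within 10%; the pink-noise floor
contributes about 1% of the oscillation's band power at the focus.

# Cluster-based permutation statistics

Channel-wise Student (pooled-variance) t-maps — independent-samples for
stim vs sham, paired for day 4 vs day 1 — are thresholded two-sided at the
data-point alpha (0.05). Same-sign supra-threshold channels are grouped
into adjacency-connected components; components smaller than 2 channels
are discarded. The cluster statistic is the summed |t| (the source does
not name its statistic; summed-t is the default of the standard toolbox it
cites), and the reported cluster-level t is the signed mean over member
channels, matching the reporting convention of the original tables. The
null distribution of the maximum cluster mass is built from 500
relabellings (independent: group-label exchanges; paired: sign flips) with
the observed labelling included, so p lies in [1/500, 1]; when the number
of distinct relabellings is at most the requested count the test
enumerates exhaustively. Two-sided clustering uses the printed data-point
alpha of 0.05 as-is (not 0.025 per tail). A small relative tolerance
guards the exceedance count against floating-point asymmetry between the
vectorised permutation t-maps and the observed map.

Adjacency is built from the layout by a pairwise-distance quantile
(default 0.12), with an optional absolute `max_distance` cap for layouts
where the quantile is degenerate. Under the null (two groups of 7, 30
channels on a grid, orthogonal adjacency), the empirical family-wise rate
over 500-study simulations sits near 0.04 — controlled at, and slightly
below, the 0.05 cluster alpha, as expected for a max-statistic test with a
minimum-extent rule.

# fNIRS layer

The optical model is the modified Beer-Lambert law with the published
constants: wavelengths 760/850 nm, molar extinction coefficients
eps_Hboxy = (1097.0, 781.0) and eps_Hbdeoxy = (645.5, 1669.0) cm^-1/M,
differential pathlength factors 5.98 and 7.15. The source binds one DPF to
each chromophore; physically DPF belongs to a wavelength, so the package
maps 5.98 to 760 nm and 7.15 to 850 nm by default and leaves the mapping
configurable. Source-detector separations are at most 3.5 cm (a uniform
3.0 cm synthetic default stands in for the unpublished cap distances).
Concentration changes are solved per sample by 2x2 inversion;
`mbll_convert()` is the exact inverse of the forward model to machine
precision, and Hbtot = Hboxy + Hbdeoxy is preserved by every linear stage.

Band-pass filtering (0.01-0.2 Hz) uses a linear-phase least-squares FIR,
designed in closed form over continuous frequency bands (the normal
equations of the integrated squared error; no frequency grid). The default
length is three periods of the low edge — 2401 taps at 8 Hz. Lightly
weighted half-amplitude transition bands ([lo/2, lo] and [hi, 1.2 hi])
keep the normal equations well conditioned at this length, and the taps
are recentred so the DC response is exactly zero. The realised response
passes 0.05 Hz within 0.1%, attenuates a 1.2 Hz cardiac tone by more than
100 dB, and stays below -40 dB beyond 1.5x the upper edge; the narrow
low-side transition reaches about -32 dB at its edge, which combined with
the exact DC zero removes linear drifts effectively (filtered
concentration series correlate above 0.98 with the noise-free truth under
the default drift and cardiac contamination). Application is zero-phase by
centred FFT convolution with reflection padding.

Channels are excluded when any chromophore fluctuates by strictly more
than 0.001 mM peak-to-peak during baseline (a fluctuation of exactly the
threshold is kept, as printed). Baseline means are subtracted per channel
after optional excision of inter-trial samples. GLM betas regress each
channel on the task boxcar convolved with a canonical double-gamma HRF
(response gamma shape 6, undershoot shape 16, ratio 1/6, unit peak —
parameters follow the convention of the named software, which the source
does not spell out), plus discrete-cosine high-pass regressors with a
128 s cutoff period and an intercept; rank deficiency raises an error
naming the collinear columns. Day contrasts are per-channel paired t-tests
thresholded at the Bonferroni-corrected alpha (family 0.05 / 20 channels
= 0.0025) with ROI summaries over the 10 M1 and 10 DLPFC channels. The
channel-wise screening rule flags a channel when its trial-wise mean
change exceeds 3.5 standard errors under the zero-change null; the p-value
printed alongside that rule in the source (0.00035) does not match a
3.5-SD normal tail (~0.000465), so the SD rule, not the p, is normative
here.

The generator's injected day-4-minus-day-1 DLPFC Hboxy changes default to
the published easy-landing contrast magnitudes (-0.0024 mM for DLPFC
stim); the OD noise scale (5e-4) is chosen so single-channel responses are
visible but individual-channel significance is not guaranteed — the
regime the original reports.

# Monte-Carlo design of the validation studies

Three simulation studies ship as package functions so the tests and the
acceptance script exercise one code path:

* `fwer_null_study()` — 500 null studies (two groups of 7, 30 channels,
  i.i.d. Normal band power), each analysed at the study's settings (500
  permutations, point alpha 0.05, cluster alpha 0.05, minimum extent 2).
* `rate_recovery_study()` — 200 replicate cohorts at the full design;
  per-subject online rates are estimated as the mean of the day-2, -3 and
  -4 within-day OLS slopes of combined scaled accuracy (day 1 is excluded
  because the adaptive ramp from 1-back compresses its early blocks). The
  group-mean check uses the estimator's standard error assembled from the
  injected between-subject SD plus the OLS slope SEs; the DLPFC-stim
  variance-shrink factor is recovered by pooling the
  measurement-error-corrected between-subject variances
  (`var(estimates) - mean(se^2)`) over cohorts, because a single-cohort
  variance ratio on 6 and 6 degrees of freedom is far too noisy to carry a
  25% tolerance.
* `hbo_sign_recovery_study()` — 30 replicate 7-subject cohorts through the
  full fNIRS pipeline (forward model, MBLL inversion, band-pass, baseline
  subtraction, GLM, day contrast), checking the sign of the recovered
  DLPFC Hboxy day contrast.

Stochastic rate assertions (the family-wise rate, the 2-SE coverage
fraction, the sign-recovery fraction) allow the one-sided 95% binomial
Monte-Carlo margin around their nominal level; a 2-SE band has exact
coverage 95.45%, so asserting "at least 95%" without the sampling margin
would reject a true property in roughly a third of runs. The problem sizes
above (500 null studies, 200 cohorts, 30 fNIRS replicates, 10 s EEG
segments, 330 s fNIRS sessions) were chosen once as the smallest sizes at
which the Monte-Carlo error is clearly smaller than the tolerances being
checked.

# What the synthetic data do and do not establish

The generator reproduces the design, the sampling rates, the effect
directions and published magnitudes, and enough noise structure to make
every pipeline stage non-trivial (adaptive difficulty dynamics, AR(1)
flight noise, pink-noise EEG with volume-conduction-like topographies,
drift/cardiac fNIRS contamination). It deliberately omits: ocular and
cardiac EEG artifacts (the source removed them with an ICA variant that is
out of scope, so synthetic signals are artifact-free); realistic
aerodynamics; scalp current-flow physics; motion artifacts and
short-separation physiology in fNIRS; and any nonlinearity of learning
curves. Passing recovery tests therefore demonstrate that the analysis
code measures what it claims to measure under the stated models — not that
the original biological effects are reproduced, which is impossible
without the unreleased human data.

# Known limitations

* The tDCS montage stores the printed total current (2 mA) and scalp
  current density (0.04 A/m^2) verbatim; they are mutually inconsistent
  with the stated electrode areas and are not reconciled.
* Trial-wise F-tests reuse subjects across trials; independence holds only
  for the Bartlett analysis on day averages, as in the source.
* The custom-cap electrode names appearing in the original cluster tables
  (E5, E11, E19) have no published geometry; the packaged layout uses
  standard labels only.
* The offline "slope" uses unit trial spacing by convention; any other
  spacing rescales offline and meta rates linearly.
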