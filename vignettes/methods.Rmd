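---
title: "Models and methods behind bcinav"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bcinav}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

`bcinav` models a two-command motor-imagery (MI) brain-computer interface:
a user imagines moving forward or backward through a virtual tunnel, and
three EEG channels over sensorimotor cortex (C3, Cz, C4; 256 Hz, ears
reference) must reveal which. The discriminative phenomenon is the **beta
rebound**: a transient event-related synchronization (ERS) of beta-band
power a few hundred milliseconds *after* imagery offset, lateralized —
C3-dominant (left hemisphere) after forward imagery, C4-dominant after
backward imagery — with the forward rebound several times stronger
(grand-average peaks near 600% vs 200% of baseline band power). During
imagery itself there is a bilateral alpha (8–12 Hz) event-related
desynchronization (ERD), which carries essentially no class information in
this paradigm.

Each 9-s trial is: 3 s static baseline, a 2-s written command, a 0.5-s
static gap, then 3.5 s of tunnel motion. Two session conventions differ
only in when imagery stops: at 5.5 s (when the tunnel starts moving;
"session 1", the open-loop calibration session) or at 5.0 s (command
offset; "session 2", the closed-loop neurofeedback session, chosen so the
rebound peaks near the 5.5 s decision point).

The human recordings behind these numbers are not publicly deposited, so
the package ships a calibrated synthetic-EEG generator and treats the
published summary statistics as the quantities a correct pipeline must
recover from it.

## The synthetic world

Per channel, a trial is built from:

* **Background**: 1/f ("pink") noise with ~5 µV RMS plus 1 µV white sensor
  noise, synthesized spectrally (flat below 1 Hz). The sum is passed
  through a soft limiter (`14 · tanh(x/14)` µV). The limiter keeps clean
  trials strictly below the 20 µV artifact-rejection criterion — without
  it, Gaussian tails reject ~28% of *clean* trials, and worse, they
  selectively reject the largest-rebound trials, biasing the recovered ERS
  downward by several percent. Real front-ends compress long before that
  range, and published baseline EEG statistics say nothing that forbids
  this choice.
* **Alpha rhythm**: 9–11 Hz band noise, 2 µV RMS, on C3 and C4 only;
  during imagery its power is reduced by `alpha_erd_fraction` (default
  0.4) with 200 ms cosine ramps. Applied identically to both classes (the
  study does not report a class difference).
* **ERS burst**: band-limited noise in the subject's ERS band (25–30 Hz
  "high beta" for 7 of 10 virtual subjects, 16–24 Hz central beta for 3)
  under a Gaussian amplitude envelope (FWHM `burst_duration_s`, default
  0.3 s), centered `latency` after imagery offset (0.3 s forward, 0.2 s
  backward), added to the dominant channel with an amplitude `crosstalk`
  fraction (0.1) leaked to the opposite channel. Per trial, the peak
  amplitude carries lognormal jitter (cv 0.1, unit mean square) and the
  latency Gaussian jitter (SD 30 ms). The carrier's energy under the
  envelope is normalized exactly, so the injected ERS power is
  deterministic per trial and only its phase structure is random.
* **Artifacts**: Poisson-count 60 ms half-sine transients of 50 µV at
  uniform random times/channels (rate 0.05 per trial), with ground truth
  recorded.

**Amplitude calibration.** The burst's peak variance is chosen so that the
package's *own* recovery pipeline — zero-phase 18th-order 8–30 Hz
Butterworth, zero-phase 4th-order sub-band filter, squaring, trial
averaging, 250 ms smoothing, percent change against the 0.5–2.5 s
reference — peaks at the requested ERD% value. A probe ensemble (800
bursts, 100 background trials, a fixed private seed, cached per
configuration) measures the chain's net gain, which accounts for the
sub-band filter's |H|⁴ zero-phase response, the broadband stage's edge
roll-off (appreciable at 30 Hz), envelope smearing by the filter impulse
response and the smoother, and latency-jitter smearing of the average.
Calibrating against anything less than the full chain leaves 5–15%
systematic error.

**Free parameters.** Jitter magnitudes are not published. They were
chosen once so that the generator satisfies its own recovery contract —
the N = 160 trial-averaged peak estimate within 15% relative error. With
amplitude-jitter cv 0.25 and latency jitter 50 ms the estimator's spread
is ~15% (violating the contract in ~30% of seeds); the shipped defaults
(0.1, 30 ms) put the dominant residual variance at the irreducible
per-sample power fluctuation of a 5-Hz-wide process smoothed over 250 ms
(~10–13% SD at N = 160 for a 200% ERS). This also motivates the 250 ms
ERD smoothing default (matched to the rebound's power-envelope width) and
the energy-normalized carrier; with an unnormalized carrier the 15%
contract is unattainable at N = 160. For a 200% rebound the contract is
still only ≈ 1.5 SD, so individual seeds can land outside it — that is
the stated world's physics, not an implementation defect.

**What a green test does *not* establish.** The generator has no volume
conduction or head model, no eye/muscle artifact taxonomy, no visual
evoked response to tunnel motion, stationary background statistics, and
its inter-trial variability is parametric. Green acceptance tests
establish that the pipeline recovers what the generator encodes — they
say nothing about robustness to the nonstationarities of real EEG.

## Preprocessing

Fixed order: 20 µV rejection on raw amplitudes (1-s segments; a trial is
dropped when a flagged segment intersects the 3–6 s analysis window) →
broadband 8–30 Hz 18th-order Butterworth → linear detrend → sub-band
decomposition (alpha 8–12, SMR 12–15, beta 16–24, high beta 25–30 Hz;
4th-order — the 18th order is specified only for the broadband stage).
The 15–16 Hz gap between SMR and beta is reproduced as printed. The
18th-order filter is realized as nine cascaded biquads (a direct form is
numerically unusable at this order); designs with poles on or outside the
unit circle raise an error rather than produce NaNs. Offline analyses use
zero-phase (forward–backward) filtering so ERS latency is not shifted;
the online simulator uses causal filtering only. Whether the original
device rejected artifacts before or after band-filtering is unknown; this
package rejects on pre-filter amplitudes.

## Features

* **TFR**: STFT power with 1-s Hanning windows, 50% overlap. "64
  frequency bins" is inconsistent with the 129 one-sided bins of a
  256-point FFT; adjacent bins are aggregated pairwise into 64 × 2 Hz bins
  (a 128-point FFT is available as a switch).
* **PSD**: 1-s Hanning periodogram, 1 Hz bins, one-sided density
  normalized so the integral matches the variance (Parseval with taper
  correction).
* **Asymmetry ratio**: `Ra = (R − L)/(R + L)` with R from C4, L from C3.
* **ERD/ERS**: `ERD%ⱼ = (Aⱼ − R)/R × 100` with A the trial-averaged
  instantaneous band power and R its mean over the reference interval.
  The reference interval is nowhere printed; 0.5–2.5 s is used (inside
  the 3-s static baseline, trimmed 0.5 s per side for filter transients).
* **Epochs**: 3.5–4.5, 4–5, 4.5–5.5, 5–6 s; half-open, 0-based.

**The epoch-3 contradiction.** The study reports epoch 3 (4.5–5.5 s) as
the best *offline* window while also placing the session-1 ERS peaks
200–500 ms *after* the 5.5 s imagery offset — outside epoch 3. In the
synthetic world, where session-1 imagery ends exactly at 5.5 s, epoch 3
contains no class information by construction; the window containing the
rebound in *both* session conventions is epoch 4 (5–6 s). The package
therefore defaults its offline simulations to epoch 4, and reproduces the
published epoch ordering (epoch 3 ≻ epoch 1) as a property of
session-2-convention data, where the rebound (peak ~5.2–5.3 s) falls
inside epoch 3. Real subjects plausibly stopped imagining early in
session 1, which would reconcile the two published statements; a
generator cannot know that, and the epoch remains a parameter everywhere.

## AR / ARX feature models

Burg's lattice recursion estimates AR coefficients (orders 2–30;
reflection coefficients bounded by 1); ARX adds a class-template
exogenous input and is fit by least squares over lagged regressors. Order
selection is Gaussian-likelihood AIC, `n·ln σ̂² + 2k`, ties to the smaller
order; one Burg pass yields all candidate orders. Because per-trial
selected orders vary, the feature builder fixes one order per channel —
the median of per-trial AIC minimizers over the *training* session — so
feature dimensions match across sessions.

AR models are fit to the epoch-restricted **sub-band signal** (mean
removed). The alternative — AR on the squared band-power envelope — was
the initial design and failed in implementation: the envelope's
smoothing-induced autocorrelation rails AIC at order 30 and a high-order
AR absorbs the rebound bump, diluting class information to ~63%
cross-validated accuracy versus ~82% for plain band power. On the raw
sub-band signal the residual variance *is* the AR-whitened epoch band
power ("AR-modeled band power"), and coefficients encode in-band spectral
shape; the envelope mode remains available (`source = "envelope"`). The
residual variance is appended as a feature by default
(`include_noise_var`).

Templates (class-mean signals) are computed within training folds only.
At prediction time the true class is unknown, so *both* class templates
are applied to every trial and both coefficient sets are concatenated —
using the matched template alone would leak labels.

## Classification

Diagonal LDA (per-class means, pooled per-feature variance floored at
1e−12 of the mean variance) and a linear L1-loss SVM solved by dual
coordinate descent with random sweep order and a regularized bias
(augmented constant feature); non-convergence is an error with
diagnostics. Features are z-scored with training statistics only (the
study is silent on normalization). Cross-validation is stratified 10-fold
— plain size-n/10 folds can lose a class at small n — with each trial
tested exactly once. The C grid is read as decade steps 1e−7…1e2 (the
printed "step value of e−1" is ambiguous; ×e spacing is available via
`dense = TRUE`); ties go to the smaller C, and exact decision ties go to
"forward" everywhere. C = 1e−2 is the study's published optimum and the
default.

## Neurofeedback simulation

The control signal is the causally filtered (broadband then ERS band)
squared EEG, block-averaged to 8 Hz and smoothed with a 3-sample trailing
moving average; the decision reads the single 8 Hz sample whose trailing
window ends at 5.5 s. Thresholds are `Th = MEAN + coefficient × STDEV`
per class channel (C3/forward, C4/backward).

**MEAN/STDEV convention.** These are computed from the pooled
*single-trial* control-signal samples in the session-1 reference
interval, not from the 160-trial-averaged curve: the averaged curve's SD
is ~12× smaller, which would place the published worked example (a 200%
ERS ≈ 2–3 SD, a 600% ERS ≈ 9 SD above baseline) off by an order of
magnitude and make a 6 SD threshold sit inside baseline noise. With the
single-trial convention the synthetic excursions land at ~2.7 and ~8 SD —
the published scale.

The STDEV coefficient is selected per channel by a generalized form of
the published recipe: round the wrong-class excursion, add 1 SD safety,
push up to 3 SD but stay ≥ 3 SD below the correct-class peak; infeasible
geometry falls back to 6. Decisions: forward iff only C3 crosses,
backward iff only C4 crosses, otherwise `none`; simultaneous crossing is
a failure (the protocol never specifies it; failure is conservative).
Success rates count all trials of a class in the denominator (`none` is a
failure) — whether the original counted no-crossing trials is unknown and
flagged.

**Learning emulation.** Session-2 generation multiplies ERS power by a
run × class matrix (`skill_by_run`) emulating closed-loop learning. True
human learning dynamics are unknowable from summary statistics, so the
defaults were calibrated once, by Monte-Carlo measurement of the
success-vs-multiplier curves on the default 10-subject cohort, to
reproduce the published run-wise success rates (forward/backward:
74.75/32.75, 55.75/57.3, 76.75/64.5 in runs 1–3; backward run 4 = 71.5).
The forward run-4 rate is not printed ("stabilized with slight
improvement"); it is inferred as 81.3% from the constraint that run-4
overall performance equal the published session-2 neurofeedback average
(76.38%). The calibrated multipliers (≈0.9–1.6 forward, ≈1.9–3.5
backward) mostly exceed 1 — active closed-loop control with feedback
is emulated as stronger than open-loop calibration imagery, which is also
why backward control *can* reach 70% despite a 200% calibration ERS
sitting below a 6 SD threshold. These values are part of the stated
world; they are not adjusted per experiment.

## Numerical and interface choices

* All times are seconds from trial onset (0-based); intervals half-open;
  sample indices 0-based in documentation (1-based inside R code).
* Session-2 seeds derive from session-1 seeds (+5000); every `trial_set`
  records its seed; all stochastic functions are reproducible from
  (data, seed).
* Datasets persist as little-endian float64 + JSON header with MD5
  checksum + CSV trial table; EDF import is supported read-only.
* The ERD reference power must be positive; zero-variance inputs,
  single-class training sets, rank-deficient ARX regressions,
  out-of-range orders and unstable filter designs are hard errors.

## Known limitations

Single dipole-free channels with purely additive structure; no
cross-channel background correlation; learning emulated as a step
function per run; thresholds assume a stationary baseline across
sessions; the AIC order for AR features regularly rails at the top of the
2–30 range on strongly narrowband signals (harmless here, but the range
is the published one, not an optimum); recovery of a 50% ERS at N = 160
is noise-limited (the max-over-window read is then dominated by its own
bias, so the recovery contract is checked at the ground-truth latency for
small amplitudes).
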