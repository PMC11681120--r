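---
title: "Methods: HRV extraction, cross-modality equivalence, and baseline-calibrated lie detection"
author: "lierhrv package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: HRV extraction, equivalence testing, lie detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lierhrv)
```

## What the package computes

`lierhrv` implements a four-stage pipeline for heart-rate-variability (HRV)
analysis across recording modalities:

1. **Beat detection** from a raw one-dimensional waveform — an ECG trace or
   a pulse-like trace (finger photoplethysmography, or a pulse signal
   already extracted from face video) — producing a `BeatSeries` of beat
   times and NN intervals.
2. **Windowed HRV extraction**: 39 standard parameters per sliding window
   (`HRVWindowMatrix`, a `SummarizedExperiment`).
3. **Cross-modality equivalence testing**: a one-sample TOST per parameter
   on paired window differences between two modalities, with Cohen's-d
   margins and a significance-marker summary (`EquivalenceReport`).
4. **Lie detection**: per-participant baseline calibration, a sign-split
   scoring function for feature selection on an external participant
   group, and a per-participant random-forest classifier compared against
   a majority-vote baseline.

A seeded synthetic-session generator makes the whole pipeline testable
without any recorded data.

## Beat detection

**AMPD** (`detectPeaksAMPD`) is the automatic multiscale peak detector in
its deterministic form: the signal is least-squares detrended, sample
\(i\) is marked a maximum at scale \(k\) if it exceeds both neighbours at
lag \(k\), the scale \(\lambda\) maximising the count of scale-\(k\)
maxima is selected, and peaks are samples that are maxima at every scale
\(\le \lambda\). The random tie-breaking entries of the original
scalogram formulation only perturb ties, so they are omitted; the result
is fully deterministic. Comparisons that fall outside the record are
treated as satisfied so that peaks close to the edges are kept; the two
endpoint samples are never peaks. The scale cap defaults to two seconds'
worth of samples, above half of any physiological beat interval.

**Energy QRS detection** (`detectRPeaksEnergy`) is a conventional
band-pass (5–25 Hz, 3rd-order Butterworth, zero-phase), squaring,
150-ms moving-window integration, block-adaptive threshold (30 % of the
10-s block maximum with a 5 % global floor) and a 250-ms refractory
period, reporting the raw-amplitude maximum of each detection region.

**Agreement fusion** (`fuseDetections`) keeps the primary detector's
peaks that are confirmed by a secondary peak within a tolerance
(default 150 ms — below half of any plausible beat interval), matched
greedily nearest-first and one-to-one. The primary detector's timestamps
are the ones retained.

Beat times are `(index - 1) / fs` seconds, so the first sample is time 0;
NN intervals are reported in milliseconds and are always derived from the
beat times, never stored separately.

## Windowing

Two stepping modes (`hrvWindowConfig`):

* `time_overlap` — fixed windows advanced by `windowLength - overlap`
  seconds (the 1-min / 30-s-overlap convention for short-term parameters;
  5-min non-overlapping for long-term parameters);
* `beat_step` — windows anchored on beats and advanced by a fixed number
  of beats (the 30-s / 2-beat-step convention of the lie-detection
  pipeline; a 15-min baseline at ~1-s beats yields on the order of 400
  windows).

Windows are half-open `[start, start + L)`; a beat exactly on the right
edge belongs to the next window. Windows with fewer than `minBeats`
(default 10) beats are dropped with a message, and a window is emitted
only if it fits inside the recorded span.

## The 39 parameters and their conventions

Where a textbook quantity has more than one common convention the package
fixes one and states it:

* **Time domain** — AVNN (mean), SDNN (sample SD), RMSSD (root mean
  square of successive differences), SEM = SDNN/√N, pNN50 with a strict
  "greater than 50 ms".
* **Poincaré** — SD1 is RMSSD/√2 *exactly* (second moment of successive
  differences about zero); SD2 is the population SD of successive sums
  over √2. The SD1–RMSSD identity is therefore exact by construction and
  is asserted to 1e-9 in the tests.
* **Fragmentation** — computed on the sign series of successive
  differences; zero differences break segments and are never inflections.
  PIP counts sign-change boundaries between consecutive nonzero-sign
  differences over all such boundaries; IALS is the inverse mean length
  (in differences) of same-sign runs; PSS and PAS count the distinct NN
  intervals touched by, respectively, same-sign runs spanning fewer than
  3 intervals and alternation runs spanning at least 4 intervals, with
  the full interval count as denominator.
* **Frequency domain** — Lomb–Scargle periodogram on the unevenly sampled
  NN series (no resampling), evaluated from 1/span to 0.4 Hz with 4-fold
  oversampling, scaled as a one-sided density (2 · mean Δt · P) so band
  integrals are in ms². Bands: VLF 0.003–0.04, LF 0.04–0.15, HF
  0.15–0.4 Hz. Normalised powers are computed against LF + HF (so
  LF norm + HF norm = 100 exactly); total power is VLF + LF + HF; BETA is
  the least-squares slope of log-density vs log-frequency at or below the
  VLF upper edge.
* **DFA** — profile integration, non-overlapping boxes, linear
  detrending; ALPHA1 over boxes 4–15 (needs ≥ 16 intervals), ALPHA2 over
  16–64 (needs ≥ 70). Note that DFA-1 over boxes 4–15 is biased slightly
  upward for white noise (≈ 0.58 rather than 0.5 at n = 1000); this is a
  property of the estimator, not an implementation artifact.
* **MSE** — coarse-graining by non-overlapping means; sample entropy with
  m = 2 and r = 0.2 × the sample SD of the *original* series; scale s
  needs at least 10·s intervals.

A parameter that cannot be computed from a window is `NA`
("not computable"), never silently zero, and never discards the window.

**Long-term parameters.** VLF norm and power, total power, BETA, ALPHA2
and MSE scales 7–15 require more data than a short window supplies
(spectral support below 0.04 Hz needs several hundred seconds; ALPHA2
needs ≥ 70 intervals; MSE scale 15 needs 150). They are computed only in
windows of at least 300 s and flagged `NA` otherwise. This is the
package's own partition (`longTermFeatures()`), derived from the
definitions, and is configurable.

## Equivalence testing

For each parameter, paired per-window differences between two modalities
are tested with the **one-sample TOST**: with margins
\(\Delta_{U,L} = \pm d \cdot \mathrm{SD}(\text{differences})\) (Cohen's d,
default 0.5), two one-sided t tests with n−1 degrees of freedom reject
"mean below \(\Delta_L\)" and "mean above \(\Delta_U\)"; equivalence is
declared when both reject at the 0.05 level. The margin SD is the sample
SD of the differences themselves (a user-supplied absolute margin can
override it). Markers: `-` if either p ≥ 0.05; `*` both in [0.01, 0.05);
`**` exactly one below 0.01; `***` both below 0.01 — "below" strict, a
boundary value counts as above. Windows are paired across modalities by
start time (nearest within half a window, one-to-one; unpaired windows
dropped). No multiple-testing correction is applied across the 39
parameters (the report notes this); the percent-similar summary divides
by the full parameter count even when some parameters are not computable,
so published-style counts like 22/39 = 56.41 % are reproduced exactly.
Zero-variance differences (e.g. comparing a table against itself) make
the d-based margin undefined; such parameters are flagged degenerate
rather than being assigned a marker.

## The lie-detection algorithm

Each participant contributes a 15-min rest **baseline** and six 1-min
**active states** (one per yes/no question, 2-min rests between). HRV is
computed in 30-s windows stepping 2 beats in both periods. Baseline
windows give per-feature mean \(\mu_f\) and sample SD \(\sigma_f\); every
active window is calibrated as \(x^{calib}_{fn} = (x_{fn} - \mu_f) /
\sigma_f\) and inherits its question's label (y = 1 truth, 0 lie).
Features with zero baseline SD are unusable and excluded.

**Feature selection** runs on an *external* participant group only
(default 20 % of the cohort, rounded up, drawn by seed) and considers
only the 25 short-term parameters, because the physiological response to
a question is brief. Per participant, \(M_L\) and \(M_T\) are the mean
calibrated values over lie and truth windows. Participants are split per
feature into a *positive* group (same sign of \(M_L\) and \(M_T\); zero
counts as same sign) and a *negative* group (opposite signs). With
\(v_p = |M_{Tp} - M_{Lp}|\), each group contributes its inverse
coefficient of variation, and the score is

\[ S = \beta\,\frac{\mu_{pos}}{\sigma_{pos}} +
      (1-\beta)\,\frac{\mu_{neg}}{\sigma_{neg}}, \qquad \beta = 0.45 . \]

An empty or single-member group contributes 0; a zero group SD with a
nonzero mean would make its term infinite, so the term is dropped and the
feature is ranked by its finite term alone; a feature with no informative
term is excluded. The three top-scoring features are selected, ties
broken by canonical parameter order, deterministically.

**Classification.** For each remaining participant, 10 seeded stratified
80/20 Monte-Carlo splits of the calibrated windows are drawn; a random
forest (100 trees, default mtry) is trained per split on the three
selected features and compared on the validation windows against the
naive majority-vote classifier (predicts the majority validation label;
an exact tie predicts truth). Cohort aggregates report mean ± sample SD
of both accuracies and of the fractions of splits in which the model was
better, exactly equal, or worse.

## The synthetic generator

`simulateRR` is an integral-pulse-frequency-modulation (IPFM) generator:
beat times are emitted where the integral of the instantaneous rate
\(1000 / rr(t)\) crosses successive integers, with

\[ rr(t) = \overline{RR} + A_{LF}\sin(2\pi f_{LF} t)
                         + A_{HF}\sin(2\pi f_{HF} t) \]

and white Gaussian noise added per interval. Defaults describe a healthy
resting adult: mean RR 900 ms, LF 0.1 Hz at 40 ms depth (Mayer waves),
HF 0.25 Hz at 30 ms depth (respiratory sinus arrhythmia), noise SD
15 ms. IPFM was chosen over autoregressive models for its transparent
band structure: the configured modulation frequencies are exactly where
the extractor should find spectral peaks, which gives generator/extractor
consistency tests real teeth. The integration grid is 10 ms with linear
interpolation of the crossings; with zero modulation and noise the
intervals equal the configured mean exactly.

`simulateSession` lays out the protocol schedule (15-min baseline, six
1-min questions, 2-min rests, half of the questions lies, placement
seeded) and perturbs lie spans with a transient sympathetic-like effect:
a 5 % instantaneous mean-RR drop and a 40 % HF-depth reduction over the
60-s span. These magnitudes are fixture parameters chosen to be
physiologically plausible for a brief sympathetic activation, not claims
about the physiology of deception. `simulateWaveform` renders beats as
analytic templates (Gaussian pulse, or a Q–R–S triplet of Gaussians for
ECG) plus white noise at a configured SNR — morphology models are out of
scope.

`simulateCalibratedCohort` bypasses signal synthesis entirely and plants
a configurable shift (default d = 1.5 on 3 of the 39 features) directly
in calibrated windows; it is the fixture for feature-selection recovery
properties. Its default cohort size of 20 keeps roughly ten participants
per sign-split group — see the limitations below for why smaller groups
are unreliable.

What the generator does *not* emulate: ectopic beats and artifacts,
non-stationary baselines, respiration-locked amplitude modulation,
realistic waveform morphology, or inter-feature correlation structure
beyond what the IPFM model induces. Passing tests on synthetic sessions
therefore demonstrate the correctness of the computations and the
internal consistency of the pipeline, not field performance on recorded
data.

## Problem sizes used by the tests

The test-suite and the acceptance script use: 20-participant cohorts for
the end-to-end pipeline (both planted and null), 100 replicates at
n = 1000 for the DFA limit exponents, 1000 simulations at n = 150 for
the TOST operating characteristics, 100 replicates for planted-feature
recovery, 300-s records for spectral recovery, and 50 replicates at
n = 3000 for the MSE coarse-graining property. These sizes were chosen
so each property is measured with comfortable statistical margin.

## Known limitations

* **Temporal leakage in window-level validation.** Active-state windows
  step 2 beats and therefore overlap by ~93 %; labels are constant
  within a question. Under window-level 80/20 splits a validation window
  almost always has a near-duplicate time-neighbour in the training set,
  so the classifier can retrieve its label without any genuine
  physiological signal: on *null* sessions (no planted effect) the model
  still beats the naive baseline by 15–30 points. This is a property of
  the evaluation design, which the package keeps as the default because
  it is the documented convention of the algorithm; `trainEvaluate(...,
  splitBy = "question")` provides a leakage-free alternative that holds
  out one whole question per label, and on null sessions its gap is
  within a few points of zero. Accuracy gaps obtained under window-level
  splits should be interpreted with this caveat.
* **Scoring instability in small groups.** The scoring function divides
  by a per-group sample SD. With fewer than ~8 participants in a
  sign-split group, a pure-noise feature occasionally draws a near-zero
  group SD and outranks genuinely discriminative features. Feature
  selection should be run with external groups large enough to keep both
  sign groups near ten members.
* **No artifact handling.** Inputs are assumed pre-filtered NN series;
  there is no ectopic-beat correction.
* The DFA small-box slope is a biased estimator at short scales (white
  noise reads ≈ 0.58, not 0.50); values should be compared against the
  same estimator, not against asymptotic theory.
* Absolute spectral band powers depend on the periodogram scaling
  convention; comparisons across packages should use normalised powers
  or peaks, which are convention-free.
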