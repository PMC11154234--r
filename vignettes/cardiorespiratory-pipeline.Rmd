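---
title: "From ECG to hyperbaric stage: the cardiorespiratory analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From ECG to hyperbaric stage: the cardiorespiratory analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`hyperhrv` analyses the cardiorespiratory response of divers exposed to
stepped pressure changes in a hyperbaric chamber, using nothing but a
3-lead ECG. The protocol it targets has five 5-minute stops — 1 atm and
3 atm during descent (`1D`, `3D`), a 5 atm bottom stage (`5`), and 3 atm
and 1 atm during ascent (`3A`, `1A`). From each subject-stage the package
derives nine parameters, converts them to stage-relative changes, and asks
two questions: can a classifier tell which pressure a subject is under,
and which subjects respond unlike the rest of the cohort?

This vignette explains the models and the numerical choices; the README
shows a worked example.

## ECG-derived respiration and the fused respiratory rate

Respiration modulates QRS morphology. Three beat-indexed series are
extracted per lead: the R-wave up-slope and down-slope (ordinary
least-squares line fits in 8 ms windows centred on the steepest samples of
the Q–R and R–S flanks, in mV/ms) and the R-wave angle

$$\phi_R = \arctan\frac{I_{US} - I_{DS}}{0.4\,(6.25 + I_{US} I_{DS})},$$

the angle between the two fitted lines after a fixed axis scaling. The
constants 0.4 and 6.25 are bound to slopes expressed in mV/ms; the slope
units are therefore fixed throughout (`rwave_angle` documents the
convention, and a test verifies the formula against the geometric angle of
the scaled lines). The steepest-sample search maximises the derivative on
the Q–R interval and the derivative magnitude on R–S — a literal maximum
of the signed derivative on the falling flank would land at the interval
edge — with ties resolved to the earliest sample for determinism.

With 3 leads × 3 series, nine EDR signals result. Each is outlier-screened
(values beyond 5 median absolute deviations are dropped), cubic-spline
resampled to 4 Hz, and band-passed to 0.07–1 Hz, the physiologic
respiratory band.

The respiratory rate is estimated every 5 s from 40 s running windows.
Each window yields a Welch spectrum per EDR signal (12 s Hamming
sub-windows, 50% overlap, zero-padded to a 0.0039 Hz grid so the
0.025 Hz accuracy target is resolvable). A spectrum is admitted to the
fused average only if it is *peaked*: at least 85% of the power inside the
reference interval $[F_R(k{-}1) - \delta,\, F_R(k{-}1) + 2\delta]$
($\delta = 0.1$ Hz) must lie within ±0.1 Hz of the selected peak
(criterion A), and the signal's power inside the reference interval must
be within $\lambda = 0.05$ (relative) of the strongest signal of that
window (criterion B). The selected peak is the
candidate nearest the previous estimate among local maxima reaching 85% of
the global peak height. Admitted spectra from the five windows around $k$
are summed and the rate is the fused spectrum's maximum inside the
reference interval, which bounds step changes at $2\delta$ by
construction; if nothing qualifies, the previous rate is held.

Two parameters here are genuinely open and were fixed by calibration on
unit fixtures:

* **Peakness window half-width, 0.1 Hz.** With 12 s Hamming sub-windows a
  pure tone's mainlobe is ≈0.11 Hz wide; a ±0.05 Hz window caps peakness
  near 73% even for a noiseless tone, so the 85% gate would reject every
  spectrum and the tracker would never update. At ±0.1 Hz (the mainlobe
  width) a clean tone scores ≈99% while broadband noise rarely produces a
  qualifying candidate at all. Exposed as `pk_halfwidth`.
* **Criterion B's reading.** The admission rule can be read as comparing
  peakness (rescaled to [0, 1], within $\lambda$ of the maximum) or
  power "close to the maximum"; both are implemented (`criterion_b`), and
  the power reading — measured inside the reference interval, where the
  method looks for the respiratory line — is the default. The peakness
  reading lets a single low-SNR signal carrying a spuriously narrow
  artifact line (e.g. from low-frequency beat-timing jitter) reach
  peakness 100 and evict every correct spectrum from the fused average
  (~0.1 Hz track excursions on the synthetic benchmark); whole-band power
  instead rewards broadband noise. Reference-interval power rewards the
  strength of the respiratory line itself, and the same records track
  within 0.005 Hz.

Three further choices: each admitted spectrum is normalised to unit
total power before summing — the summed-spectra fusion implicitly
assumes commensurate scales, but slope series (mV/ms) and angle series
(rad) differ several-fold in power, and without normalisation one unit
system dominates the fused average instead of the admitted surrogates
voting as an ensemble (the admission criteria always see the raw
spectra); the track is initialised by a majority vote (0.02 Hz
bins) over the nine largest-peak locations of the first window, ignoring
powerless spectra; and pooling is symmetric around $k$ (10 s latency) with
a causal mode (`mode = "causal"`) for on-line use. Symmetric mode fixes
the admission flags with a causal first pass, then re-fuses.

## Heart rate, HRV, and the time parameters

Beats are modelled by integral pulse frequency modulation (IPFM): a beat
fires each time $\int (1 + m(t))\,\bar{HR}/60\,dt$ crosses an integer,
where $m(t)$ is the autonomic modulating signal. The analysis inverts
this: a cubic spline through (beat time, beat index) has derivative equal
to the instantaneous rate, sampled at 4 Hz. The mean rate `mHR` is the
zero-phase 0.03 Hz low-pass of HR, and `HRV = HR − mHR` exactly; a
`normalized` flag returns `(HR − mHR)/mHR`, the mean-rate-compensated
modulation estimate, though the downstream parameters use the difference.

Before any of this, detected beats are cleaned: intervals deviating from a
5-point running median by more than 30% are flagged; adjacent short pairs
summing to the local median are merged (false detection), intervals near a
multiple of the median are split evenly (missed beats), and the remainder
are replaced by spline interpolation (ectopic timing). The rule is a
documented stand-in — the correction literature the study chain relies on
is not restated there — and the 0.3 factor is configurable. The QRS
detector itself is an energy detector (10–45 Hz band-pass, squaring, 80 ms
integration, deterministic two-means threshold, half-threshold search-back
in long gaps); detector identity is not part of the scientific
contribution, and its contract — beat times within 10 ms, ≥99%
sensitivity and precision at 10% noise — is validated against generator
ground truth in the tests.

Four time parameters summarise the NN intervals of each stage's final four
minutes: the median NN, the NN interquartile range, RMSSD, and pNN50. Two
wording-level interpretations are fixed here: scalar statistics are
computed once over the 4-minute window (no inner averaging), and pNN50
divides the count of successive differences above 50 ms by the *interval*
count, following the definition's wording; the conventional
difference-count denominator is available via `pnn50_denom = "diffs"`.

## Orthogonal subspace projection of HRV

Conventional HRV band analysis misreads subjects whose respiratory rate
falls outside 0.15–0.4 Hz, since respiratory sinus arrhythmia then leaks
into the wrong band. OSP separates respiration-driven variance
structurally instead of spectrally: a subspace $V$ is built from the
respiration surrogate and its delayed copies (default delays 0–40 samples
at 4 Hz, i.e. 0–10 s, one-sided; two-sided delays optional), HRV is
least-squares projected onto $\mathrm{span}(V)$ giving the respiratory
component $HRV_R$, and the residual $HRV_\perp = HRV - HRV_R$ carries
everything respiration cannot linearly explain. The decomposition is exact
and orthogonal by construction, so $P_R + P_\perp = 1$ when powers are
normalised by total HRV power. Four frequency parameters follow: $P_R$,
$P_\perp$, and the LF (0.04–0.15 Hz) and HF (0.15–0.4 Hz) band powers of
the residual, from its Welch spectrum, normalised by total HRV power
(residual-power normalisation is a switch; the delay span and
normalisation are config keys because the upstream method leaves them
open). The respiration input defaults to the up-slope EDR signal of the
detection lead; any EDR signal can be substituted. Rank-deficient normal
equations (e.g. near-constant respiration) fall back to a small
documented ridge.

## Stage statistics

Inter-subject scale is removed by the relative change
$R(Y_S) = (Y_S - Y_{1D})/(Y_S + Y_{1D})$ against the baseline stage; it is
bounded, antisymmetric, and undefined only when $Y_S + Y_{1D} = 0$, which
is reported as missing (a subject with such a ratio drops out of the
affected classification task — the same eligibility rule that handles
subjects with missing stages). Each stage's ratios are tested against zero
with a paired Student t test when a Shapiro–Wilk test (gate at 0.05, a
conventional unstated default) accepts normality, and a Wilcoxon
signed-rank test otherwise; stars mark 0.05/0.01/0.001. Across the four
non-baseline stages a repeated-measures ANOVA (or Friedman test when any
stage sample fails the gate) is followed by Bonferroni-corrected pairwise
comparisons over the six stage pairs, reporting directed arrows from the
higher-median stage.

## Classification and anomalous subjects

Five class sets are considered: the sequential pressure contrasts C.3D-5,
C.5-3A, C.5-1A, C.3A-1A, and the three-class C.3DA-5-1A (3D and 3A
merged). Each eligible subject contributes one nine-feature ratio vector
per member stage, so a two-class task over $n$ subjects has $2n$ cases —
this sample structure is forced by the accuracy arithmetic (e.g. 26
subjects, 6 errors, 88.5%). Evaluation is leave-one-subject-out: both of
the held-out subject's samples are predicted by a model trained on
everyone else, with features z-scored by training-fold statistics (the
scale-sensitive families need it, and it mirrors the common
classification-app default). A canary assertion inside the fold guards
against the held-out subject leaking into training.

Four classifier families are used, with hyperparameters chosen as
preset-equivalents and all configurable: LDA with pooled covariance;
Gaussian-kernel SVM with kernel scale $\sqrt{p}$ (i.e. `gamma = 1/p` for
$p$ features) and box constraint 1; cosine-distance 10-nearest-neighbours;
and a discriminant ensemble (DEC) of 30 pooled-covariance linear
discriminants on random `ceiling(p/2)`-dimensional feature subspaces with
majority vote. The ensemble's internal discriminant is cross-checked
against `MASS::lda` predictions in the tests.

Features are chosen by a greedy wrapper: every remaining feature is
appended to the selected set, evaluated by leave-one-out accuracy, and the
best joins the set, ties broken uniformly at random under a fixed seed.
The full 9-point accuracy curve and per-case correctness of every
(family, feature-count) cell feed the anomaly scan: cells with accuracy
strictly above 70% qualify, each subject's misclassifications are counted
across qualifying cells (at most 2 classes × 4 families × 9 counts = 72
slots per two-class task), and subjects above a configurable count cut
(default 20, matching the narrative reading of the richly-populated task
pairs) are flagged as responding anomalously.

## The synthetic cohort: what it emulates, and what it does not

No raw recordings of the chamber study are deposited, so the generator is
the package's test bed. It emulates, per subject and stage: IPFM beat
timing driven by $m(t) = a_{RSA}\sin(\text{resp phase}) +
a_{LF}\sin(2\pi\,0.1\,t)$ plus band-limited (0.03–0.5 Hz) broadband
modulation noise; a respiration signal of known, optionally drifting rate
in 0.07–1 Hz; and a 3-lead ECG built from a cosine-ramp QRS template
whose amplitudes are scaled by `1 + depth × resp(beat time)` — so slopes
and angle all carry the modulation — with per-lead gains, band-limited
additive noise, and optional sub-0.03 Hz baseline wander. Cosine ramps
give each flank a unique steepest point with a near-linear stretch wider
than the 8 ms fit window, making the EDR ground truth analytically
controllable. Beats fire starting at $t = 0$, and the final partial
integral never fires a beat, so a constant 60 beats/min minute contains 61
beats — the documented counting convention.

The cohort template encodes the directions reported for hyperbaric
exposure — heart rate falls with depth and stays low through ascent (NN
longest at `1A`), RSA rises with pressure (peaking at the bottom stage),
LF modulation rises during descent and falls below baseline during ascent,
respiratory rate creeps upward — with multiplicative per-stage factors.
The magnitudes are generator defaults, not measured effect sizes: the
study reports directions and significance, not effect magnitudes, so these
are free parameters chosen once. Baselines (70 beats/min ± 6;
RSA depth 0.045 and LF depth 0.03 with log-normal spread; respiratory rate
0.25 ± 0.03 Hz) sit in the typical resting-adult range and were
constrained to keep RMSSD near 30–50 ms and pNN50 strictly positive — a
near-sinusoidal RSA with RMSSD just below 50 ms produces the degenerate
pNN50 ≡ 0, whose baseline ratio is 0/0 and silently removes the subject,
an artifact no real cohort shows.

Anomalous subjects (6 of 28 by default) draw stage factors with the
autonomic deviations reversed (RSA, LF, respiratory-rate factors at −1
times the normal deviation) and the heart-rate deviation
attenuated-reversed (−0.5 times). Full reversal of every parameter would
make the cohort an exact mirror image: the best possible classifier would
then misclassify every anomalous sample and accuracy would be pinned at
$(n - 2 n_{anom})/n$ regardless of noise. Partial reversal reproduces the
intended phenomenology: anomalous subjects accumulate misclassifications
across the cell grid while the cohort's headline accuracy stays high.

What the generator does *not* emulate: realistic P and T waves (the
template is QRS-only, which flatters the beat detector), pressure and
temperature channels, electrode motion artifacts, non-stationary autonomic
state within a stage, and any nonlinear coupling between respiration and
HRV beyond the linear IPFM pathway. Passing tests therefore demonstrate
that the estimation and classification machinery recovers known ground
truth under controlled conditions — not that the pipeline's physiological
conclusions transfer to real chamber recordings.

## Numerical choices

* **Zero-phase filtering** is done in the frequency domain: a real,
  non-negative response with raised-cosine transition bands applied to the
  FFT of the reflection-padded signal, extended to a 5-smooth transform
  length. This is exactly zero-phase (fiducial timing is never shifted),
  trivially exceeds 40 dB stop-band attenuation, and avoids the ~10^5-tap
  FIR a 0.03 Hz cut-off would need at 2000 Hz. Baseline estimation
  decimates to ~8× the cut-off before filtering and splines back.
* **Welch spectra** are hand-rolled (Hamming, 50% overlap, zero-padding)
  and scaled so the integral matches the variance; a Parseval test and
  line-spectrum tests pin the scaling.
* **Degenerate inputs**: empty fusion selections hold the previous state;
  all-rejected EDR windows and sub-30-interval stage windows are flagged
  undefined rather than guessed; zero-power HRV makes the OSP powers
  undefined; a constant respiration subspace is an error.
* **Tie-breaks** are deterministic everywhere except the wrapper's
  documented uniform-random tie among equal-accuracy features, which is
  seed-controlled.

## Problem sizes

The shipped tests run the full pipeline at the study's scale where it
matters and smaller elsewhere: the respiratory-rate benchmark in the test
suite uses three rates × two seeds at 1000 Hz, while
`scripts/acceptance.R` runs the full grid (eight rates × ten seeds,
five-minute records at the study's 2000 Hz); the cohort property runs
twenty 28-subject cohorts at beat level — features are computed from
ground-truth beats and respiration through the same NN-correction, IPFM
inverse, fusion, OSP and classification code, skipping only ECG synthesis
and beat detection, which the ECG-level tests cover separately.

## Known limitations

The wrapper's greedy order is not guaranteed globally optimal beyond the
step-2 equivalence the tests verify; the DEC composition is a
preset-equivalent reconstruction, not a reimplementation of a published
ensemble; the ectopic-correction rule is a stand-in validated on
constructed cases; and the three-class task C.3DA-5-1A is constructed and
evaluated but, as in the study setting, not expected to be separable with
these features.
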