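---
title: "Detecting freezing of gait from subthalamic LFP: models and methods"
author: "fogdetect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting freezing of gait from subthalamic LFP: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Freezing of gait (FOG) is an episodic, unpredictable inability to produce
functional steps that affects many people with advanced Parkinson's disease.
Adaptive deep brain stimulation (aDBS) could in principle respond to FOG as
it develops, but that requires detecting FOG from the sensed neural signal
itself. `fogdetect` implements an end-to-end pipeline that detects FOG
episodes from bilateral subthalamic-nucleus (STN) local field potentials
(LFP): bespoke spectral feature engineering, windowed labelling, a sequence
classifier adapted per trial by transfer learning, leave-one-trial-out
cross-validation (LOTOCV) with timepoint- and event-level evaluation, and
channel-grouped gradient Shapley attribution.

Because the clinical recordings this kind of pipeline is developed on are
not publicly deposited, the package ships a first-class synthetic cohort
generator. Every stage is developed and tested against simulated cohorts
whose ground truth is known exactly.

## The synthetic cohort generator

`cohort_spec()` / `simulate_cohort()` emulate the recording situation of a
sensing-enabled DBS system: six bipolar channels (three per hemisphere,
contact pairs 0-2, 0-3 and 1-3) sampled at 250 Hz, one walking trial per
participant per module (`physical`, `anxiety`, `cognitive`), and a seated
resting recording of at least 20 s per participant.

Each hemisphere is built from four latent monopolar contact signals; the
recorded pairs are emitted as contact differences. This matters: the
downstream channel algebra (reconstructing pairs 0-1, 1-2 and 2-3 as linear
combinations of the recorded pairs) is then physically meaningful, and the
telescoping identity `(0-1) + (1-2) + (2-3) = (0-3)` holds exactly.

Each contact carries:

* a 1/f^alpha aperiodic background (default exponent 2, flattened below
  1 Hz to mimic the device high-pass), unit SD;
* a band-limited oscillation at the participant's peak frequency
  (6 Hz-wide filtered noise; the right hemisphere is offset by +1 Hz),
  amplitude-modulated into bursts, with a contact-dependent gain so the
  bipolar pairs retain oscillatory signal;
* white broadband noise (default SD 0.05).

Bursts arrive as a Poisson process (0.6/s) with exponential durations
(mean 0.25 s outside FOG). During a FOG event the oscillatory amplitude is
multiplied by `10^(fog_power_shift_db / 20)` -- ramped linearly in dB over
`pre_fog_ramp_s` (default 2 s) before the onset, reflecting the gradual
pre-freeze changes visible in clinical probability traces -- and burst
durations are scaled by `fog_burst_scale` (default 2). Burst amplitude
inside FOG is divided by `sqrt(fog_burst_scale)` so that the expected burst
power is unchanged: the configured dB shift remains the sole driver of the
FOG band-power change, which is what lets an independent periodogram oracle
recover it within 2 dB.

Defaults mirror the study design the package emulates: 5 participants x 3
modules (15 trials), trials of 100 s with 1-3 freezes of 5-12 s placed with
at least 3 s separation. Under these defaults roughly 9 of 15 trials end up
with a freeze in both the tuning and the testing partition -- the same
order as the 8 of 15 eligible trials reported clinically. The published
work gives no quantitative effect sizes for FOG spectral signatures; the
generator defaults (+6 dB at the peak, burst durations doubled) are tunable
emulation parameters, not claims about biology.

`heterogeneous_cohort_spec()` is a compact 3-participant x 2-module preset
whose band-power shift flips sign across participants (+7, -7, +7 dB),
emulating the reported between-participant heterogeneity (attribution
plots in the source clinical study show both signs). It is the cohort on
which the value of per-trial transfer learning is demonstrated.

What the generator does **not** emulate: gait kinematics, stimulation or
movement artifacts, line noise, packet loss, nonstationary baselines, or
genuine biophysics of STN circuits. Passing the end-to-end tests on this
cohort shows the pipeline is wired correctly and can learn the kind of
signature it was designed for; it is not evidence about performance on
patient data.

## Feature engineering

All features are per-channel and causal (trailing windows only), computed
on the 12-channel set after per-participant z-scoring:

* **Derived channels** (`derive_channels()`): `0-1 = 0-3 - 1-3`,
  `1-2 = 1-3 + 0-2 - 0-3`, `2-3 = 0-3 - 0-2`, per hemisphere.
* **Z-scoring** (`zscore_participant()`): statistics pooled over all of a
  participant's walking trials. The resting recording is normalized with
  the same statistics so resting-derived thresholds live in the same units
  as the walking data they threshold. A constant channel yields zeros plus
  a warning rather than NaN.
* **Canonical band powers** (`band_power_series()`): delta (1-4 Hz), theta
  (4-8), alpha (8-13), beta (13-30), gamma (30-100), each estimated at
  every timepoint from a single Hann-windowed periodogram of the trailing
  500 / 250 / 125 / 62 / 31 samples respectively, integrated over the band
  by the trapezoid rule. One segment is used because these histories are
  far too short for multi-segment averaging. The literal one-sample step is
  O(N x W); `stride` computes every k-th sample and holds the value, which
  is the documented approximation the cross-validation experiments run
  with (stride 25, i.e. 0.1 s).
* **Participant-specific bands** (`find_custom_bands()`): Welch PSDs (1 s
  Hann, 0.5 s overlap) of the resting recording, a `C / f^alpha` baseline
  fitted per channel over 1-100 Hz *excluding* 8-30 Hz (so the peak cannot
  bias its own baseline), and the largest above-baseline alpha-beta peak
  across each hemisphere's six channels selected. A peak must rise at
  least half the aperiodic level above the baseline; otherwise the
  midpoint fallback of 19 Hz is used with a warning, so a flat spectrum
  cannot halt the pipeline. Three bands of 6 / 10 / 20 Hz bandwidth are
  centered on the peak (edges clipped to 1-100 Hz) and converted to powers
  with a 125-sample history -- the alpha-band history, chosen because the
  custom bands live in 8-30 Hz; the source method states no history for
  them.
* **Rolling statistics** (`rolling_stats()`): trailing mean, min, max and
  sample SD over 0.125 / 0.5 / 2 s windows for every base series, with an
  expanding window during warm-up so no timepoint is missing.
* **Burst features** (`resting_burst_threshold()`, `burst_durations()`):
  the resting threshold is 4x the mean of five medians of
  minima-interpolated squared band-passed copies of the resting channel.
  The five 6 Hz noise bands "spanning 45-63 Hz" are realized as the only
  five-band 6 Hz layout inside that span: 45-51, 48-54, 51-57, 54-60,
  57-63 (3 Hz hop). Walking-trial data are band-passed (6 Hz around the
  trial's alpha-beta peak, zero-phase 4th-order Butterworth), squared, and
  the envelope estimated by linear interpolation through local maxima;
  bursts are maximal supra-threshold intervals. Besides the per-trial mean
  duration, a time-resolved series gives the duration of the burst
  containing each timepoint -- needed for time-resolved attribution
  coloring, since a per-trial constant cannot vary within a trial. Burst
  features are the one non-causal family: envelope interpolation and the
  duration-of-containing-burst definition both look across the whole
  trial, exactly as in the offline source method.

The full composition is 118 features per channel (1 raw + 5 canonical + 3
custom + 12 rolling statistics of each of those 9 + 1 burst series), 1,416
over 12 channels. The clinical study states 1,020 features split evenly
over 12 channels (85 per channel), which is not recoverable from the
composition it describes; the discrepancy is documented rather than
resolved, and `feature_config()` makes the composition explicit and
configurable. `reduced_feature_config()` (canonical + custom + burst, 108
features, stride 25) is the composition the cross-validation experiments
run on.

**Correlation pruning** (`prune_correlated()`): pairs with |r| > 0.95 over
the pooled cohort timepoints are visited in deterministic sorted-name
order and one member of each surviving pair is dropped by a seeded
generator -- "at random", but reproducibly. Pruning is done once per
cohort, as in the source pipeline.

## Windows and labels

Time is trial-relative with t = 0 at the first sample; FOG intervals are
half-open `[start, end)`, so boundary samples are labelled unambiguously.
Trials are truncated to at most 10 s of non-freeze before the first and
after the final freeze. Feature matrices are segmented into 3 s windows at
0.5 s steps, each labelled by its final timepoint.

Two grid conventions exist, and their difference is deliberate:

* **training**: ends at 3.0, 3.5, ... s after the span start -- every
  window has a full in-span history. Training windows whose 3 s history
  would cross the truncation boundary are simply not generated in-span;
  windows at the span start use back-filled warm-up when the grid demands
  them (prediction mode).
* **prediction**: one grid point every 0.5 s from the test-span start
  through its end inclusive (count = span / 0.5 + 1), drawing the trailing
  history from the preceding (tuning) samples. This is the unique
  convention under which the eight published test-set durations yield
  exactly the published total of 902 windows, which the acceptance suite
  verifies.

Class weights are balanced inverse frequency, `n / (2 * n_c)` (the source
names none). Tuning data are augmented with two Gaussian-jitter copies
(SD = 1% of each feature's SD over the input windows), tripling the set.

## The classifier

`model_spec()` / `build_model()` define a sequence classifier containing
every component named for the clinical model, at the smallest sizes that
exercise them (layer order and sizes are this package's choices; the
source describes components, not an architecture diagram):

1. a three-block convolutional stack with multi-scale kernels (7 / 5 / 3).
   The first block is dilated by 25 samples -- the band-power stride -- so
   its receptive field covers 0.7 s of genuinely varying feature history,
   and strided so the 750-sample window is reduced to a 6-step latent
   sequence of 32 channels;
2. sinusoidal positional encoding;
3. one transformer block (2-head self-attention + feed-forward, residual
   connections and layer norm);
4. a cross-attention block in which the transformer output queries the
   convolutional features;
5. a bidirectional GRU (16 units per direction) whose input concatenates
   the attended sequence with the convolutional features (the shortcut
   connection), mean-pooled over time;
6. a dense head and a temperature-scaled sigmoid. The temperature is a
   single learnable scalar dividing the logit (initialized at 1); whether
   the source learned or fixed it is unstated, and learning it is the more
   general choice. Lowering the temperature moves probabilities away from
   0.5 without changing any 0.5-threshold decision, which the tests
   verify.

The network, its backward pass and the Adam optimizer are implemented in
plain R matrix code; correctness rests on finite-difference gradient
checks over every parameter block in the test suite. Training minimizes
class-weighted binary focal cross entropy (focusing parameter gamma = 2, a
standard default the source does not override, combined multiplicatively
with the class weights) for up to 100 epochs at learning rate 1e-3, with
learning-rate halving on training-loss plateaus and early stopping on a
stratified 10% validation split.

**Transfer tuning** freezes the first two layers -- read literally as the
first two convolutional blocks -- drops the learning rate to 5e-6 and
trains up to 100 further epochs on the held-out trial's augmented opening
segment. The early-stopping monitor for tuning is the untouched tail (15%)
of the raw tuning windows rather than a random split: a random split would
place jittered copies of training windows in the monitor and make it
worthless. Frozen parameters are bit-identical before and after tuning.

## Cross-validation and evaluation

`plan_lotocv()` holds out each trial once. Its first 40 s (after
truncation -- processing precedes partitioning) are the tuning set, the
remainder the test set; the training set is every other trial of the same
participant plus every other participant's trials of the same module.
Trials lacking a freeze in either partition are excluded, with the reason
recorded. Before modelling, band-power features are mapped to log power
and all features standardized with statistics pooled over the fold's
training trials only -- the held-out trial never informs its own scaling.

Evaluation mirrors the clinical report:

* **timepoint level** (`timepoint_metrics()`): confusion metrics on the
  0.5 s grid at probability threshold 0.5 (sensitivity, specificity,
  precision, macro and support-weighted F1);
* **event level** (`event_detection()`): a freeze is detected when at
  least 25% of its in-event grid predictions are at or above 0.5; the
  looser any-positive count is reported alongside. Events containing no
  grid point are flagged and excluded from denominators;
* **threshold selection** (`select_event_threshold()`): the detection
  fraction maximizing the Youden index subject to specificity >= 0.5.
  The source does not define event-level specificity; here the non-FOG
  gap intervals between freezes act as negative events, a gap counting as
  falsely detected when at least the candidate fraction of its grid
  predictions is positive. Ties go to the smaller fraction;
* **false-positive taxonomy** (`fp_taxonomy()`): each false positive is
  early-onset (within 2 s before an onset, in an unbroken positive run
  continuing through it), overextension (within 2 s after an offset,
  contiguous with in-event positives), or isolated;
* **aggregation** (`aggregate_report()`): sums for durations and counts,
  unweighted means for rates and F1 scores -- the convention that
  reproduces the published summary row from its per-trial rows.

## Problem sizes and numerical choices

The shipped experiments are sized for a single CPU: the easy cohort (15
trials of 100 s, 108 features before pruning) runs full LOTOCV in a few
minutes; the test suite replicates it over five training seeds with the
eligible folds rotated across seeds (two per seed, so every trial is held
out under some seed), and replicates the heterogeneous comparison fully
per seed. The acceptance script runs one full easy-cohort LOTOCV and five
heterogeneous comparisons. Tolerances: oracle equivalence at 1e-6
relative; generator spectral fidelity at 2 dB for shifts of at least 3 dB
measured on freezes of 15 s or more; Shapley additivity at 0.02 absolute
on the probability scale. Degenerate inputs (constant channels, flat
spectra, all-silent signals, single-class labels, events without grid
points) each have a defined behaviour -- zeros with a warning, the 19 Hz
fallback, a zero threshold, an error, and exclusion, respectively.

## Attribution

`estimate_shap()` approximates Shapley values by expected gradients:
integrated gradients (midpoint rule, default 8 steps) along the straight
path from each background window to the explained window, averaged over a
seeded background set drawn from the fold's base-training windows (default
100; the source states only that references come from the training set).
The baseline is the mean model output over the same background windows, so
baseline + sum of contributions approximates the prediction (local
accuracy; the estimator is not exact, and 0.02 on the probability scale is
the documented tolerance). `group_by_channel()` sums contributions over
each channel's features -- an exact partition of the feature set -- and
`partial_dependence_table()` produces one row per window-timepoint with
the summed raw values of a channel's band-power features (and their
rolling metrics) against their summed contributions, colored by the
channel's time-resolved burst duration.

On the heterogeneous cohort, participants with opposite-signed FOG power
shifts produce opposite-signed raw-versus-attribution associations in
these tables -- the qualitative signature of participant-specific FOG
neurophysiology that motivates the per-trial transfer-learning design.

## Known limitations

* The synthetic signatures are far cleaner than patient LFP; reported
  synthetic F1 scores say nothing quantitative about clinical performance.
* Burst features are offline quantities (non-causal by construction),
  matching the source method but meaning they could not be computed as-is
  in a streaming implant.
* The classifier is deliberately small; at this scale the 5e-6 tuning
  rate moves parameters little, and transfer gains on the heterogeneous
  cohort are consistent but modest.
* The 1,020-feature total stated by the source cannot be reconciled with
  its own described composition; the package documents both numbers and
  makes the composition configurable.
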