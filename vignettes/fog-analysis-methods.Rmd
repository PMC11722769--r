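---
title: "Freezing-of-gait probability analysis: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Freezing-of-gait probability analysis: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Freezing of gait (FOG) is an episodic, hard-to-assess symptom of Parkinson
disease: the feet stop progressing despite the intention to walk.
Foot-worn inertial sensors paired with a detection algorithm output a
per-sample probability that a freeze is occurring (a *FOG-probability
trace*, one per foot). `fogr` analyses such traces: it extracts FOG events,
scores them against video-style ground truth on a time basis, asks whether
the pre-onset shape of the trace *predicts* upcoming freezes, summarises
which provocation tasks elicit FOG, and quantifies how detection degrades
when the sensor sampling rate is lowered.

The upstream probability computation itself is out of scope: `fogr`
consumes probability traces (or, for the sampling-rate study, raw
accelerations through a clearly labelled surrogate detector). Because
participant recordings of this kind are rarely shareable, the package
ships a seeded synthetic session generator so that every analysis runs —
and is tested — end to end without real data.

## Event extraction and time-based scoring

An FOG event is any maximal run of samples with probability strictly above
0.7 on the *combined* trace (the pointwise either-foot maximum); events
separated by strictly less than 2 s are merged into one episode,
transitively, until every remaining gap is at least 2 s. Intervals are
half-open `[start, end)` on the sample grid, which makes the bookkeeping
exact: classifying each active sample as TP/FP/TN/FN (by sample-center
containment) conserves `tp + fp + tn + fn = analyzed` to the sample.
Samples flagged sedentary by the hip-sensor mask are excluded entirely.
Ties at exactly 0.7 are non-freeze ("above" is read strictly), and a gap
of exactly 2 s does *not* merge ("less than two seconds" is strict).

Accuracy is `100 * (tp + tn) / analyzed`; percent of walking time spent
freezing is `%WTSF = 100 * freeze time within active samples / active
time`. Per-task figures restrict the confusion to each task segment's
active samples; category and overall figures pool confusion *times* across
segments rather than averaging task percentages, because accuracy is a
time ratio (the two differ when tasks have unequal lengths). Task potency
is assessed on the ground-truth annotations, not algorithm events: per
task, the number of participants with at least one overlapping annotation
and the summed overlapped duration.

## The prediction rule

A freeze is *predicted* when the probability rises monotonically above a
prediction threshold in the seconds before the event onset. Concretely, a
*crossing* of threshold `tau` is the first sample strictly above `tau`
preceded by a non-decreasing run of at least `min_run_s` (default 0.25 s)
starting at or below `tau`; repeated crossings require the trace to return
below the threshold and respect a refractory period (default 1 s). An
event counts as predicted if some crossing falls in
`[onset - window_s, onset - lead_min_s]` with `window_s = 3` and
`lead_min_s = 1` by default; a crossing is a false alarm if no onset
follows within `fp_horizon_s = 3` s. Seven thresholds are swept (0.20 to
0.50 in steps of 0.05, centred on 0.35 — half the 0.7 event threshold),
and per-participant true/false prediction rates are averaged across the
cohort, excluding participants with no events (true rate) or no crossings
(false rate) from the respective denominators.

Several of these quantities are deliberately configurable because the
procedure they formalise is underdetermined:

* *"monotonically"* is not a quantitative notion; we read it as a
  non-decreasing run (flat samples allowed) of configurable minimum
  duration.
* The required lead is 1 s by default, but `lead_min_s = 0` is supported
  because a rise only 0.5 s before detection can still reasonably be
  called an accurate prediction; both conventions are one argument away.
* The lead is measured to the *algorithm's* event onset (the 0.7
  crossing), not the video onset, since prediction targets the detector's
  own alarm.
* No false-alarm horizon is canonical; we use `fp_horizon_s = window_s`
  for symmetry with the pre-onset window.
* Multiple qualifying crossings before one event count the event once;
  crossings are tallied separately, and crossings inside an ongoing event
  are discarded (prediction is only meaningful pre-onset).

On the synthetic ramps (below) these defaults have a closed-form
consequence: a linear pre-onset ramp from 0.05 to 0.95 over 3 s crosses
`tau` with lead `3 * (0.7 - tau) / 0.9` relative to the onset, so
thresholds up to 0.4 are predicted (lead ≥ 1 s) and 0.45/0.5 are not —
the mechanism behind the monotone decline of the true-rate column in a
threshold sweep.

## Sampling-rate conversion

Rate conversion uses bandlimited interpolation with a 21-point sinc kernel
under a Hanning window — the standard anti-aliased "resample" operation.
The cutoff sits at half the lower of the two rates; each output sample's
kernel weights are normalised to sum to one, so constants pass through
exactly, and the input is reflect-padded so the output spans the input's
duration. Up-sampling (e.g. to 128 Hz) uses the same kernel with the
cutoff at the source Nyquist. Masks and annotations are never low-pass
filtered — the activity mask maps by nearest source sample and annotations
live in seconds. Probability traces are clipped back to [0, 1] after
filtering, since a 21-tap kernel has visible ringing. With 21 taps the
transition band is wide (roughly 16 Hz at a 100 Hz input rate), so a 100
to 30 Hz conversion attenuates appreciably from about 10 Hz upward; the
tests check the measured response of sinusoids against the analytically
evaluated kernel transfer function rather than against idealised
brick-wall behaviour.

## Statistics

Overall accuracies across sampling rates are compared with a one-way ANOVA
(α = 0.05) followed by Tukey HSD, both implemented from their sums-of-
squares/studentized-range definitions (with the Tukey–Kramer correction
for unbalanced groups; the studentized range distribution is evaluated
numerically via `stats::ptukey`). Treating the three rates as independent
groups mirrors the repeated-measures data being analysed this way in
practice — a noted simplification, not an endorsement. Normality is
summarised by moment skewness and excess kurtosis. Unit tests cross-check
every statistic against base R's `oneway.test`, `t.test` and `TukeyHSD`
on shared fixtures; the implementations themselves are self-contained.

## The synthetic session generator

The generator emulates a one-visit lab protocol: ten ordered task segments
(Hallway, GOT and 360-degree turn, each single and dual-task; vacuuming,
dishwasher, sitting, community navigation), with sitting sedentary and
masked out of active time. Defaults: 100 Hz, 720 s total, tasks of
45–120 s.

Each planted freeze is a piecewise-linear probability excursion on one
randomly chosen foot (the other stays at baseline, exercising the
either-foot rule): a monotonic ramp 0.05 → 0.95 over 3 s, a 3 s plateau,
and a 1 s decay. The ground-truth onset/offset are the exact 0.7 up/down
crossing times, so with zero annotation jitter, event detection recovers
the truth to within one sample period — the planted-truth consistency that
many tests lean on. Freeze counts per task are Poisson (mean 1.5 per
active task) with an exact-count override for tests; the mean was chosen
so a default cohort's overall %WTSF lands in the mid-single digits,
the scale reported for in-lab sessions of this design. False rises share
the ramp shape but peak at 0.6 (below the event threshold), so they
trigger the prediction rule without ever becoming events; they are placed
clear of true onsets by more than the false-alarm horizon so their labels
are unambiguous. Baseline noise is Gaussian (mean 0.05, SD 0.01) clipped
to [0, 1] — no distributional description of real baseline noise exists,
so these are stipulated, not fitted. Annotation jitter (optional,
truncated so intervals never invert or overlap) emulates rater onset
uncertainty. Everything is a pure function of the configuration and seed.

When raw IMU emulation is enabled, each foot gets a tri-axial acceleration
series: a 2 Hz locomotion sinusoid plus wideband noise while walking;
during freezes, a trembling burst with fundamental drawn uniformly from
3–8 Hz *plus second and third harmonics* (amplitude ratios 0.8 and 0.55 —
trembling is non-sinusoidal, closer to a shuffle than a pure tone) and a
1.5 Hz sway component; near-silence while sedentary.

What the generator does *not* emulate matters for interpreting green
tests: real pFOG traces have autocorrelated, non-Gaussian baselines,
freezes with variable ramp shapes and durations, rater disagreement beyond
simple jitter, and detector-specific artefacts. Passing tests demonstrate
that the pipeline's arithmetic and logic are correct under controlled
conditions, not that any particular detector achieves these accuracies on
patients.

## The surrogate detector and the sampling-rate study

The true probability computation is proprietary to its upstream pipeline,
so the sampling-rate study needs a stand-in that (a) computes at any rate
and (b) plausibly degrades when down-sampling discards spectral content.
The surrogate is a spectral-ratio detector in the freeze-index tradition:
per 2 s sliding window (0.1 s hop), the periodogram power ratio
`Pf / (Pf + Pl)` between a freeze band and a locomotion band (0.5–3 Hz),
squashed through a logistic, gated by a minimum-power floor so sedentary
stretches map to zero, and interpolated back onto the sample grid. It
makes no claim of equivalence to any published detector.

Two calibration choices are load-bearing and deserve justification:

* **Freeze band 3–15 Hz.** The classical trembling fundamental band is
  3–8 Hz, which lies below the Nyquist of every rate studied (15 Hz at
  30 Hz sampling) — a detector measuring only 3–8 Hz would be essentially
  rate-invariant, contradicting the degradation the study is designed to
  expose. Real trembling is non-sinusoidal, with harmonics extending
  toward and beyond 15 Hz; the surrogate's freeze band therefore extends
  to 15 Hz so that this harmonic power is part of the measurement.
  Down-sampling to 30 Hz (anti-alias cutoff 15 Hz, with the 21-tap
  kernel's wide transition band biting from ~10 Hz) strips it; 60 Hz
  leaves it intact.
* **Logistic midpoint 0.75, slope 35.** Measured on generated sessions,
  freeze windows give ratios of 0.80–0.82 at 100 and 60 Hz across the
  3–8 Hz fundamental range, 0.72–0.82 at 30 Hz (higher fundamentals lose
  more harmonic power), and walking gives ~0.14. The logistic's
  0.7-probability point (ratio ≈ 0.774) sits between the degraded and
  intact freeze ratios, so events with high-frequency trembling are missed
  at 30 Hz while everything is detected at 100/60 Hz and walking never
  false-alarms.

Under these conditions a 13-participant study at 100/60/30 Hz shows the
expected pattern: mean accuracy at 30 Hz significantly below 100 and
60 Hz (Tukey p < 0.05 for both), no difference between 100 and 60 Hz —
with an effect size (1–2 percentage points) far smaller than a real
detector's, because the surrogate's failure mode is narrower than real
"smoothing out" of probability nuance. The direction and significance
pattern, not the magnitude, are the reproducible claims. A plug-in
registry lets an external detector (e.g. CSV probability output) replace
the surrogate in the same study harness.

## Numerical conventions and problem sizes

Half-open intervals and 0-based sample indexing are used throughout;
sample `i` covers `[t0 + i/fs, t0 + (i+1)/fs)` and membership is by
sample-center. Report CSVs print times and rates with six decimal places
so identical configuration + seed yields byte-identical bundles. The test
suite works at deliberately modest scales — 30 s traces for the
brute-force oracle comparisons, cohorts of 5 for prediction properties,
13 participants by 720 s sessions at three rates for the end-to-end
study — sizes at which every property is checkable in seconds to a couple
of minutes while still exercising the full pipeline.

## Known limitations

* The surrogate detector is an instrument for studying the *pipeline*,
  not a FOG detector; its accuracies say nothing about clinical
  performance.
* Independent-groups ANOVA on repeated measures inflates the within-group
  variance estimate; a mixed model would be more efficient but is not what
  this analysis tradition runs.
* No video/sensor clock-alignment correction is applied; annotations are
  taken at face value.
* Per-participant threshold personalisation is out of scope.
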