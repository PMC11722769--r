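# fogr

Analysis tools for **freezing of gait (FOG)** probability signals from
foot-worn inertial sensors in Parkinson disease.

FOG is an episodic absence of forward foot progression despite the
intention to walk. Wearable-sensor pipelines summarise each foot's motion
as a per-sample probability that a freeze is occurring; an FOG **event**
is any time either foot's probability exceeds 0.7, with events separated
by less than 2 s merged into one episode. `fogr` takes such per-foot
probability traces (plus a hip-sensor-derived active-time mask and a task
segmentation) and provides, for researchers and algorithm developers:

* **Event extraction and time-based scoring** — thresholding, gap
  merging, and sample-wise TP/FP/TN/FN durations against video-style
  ground-truth annotations over active time only.
  Accuracy = 100·(TP + TN)/analyzed time;
  %WTSF = 100·(freeze time)/(active walking time).
* **Freeze prediction** — a monotonic-rise rule: an event counts as
  predicted if the probability rises monotonically above a threshold
  τ ∈ {0.20, …, 0.50} within the 3 s pre-onset window, at least 1 s before
  onset; swept over thresholds with per-participant true/false prediction
  rates, mean (SD).
* **Task potency** — how many participants each provocation task (Hallway
  Pivot, Go-Outside-and-Turn, 360° turn; single/dual-task; simulated
  IADLs) elicited FOG in, and the total annotated FOG duration per task.
* **Sampling-rate study** — 21-point Hanning-windowed-sinc resampling
  (100 → 60/30 Hz and up to 128 Hz), a spectral-ratio surrogate detector,
  and per-rate accuracy compared by one-way ANOVA (α = 0.05) with Tukey
  HSD post hoc.
* **Synthetic sessions** — a seeded generator that emulates a full in-lab
  visit (two-foot traces, planted freeze ramps, sub-threshold false rises,
  sedentary periods, optional surrogate tri-axial accelerations), so every
  analysis runs end to end without participant recordings.

See the methods vignette (`vignettes/fog-analysis-methods.Rmd`) for the
models, conventions (half-open intervals, strict thresholds) and design
rationale.

## Worked example

```r
library(fogr)

cfg <- fog_synth_config(seed = 42, false_rise_rate = 2)
gs  <- generate_session(cfg)       # session + ground-truth annotations
ses <- gs$session
ses
#> <fog_session> 72000 samples @ 100 Hz (720.0 s), 630.0 s active, 10 segments, raw IMU: no

comb <- combine_feet(ses$left, ses$right)      # either-foot maximum
ev   <- detect_events(comb, threshold = 0.7, merge_gap = 2.0)
nrow(ev)
#> [1] 18

conf <- classify_time(ev, gs$annotations, ses$active_mask, ses$sampling_rate)
conf
#> <fog_confusion> analyzed 630.00 s: TP 73.90, FP 0.11, TN 555.90, FN 0.09 (s)
accuracy(conf)                                  # 100 * (TP + TN) / analyzed
#> [1] 99.96825
wtsf(ev, ses$active_mask, ses$sampling_rate)    # % of walking time frozen
#> [1] 11.74603

threshold_sweep(list(list(session = ses, events = ev)))
#> <fog_sweep> prediction-rate sweep; mean (SD) across participants
#>  threshold   true_rate  false_rate
#>       0.20 1.00 (0.00) 0.61 (0.00)
#>       0.25 1.00 (0.00) 0.61 (0.00)
#>       0.30 1.00 (0.00) 0.61 (0.00)
#>       0.35 1.00 (0.00) 0.61 (0.00)
#>       0.40 1.00 (0.00) 0.61 (0.00)
#>       0.45 0.00 (0.00) 0.61 (0.00)
#>       0.50 0.00 (0.00) 0.61 (0.00)
```

Reading the sweep: every planted freeze in this session is preceded by a
3 s linear ramp, which crosses τ = 0.2 about 1.7 s before the event onset
(predicted, lead ≥ 1 s) but crosses τ = 0.5 only 0.7 s before onset (not
predicted). The 0.61 false prediction rate reflects the sub-threshold
false rises planted at 2/min: 61 % of counted monotonic rises were not
followed by an event. True and false rates both fall as the threshold
rises.

For the sampling-rate study, generate a cohort with raw accelerations and
run the study end to end (resample → surrogate detector → events →
accuracy vs. fixed truth → ANOVA/Tukey):

```r
cfg <- fog_synth_config(seed = 3, emit_raw_imu = TRUE)
co  <- generate_cohort(cfg, 13, seed = 5)
st  <- sampling_study(lapply(co, `[[`, "session"),
                      lapply(co, `[[`, "annotations"),
                      rates = c(100, 60, 30))
st
#> <fog_sampling_study> 13 participant(s) x rates {100, 60, 30} Hz
#>  rate    accuracy       wtsf
#>   100 96.8% (1.0) 5.7% (1.6)
#>    60 96.8% (1.0) 5.6% (1.6)
#>    30 95.3% (1.5) 4.2% (1.2)
#> <fog_anova> F(2, 36) = 6.621, p = 0.003559 (alpha = 0.05)
```

Tukey HSD flags 30 Hz vs. both 100 Hz and 60 Hz (p ≈ 0.009 each) and not
60 Hz vs. 100 Hz — detection survives halving the rate but degrades at
30 Hz, where the anti-alias filter strips trembling harmonics near the
15 Hz Nyquist.

`run_pipeline(run_config(...))` orchestrates all of the above and writes a
reproducible report bundle (events, sweep, potency, sampling study, stats
JSON, run log); `inst/cli/fog.R` is a thin command-line front end over the
same functions.

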