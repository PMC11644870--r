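# semgfog

Surface electromyography (sEMG) processing and freezing-of-gait (FOG)
precursor detection for wearable lower-limb recordings.

Freezing of gait is a paroxysmal gait disorder of advanced Parkinson's
disease: the feet stop moving despite the intention to walk, often causing
falls. Wearable sEMG garments over the thigh muscles show a characteristic
signature *before* a freeze: the envelope of muscle activity, which normally
oscillates around ±3 mV during walking, collapses to around ±1 mV — a
near 3-fold drop — starting 3–4.5 s before the episode and persisting for
more than 3 s. That lead time is an alerting budget: detect the drop early
enough and the wearer can be warned before the freeze.

`semgfog` implements the full analysis chain for this signal, plus a seeded
synthetic-session generator so the chain can be validated end to end without
patient recordings (which are not publicly available for this kind of
study):

- **io**: a plain-CSV dialect for multi-channel recordings (mV) and
  timestamped event annotations, with video-frame/sensor clock conversion
  (33 frames/s) and alignment.
- **preprocess**: 15–450 Hz Butterworth bandpass (zero-phase or causal),
  optional 60 Hz notch.
- **features**: sliding-window RMS/MAV/peak-to-peak envelopes (200 ms
  window, 10–50 ms step) and a threshold-normalized training load.
- **fatigue**: per-window median frequency (MDF) from a Hann periodogram and
  an OLS trend test — declining MDF indicates emerging muscle fatigue.
- **fog_detect**: the headline analysis. A causal rolling baseline of the
  RMS envelope (trailing median, with in-drop exclusion), hysteresis
  thresholding at 50% of baseline, a >3 s persistence rule, thigh-pair
  fusion (quadriceps + hamstring), matching to annotated FOG onsets, lead
  times, and fold-change quantification.
- **stats**: one-way ANOVA comparisons between activity states
  (active/pause, precursor/normal), at window or episode level.
- **synth**: gait-modulated band-limited Gaussian noise with embedded FOG
  episodes, bicep-curl protocols (10 s pause / 30 s curls / 30 s pause /
  curls) and spectral fatigue compression.

Everything is tibble-first and pipe-friendly; result objects have
`tidy()`/`glance()` methods and `autoplot()` visualizations.

## Worked example

Detect precursors in the first session of the built-in synthetic cohort
(right quadriceps + hamstring, four embedded FOG episodes):

```r
library(semgfog)

ses  <- default_cohort()[[1]]
filt <- bandpass(ses$recording)          # 15-450 Hz, zero phase
env  <- sliding_features(filt)           # 200 ms window, 10 ms step

events <- detect_precursors(env, detector_config(), ses$annotations) |>
  fuse_events() |>                       # require both thigh channels
  match_events(ses$annotations)
events <- fold_change(events, env, ses$annotations)

events[, c("start_s", "end_s", "lead_s", "fold_drop", "fold_change")]
#> # A tibble: 4 x 5
#>   start_s end_s lead_s fold_drop fold_change
#>     <dbl> <dbl>  <dbl>     <dbl>       <dbl>
#> 1    21.3  28.9   3.70      2.88        2.93
#> 2    51.4  57.2   3.61      2.85        2.87
#> 3    81.5  89.1   3.54      2.83        2.92
#> 4   111.  118.    4.02      2.86        2.93

glance(evaluate_detection(events, ses$annotations))
#> # A tibble: 1 x 9
#>   n_onsets n_matched n_false_alarms sensitivity false_alarms_per_min lead_min_s
#>      <int>     <int>          <int>       <dbl>                <dbl>      <dbl>
#> 1        4         4              0           1                    0       3.54
```

All four episodes are caught with no false alarms; each alert starts
3.5–4 s before the annotated onset (the 3–4.5 s alerting window), and
activity during the precursor sits at roughly a third of normal walking
levels (`fold_change` ≈ 2.9).

`run_pipeline()` wraps the same chain (plus MDF and the ANOVA comparison)
into one seeded, logged run that writes CSV/JSON artifacts stamped with a
config hash.

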