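---
title: "Methods: sEMG conditioning, fatigue trending and FOG precursor detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sEMG conditioning, fatigue trending and FOG precursor detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`semgfog` analyses lower-limb surface electromyography (sEMG) for the
signature that precedes freezing-of-gait (FOG) episodes in Parkinson's
disease: a sustained collapse of the activity envelope, from a normal
walking scale of about ±3 mV down to about ±1 mV, beginning several
seconds before the freeze. This vignette describes the processing model,
the tunable parameters and their defaults, what the synthetic generator
does and does not emulate, and the numerical choices made where the design
was genuinely open.

## Signal conditioning

Raw channels are conditioned with a Butterworth bandpass of overall order 4
(two poles per edge), passband 15–450 Hz — the standard surface-EMG band:
below 15 Hz lives motion artifact and baseline wander, above 450 Hz mostly
amplifier noise. The filter family and order are not dictated by the
measurement chain itself, so the package picks the field-standard choice
and exposes both edges and the order in `filter_spec()`.

Two application modes are provided because an embedded implementation would
run causally while offline analysis prefers symmetry:

* `zero_phase` (default): forward–backward passes, no group delay. Inputs
  are odd-reflection padded with three low-frequency periods per side so
  that short fixtures do not show startup transients.
* `causal`: a single forward pass, usable in simulated-real-time replay;
  it carries the usual IIR group delay and a startup transient.

A 60 Hz biquad notch (constant-Q, Q = 30) is available but off by default:
the conditioning chain is defined by the bandpass alone, and the notch
exists mainly to demonstrate removal of the powerline component that the
generator injects.

## Envelope features

`sliding_features()` computes RMS, mean absolute value and peak-to-peak per
200 ms window, stepped by 10 ms (the fine end of the supported 10–50 ms
range; the coarse end suits constrained hardware). The first window starts
at the first sample, times are reported at window centres, and partial
trailing windows are dropped. The 10 ms default maximizes lead-time
resolution; window counts follow `floor((n - w)/s) + 1` exactly and the
features are required (and property-tested) to agree bit-for-bit with a
naive per-window loop.

The training load summary is defined as the time integral of the RMS
envelope over annotated active intervals divided by an isometric reference
amplitude — threshold-normalized activity-seconds. The app-style "level of
effort" figure this stands in for has no published formula; this definition
was chosen because it is dimensionally transparent, monotone in both
duration and intensity, and exactly testable (RMS held at the threshold for
30 active seconds gives a load of 30).

## Median frequency and fatigue

Muscle fatigue shifts the sEMG spectrum downward, so the median frequency
(MDF) of successive windows is the fatigue marker. Each window is
mean-removed, Hann-tapered, and its periodogram restricted to the 15–450 Hz
analysis band; the MDF is the frequency splitting the in-band power into
equal halves, with linear interpolation inside frequency bins.

Two deliberate choices:

* **Window length 1 s**, decoupled from the 200 ms envelope window. At
  200 ms the bins are 5 Hz wide — too coarse near typical sEMG MDFs of
  80–120 Hz; 1 s gives 1 Hz bins. The window is a parameter of
  `mdf_series()`.
* **Plateau convention.** The half-power level can be reached exactly at
  the top of one spectral cluster and not exceeded until the next (e.g. two
  separated equal-power lines). Taking "first bin at or above half power"
  would park the estimate on the lower cluster and is numerically unstable
  under tie-breaking. `median_frequency()` instead averages the
  interpolated first-reach and first-exceed crossings (with a 1e-8 relative
  tie tolerance), which reduces to ordinary interpolation when the
  cumulative power crosses cleanly and returns the plateau midpoint for the
  two-line case — the behaviour expected of a distributional median.

An all-zero window has no spectrum; it yields an `NA` sentinel that trend
fitting skips. `fatigue_trend()` is ordinary least squares of MDF on time
with a two-sided slope test; fatigue is flagged at slope < 0, p < 0.05.
Because envelope and MDF windows overlap when stepped finely, the p-value
is taken as descriptive, not as an independent-sample test.

## Precursor detection

Detection runs on the RMS envelope per channel, causally, so the same logic
could drive a real-time alert:

1. **Baseline.** A trailing 10 s median of window RMS, *excluding* windows
   currently inside a candidate drop — otherwise the baseline would chase
   the drop downward and the event would self-terminate. The first 10 s are
   seeded with the global active-period median. The trimmed mean (20%) is
   available as an alternative statistic.
2. **Hysteresis thresholding.** A candidate drop opens when RMS falls below
   0.5 × baseline and closes when it recovers above 0.6 × baseline. The
   0.5 default sits halfway between normal walking variation and the
   reported 3-fold collapse; the 0.1 hysteresis gap prevents chattering at
   the boundary. Both are `detector_config()` fields.
3. **Merge, then persist.** Candidate drops separated by less than the 2 s
   refractory gap are merged *before* the ≥3 s persistence filter. Order
   matters: at intermediate attenuations the close threshold can be crossed
   briefly inside one genuine sustained drop, and filtering first would
   discard the fragments piecewise. A lone short dip still fails the
   duration filter, so the 3 s persistence rule is preserved.
4. **Fusion.** The consistent signature sits on the thigh; a session-level
   event requires simultaneous drops on at least two thigh channels
   (quadriceps + hamstring), taking the overlap interval. Calf channels are
   treated as less reliable and excluded from fusion by default;
   single-channel mode is available.

Event boundaries are reported as the signal-time support of the
below-threshold windows (first window centre minus half a window, last plus
half). The lead time is measured from this event start to the matched
annotated onset — the start-of-red-window convention; measuring to the
envelope trough would be the main alternative and would report shorter
leads. Matching assigns each event the earliest unmatched onset within a
10 s horizon, earliest event first.

Two fold statistics are reported per event: `fold_drop`, the online
baseline over the in-event mean RMS, and `fold_change`, the offline ratio
of mean RMS over clean reference windows (active intervals minus all event
and FOG spans, with a one-window guard) to mean RMS inside the event. The
RMS ratio is the primary reading of the "n-fold drop"; the peak-to-peak
ratio is reported alongside since the amplitude language of ±3 mV → ±1 mV
could also be read peak-wise.

## State comparison

`one_way_anova()` is the classical fixed-effects decomposition (between/
within mean squares, F-distributed p), computed from sums of squares with
an explicit degenerate branch: all-zero within-group variance returns
p = 0 with a flag rather than an error. `state_comparison()` assigns
envelope windows to states by interval membership, excluding windows that
straddle a boundary (fractional weighting was rejected as needless
complexity), and reports F, p and the ratio of state means.

The sampling unit is genuinely ambiguous for this analysis — a handful of
episodes versus thousands of windows. Both are provided: `unit = "window"`
(default, high power, but overlapping windows are autocorrelated, so p is
anti-conservative at fine steps) and `unit = "episode"` (one mean per
interval; the defensible unit when episodes number ~8). The package makes
no claim to reproduce a specific p-value on real recordings.

## The synthetic generator

The generator produces the signal structure the analysis assumes, not a
biophysical simulation:

* **Carrier**: zero-mean Gaussian noise shaped to 20–400 Hz, matching the
  bandwidth implied by the analysis filter. No motor-unit structure.
* **Gait modulation**: a periodic envelope (cycle 1.1 s, burst duty 0.4)
  with Hann-shaped bursts over a tonic floor of 0.7 of the burst peak, and
  muscle-specific phase offsets (antagonists half a cycle apart). The
  tonic floor models co-activation and background tone; it also keeps
  normal-walking window RMS inside a band (≈0.7–1.0 of scale) that is
  cleanly separated from a 1/3-attenuated regime, which is what makes the
  0.5 threshold a meaningful operating point. Sessions that silenced the
  envelope completely between bursts would put normal walking below the
  alert threshold twice per stride and describe a different signal than
  sustained walking activity.
* **Amplitude semantics**: "oscillates within ±3 mV" is mapped to the 95th
  percentile of |signal| during normal walking — a testable statistic —
  rather than a hard clip; physiological amplitudes exceed nominal bounds.
* **Episodes**: inside [onset − lead, onset + duration] the envelope is
  multiplied by the attenuation (default 1/3, i.e. 3 mV → 1 mV). The drop
  is held through the episode itself; whether activity rebounds during a
  freeze is not established, and keeping the attenuation constant is the
  simplest defensible model. Leads in the default cohort are drawn
  uniformly from 3–4.5 s.
* **Interference**: additive 60 Hz sinusoid (0.05 mV) and slow drift
  (0.2 mV at 0.25 Hz; removed by the 15 Hz edge).
* **Fatigue**: the upper spectral corner decays exponentially with active
  time (per-second rate), realized by overlap-added 1 s blocks filtered
  from one continuous noise stream; MDF then declines in proportion.
* **Curl protocol**: 10 s pause, 30 s set, 30 s pause, 30 s second set;
  Hann repetition bursts (4 s period) only inside sets; pauses at a
  0.05 mV noise floor.

The default cohort is three fixed-seed sessions with 4 + 2 + 2 episodes
(eight in total), onsets on a 30 s grid from 25 s, FOG durations uniform in
2–6 s. Problem sizes throughout (sessions of tens of seconds to ~2.5
minutes at 1 kHz, 10 ms envelope steps) were chosen so that the full
validation suite exercises the complete chain at realistic sampling rates
while remaining quick to run.

What passing tests on this generator demonstrate: the chain recovers the
parameters it embeds (attenuation, leads, episode counts, spectral
compression) under realistic noise, windowing and interference, with
calibrated false-alarm behaviour on null sessions. What they cannot
demonstrate: robustness to electrode lift-off, motion artifact bursts,
inter-subject amplitude variability, or FOG episodes whose precursor
signature deviates from a multiplicative envelope drop. Real-recording
validation remains a separate exercise.

## Degenerate inputs and numerical notes

* Recording ingest rejects NaN rather than imputing; dropout belongs in the
  generator, not silently in the data.
* The recording CSV dialect serializes doubles at 17 significant digits and
  parses with strtod, so write–read round trips are bit-exact.
* All-zero envelopes yield zero baselines and no events (an RMS strictly
  below half of a zero baseline is impossible).
* If a drop outlasts the entire trailing baseline window, the last valid
  baseline is carried rather than recomputed from nothing.
* Identical seeds give bit-identical sessions and pipeline artifacts;
  `run_pipeline()` stamps outputs with the MD5 of the stored configuration.

## Known limitations

* The detector assumes a multiplicative envelope drop; additive offsets or
  impedance drift would need baseline adaptation beyond the trailing
  median.
* Channel fusion is a hard two-channel AND over the thigh pair;
  probabilistic fusion across four muscle groups is future work.
* The window-level ANOVA inherits autocorrelation from overlapping windows;
  use episode-level aggregation for calibrated inference.
* Lead-time accuracy is bounded by the envelope step (10 ms) plus the
  window length (200 ms); reported leads are accurate to roughly ±0.15 s
  on the generator.
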