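---
title: "Methods: swallow-breathing coordination analysis and its synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: swallow-breathing coordination analysis and its synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(picoswallow)
```

## The problem

Brief optogenetic stimulation of the postinspiratory complex (PiCo) in
anesthetized mice evokes one of three behaviors depending on where in the
respiratory cycle the laser pulse lands: a swallow (during inspiration and
early expiration), laryngeal activation (late in expiration), or no motor
response. The behaviors differ in kind: swallows are all-or-none motor
programs whose duration does not depend on the stimulus duration and which
reset the respiratory rhythm, while laryngeal activation is a graded,
stimulus-locked response that leaves the rhythm essentially untouched.
`picoswallow` implements the complete measurement chain that turns raw
multi-channel EMG/ENG recordings of such sessions into these statements:
signal conditioning, burst and breath detection, per-stimulus behavior
classification, swallow metrics, and respiratory phase/reset statistics.

Because raw in vivo recordings are large and external, the package also
contains a first-class synthetic-session generator with exact ground
truth. All validation in `tests/` runs the full pipeline against
generated sessions; the generator is therefore part of the scientific
artifact, not a fixture.

## Signal conditioning

Each EMG/ENG channel is processed as the recordings were in acquisition
practice:

* **ECG excision** (`remove_ecg()`). Heart artifacts are brief biphasic
  spikes present on every channel. R-peaks are taken from the `ecg`
  reference channel when present (detected on the target channel
  otherwise, requiring at least five regularly spaced spikes), and each
  R-peak-aligned epoch (+/-10 ms) is replaced by linear interpolation.
  Excision runs on the *raw* trace: a compact spike excised after
  band-pass filtering would already be smeared over the ~80 ms FIR kernel
  and escape its epoch. Epochs whose surroundings carry EMG activity well
  above the quiet-signal scale (upper-quartile criterion) are skipped:
  there the artifact is masked by the burst, and excision would punch
  20 ms holes into genuine signal - in development this visibly split
  diaphragm and submental bursts in two.
* **Band-pass 200-700 Hz, 40 Hz transition** (`bandpass_filter()`). A
  linear-phase Hamming-windowed FIR (~3.3 x rate / transition taps)
  applied by FFT convolution with group-delay compensation, hence exactly
  zero-phase; burst timing, on which classification depends, is not
  shifted (verified to < 2 ms on deterministic-carrier bursts).
* **Rectify and smooth 20 ms** (`rectify_smooth()`). Full-wave
  rectification followed by a centered boxcar moving average; the window
  shrinks at the trace edges so length is preserved. Boxcar rather than
  exponential smoothing keeps peak timing symmetric.

## Burst and breath detection

`detect_bursts()` marks maximal intervals where the envelope exceeds
`baseline_mean + k_onset * SD` (default `k_onset = 3`), extends them by
hysteresis down to `k_offset = 1`, merges neighbors closer than 10 ms,
and discards runs under 15 ms (below the shortest 40 ms laser pulse,
above the smoothing scale). Two estimation choices matter:

* the baseline **SD is taken from the rectified, pre-smoothing signal**.
  The smoothed envelope's own spread is several-fold smaller than the
  variability a threshold must clear, and an envelope-SD criterion fires
  on ordinary noise excursions (~20 false bursts per minute in
  development); against the rectified spread, a minute of pure noise
  yields essentially none.
* with no explicit baseline window the statistics are **robust**
  (median, 1.4826 x MAD over the whole trace). The diaphragm channel has
  no activity-free window - breathing is continuous - and robust
  statistics tolerate a sub-50 % burst duty cycle.

`segment_breaths()` delimits respiratory cycles from one diaphragm burst
onset to the next. Diaphragm bursts whose onset falls inside a
swallow-related submental burst are Schluckatmung, not inspirations, and
are removed from the rhythmic train before segmentation.
`exclude_perturbed_breaths()` flags every cycle containing a laser pulse
or water bolus; only unperturbed cycles serve as controls.

## Behavior classification

`classify_response()` applies an ordered rule per stimulus over the
window from laser onset to offset + 500 ms:

1. **swallow** - a submental and a laryngeal burst occur in the window,
   the laryngeal burst outlasts the laser by > 20 ms, and the laryngeal
   peak follows the submental peak (positive swallow sequence);
2. **laryngeal activation** - a laryngeal burst starts within 30 ms of
   laser onset and ends within 40 ms of laser offset, with no diaphragm
   burst starting during the pulse;
3. **no response** otherwise; responses matching neither template fully
   (e.g. reversed peak order) are flagged `atypical` and excluded from
   swallow/laryngeal statistics while remaining in the tables.

The tolerances quantify the verbal definitions ("outlasting",
"onset-to-offset-locked"); all are `analysis_params()` arguments. When
the submental EMG is absent the hypoglossal (XII) ENG is the swallow
channel. Swallow metrics follow the standard definitions: swallow
duration (submental onset to termination), swallow sequence (laryngeal
peak minus submental peak), Schluckatmung duration, laryngeal activation
duration, diaphragm inter-burst interval, and inspiratory delay
(swallow-related laryngeal offset to next inspiratory onset). Amplitudes
are reported as % of max, the per-channel maximum water-swallow burst
amplitude; sessions without a water swallow on a channel are flagged
non-normalizable and left in a.u.

## Phase and reset statistics

The respiratory cycle is diaphragm-onset to diaphragm-onset. Two
quantities are attached to every stimulus:

* **respiratory phase** - time from the onset of the containing
  inspiration to the stimulus, divided by the *expected phase*;
* **phase shift** - duration of the stimulus-containing cycle divided by
  the duration of the nearest preceding control cycle (1 = no reset).

The expected phase is taken as the **mean duration of the session's
control cycles**. The alternative - dividing by the single preceding
cycle, the same denominator as the phase shift - couples the two ratios
through shared cycle-to-cycle noise: with breathing-period CV 0.1 the
correlation between phase and shift is then ~0.23 *under the null of no
reset* (both ratios contain the containing-cycle duration, and the
denominators coincide), which would mimic a weak reset in the non-swallow
group. With the mean-cycle denominator the null correlation drops to
~0.1. Phases above 1 (stimulus in a cycle longer than expected) are
retained in tables but excluded from the ten-bin curves, where they are
counted as overflow; bins are half-open with the last bin closed.

`probability_curves()` bins the per-stimulus class indicators, so the
three class probabilities sum to exactly 1 in every non-empty bin; empty
bins are reported missing, not zero. `reset_correlation()` computes the
Pearson r, least-squares slope/intercept and the two-sided t-test
p-value per response group (swallow vs. non-swallow, the latter pooling
laryngeal activation and no response). A constant shift returns a flat
slope with undefined r; zero phase variance is an error.

## The synthetic-session generator

`generate_recording()` builds a 240 s, 5 kHz session: breathing at
0.7 s +/- CV 0.1; 20 water boluses; then 25 laser pulses at each of
40/80/120/160/200 ms, one pulse every other breath at an independently
uniform respiratory phase (Kolmogorov-Smirnov-testably uniform).
Behavior is drawn per stimulus from a phase-interval policy (defaults:
P(swallow) = 0.8 below phase 0.3, 0.5 up to 0.6, then 0.05 with
laryngeal activation dominating late expiration; the underlying study
reports the preference, not per-bin rates, so these are generator
choices). Key modeling decisions:

* **Durations are lognormal**, moment-matched to the requested mean/SD.
  The reported water-swallow spread (SD 125 ms at mean 290 ms) puts a
  normal's mass below zero, and truncating shifts the mean by ~+7 %;
  the matched lognormal keeps the mean exact and durations positive.
* **Bursts** are amplitude-modulated band-limited oscillations: a
  constant-modulus FM cosine hopping in 300-600 Hz under a tapered
  envelope with raised-cosine ramps (15 ms attack, 25 ms decay,
  motor-unit recruitment scale) and a defined peak. A Gaussian-noise
  carrier was rejected: its 20 ms-smoothed envelope fluctuates ~20 %,
  leaving burst peak times so ill-defined that the submental/laryngeal
  peak order - which real swallow EMG exhibits clearly - flipped in a
  few percent of trials. The ramps place the threshold-crossing edges of
  the smoothed envelope on the nominal burst support, so measured
  durations are centered on the drawn ones (residual bias a few ms,
  amplitude-dependent).
* **All-or-none vs. graded**: swallow (submental) durations are drawn
  independently of pulse duration; laryngeal-activation bursts span the
  pulse scaled by `laryngeal_response_gain` with a few ms of edge
  jitter. A swallow's laryngeal burst is additionally required to outlast
  the pulse (airway protection does not end mid-stimulus).
* **Reset**: a swallow sets the next inspiratory onset to the
  swallow-related laryngeal offset + 0.35 s (+/- 0.05 s), producing the
  slope~1 reset line; a swallow beginning during inspiration truncates
  the ongoing diaphragm burst. Non-swallow trials leave the rhythm
  untouched. A pulse that would still be on when the next inspiration is
  due cannot produce the diaphragm-silent laryngeal pattern; such trials
  are generated as no-response. Without this rule the generator and the
  classifier's own diaphragm-silence criterion contradict each other for
  ~40 % of late-phase long pulses.
* **Amplitudes**: water swallows at 0.8 +/- 0.08 of the channel scale
  define the % of max baseline; laser swallows at 0.45 +/- 0.12
  (floored at 0.25 so every rendered swallow stays above the 3 SD
  detection threshold at the default SNR of 10) reproduce the reported
  ~40-50 % of max contrast. ECG spikes (7 Hz, per-channel gains) and
  white noise (SD 0.1) contaminate all channels.

What the generator does *not* emulate: movement artifacts,
electrode drift, mains hum, inter-animal variability, genuine motor-unit
interference patterns, sensory feedback (water-swallow timing relative
to bolus delivery is schematic), and the 10 s prolonged-stimulation
protocol. Passing tests therefore demonstrate that the measurement chain
recovers known structure under realistic noise, artifact, and timing
conditions - not that it is robust to every failure mode of in vivo
data.

## Problem sizes and numerical choices

The validation suite runs full-size sessions (125 pulses, 20 boluses,
240 s at 5 kHz); parameter-recovery and classifier-fidelity checks pool
three to six seeded sessions (several hundred stimuli), chosen so that
group-mean comparisons are resolved well below their tolerances - e.g.
the all-or-none check compares five per-duration group means of ~60
swallows each, where a single session's ~10 per group would leave the
expected range of the means (~12 %) above the 10 % bound by sampling
noise alone. Filtering uses FFT convolution (power-of-two padding);
analyses are fully deterministic given a recording, and sessions are
bit-reproducible given config + seed (verified down to output bytes).
Degenerate inputs are defined: empty envelopes, single diaphragm bursts,
sessions too short for the protocol, missing channels, overlapping
stimuli and zero-variance regressions all raise typed errors, while an
undetectable ECG artifact only warns and passes the trace through.

## Worked example

```{r example, eval = FALSE}
cfg <- generator_config(seed = 1)
sess <- generate_recording(cfg)
an <- analyze_recording(sess$recording)
print(an)
an$reset$swallow$r        # ~0.85: swallows reset the rhythm
an$reset$non_swallow$r    # ~0.1: non-swallows do not
plot_probability_curves(probability_curves(an$events))
```

## Known limitations

* The burst detector's onset criterion is a stated choice
  (3 SD + hysteresis), not a published parameter; duration measurements
  carry an amplitude-dependent bias of a few ms.
* % of max normalization uses the session's own water swallows; sessions
  without water swallows are not normalized.
* Group-level inferential statistics (ANOVA, post hoc contrasts, sex and
  genotype comparisons) are deliberately out of scope: the package emits
  tidy per-event tables for any external statistics tool.
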