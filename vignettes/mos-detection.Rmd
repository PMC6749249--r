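---
title: "Detecting moments of stress from wearable GSR and skin temperature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting moments of stress from wearable GSR and skin temperature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosdetect)
```

## The model

Acute stress activates the sympathetic nervous system at two endpoints a
wrist-worn sensor can observe: sweat-gland activity raises the skin
conductance (galvanic skin response, GSR, in microsiemens), and peripheral
vasoconstriction lowers the skin temperature (ST, degrees Celsius) a few
seconds later. A stimulus-driven skin-conductance response (SCR) has a
well-described anatomy: a latency of roughly 1–5 s from stimulus to onset,
a rise of 1–5 s from onset (a local minimum) to peak (a local maximum), and
an asymptotic recovery conventionally summarised by the half-recovery time
(1–10 s, the time from peak to 50% return toward the pre-stimulus level).

`mosdetect` scores every candidate conductance rise in a 1 Hz record
against five rules, each answering with a ternary degree of fulfilment
$sc \in \{0, 0.5, 1\}$:

| rule | signal | full score (1) | partial (0.5) | none (0) |
|------|--------|----------------|----------------|----------|
| R1 rise duration | GSR | positive derivative for 2–5 s | 5–8 s | otherwise |
| R2 temperature drop | ST | ≥ 3 s decrease starting 3 s after the rise onset | decrease starting 2–6 s after | otherwise |
| R3 rising time | GSR | 1–5 s onset to peak | 5–15 s | > 15 s |
| R4 response slope | GSR | $\arctan(\Delta g / \Delta t) \ge 10^\circ$ | $\ge 8^\circ$ | below |
| R5 duration | — | > 10 s since the last accepted event | — | within 10 s |

Each score is multiplied by an importance weight $w_n \ge 0$ with
$\sum_n w_n = 100$ and summed into the total score
$TS = \sum_n sc_n\, w_n \in [0, 100]$. A candidate becomes a **moment of
stress (MOS)** when $TS$ reaches the critical score (default $CS = 75$).
Detections inherit the candidate onset second and that second's GPS fix,
producing a geolocated event stream.

Two readings in the rule set deserve a note:

* **Slope units.** R4 compares a ratio of microsiemens per second with a
  threshold in degrees; the only well-formed reading applies `atan` to the
  ratio and states the threshold on axes scaled in μS and s. The threshold
  is therefore unit-dependent by construction, and the documentation says
  so.
* **R5 as a feasibility constraint.** A stress response spans about 10 s
  (mean latency + rise + half-recovery), so a second MOS within 10 s of an
  accepted one is physiologically implausible. With the shipped weights a
  full-scoring candidate inside the window would still total 85 ≥ 75, so
  R5 is enforced both as a scored rule and as a hard refractory veto:
  emitted sequences always have consecutive gaps above 10 s.

### Weights

The five weights are a multi-criteria judgement, not a published constant.
The shipped defaults `(30, 25, 15, 15, 15)` put most mass on the two
primary indications (the conductance rise and the delayed temperature
decrease) and are deliberately labelled artifact defaults;
`calibrate_weights()` searches the weight simplex and the critical score
against ground-truthed sessions and is the supported route to
study-specific settings.

## Preprocessing

The chain mirrors standard practice for this sensor class:

1. **Imputation** at the native rate: a missing sample is replaced by the
   mean of its nearest valid neighbours. Runs longer than `max_gap`
   (default 1) are a data-quality error; wider gaps can be linearly
   interpolated by raising `max_gap` explicitly. Imputation runs *before*
   filtering because the filters cannot traverse missing samples.
2. **GSR filtering**: first-order Butterworth low-pass at 5 Hz (noise
   removal), then a first-order 0.05 Hz high-pass separating the phasic
   SCR from the tonic level; `tonic = filtered − phasic` holds exactly.
3. **ST filtering**: second-order low-pass at 1 Hz (noise removal) and a
   second-order 0.1 Hz high-pass for the band-limited trace.
4. **Downsampling to 1 Hz**: each integer-second window becomes its plain
   sample mean; edge windows with partial coverage are filled by natural
   cubic-spline interpolation through the complete-window means.
5. **Geolocation**: each second receives the nearest fix in time within
   5 s, else null coordinates (lab sessions carry no GPS and the spatial
   stage is simply disabled).

Three numerical choices matter:

* **Nyquist clamping.** A 5 Hz cut-off cannot exist on a 4 Hz stream
  (Nyquist 2 Hz). Cut-offs at or above Nyquist are clamped to
  0.99 × Nyquist with a logged message, preserving the stated intent — an
  anti-noise stage that leaves the responses untouched — at any input
  rate.
* **Zero-phase filtering.** Filters run forward–backward with steady-state
  initial conditions and odd signal extension, so constants map exactly
  and event onsets are not shifted in time; R2's 3 s delay test depends on
  that alignment. A causal mode (`zero_phase = FALSE`) exists for
  streaming-style use.
* **Which channel feeds which rule.** The rise rules read the phasic
  component (the stated purpose of the separation). The temperature rule
  reads the *low-passed* ST (`st_smooth`), not the fully band-passed
  trace: a 0.1 Hz high-pass removes precisely the multi-second monotone
  decrease the rule tests for, leaving the derivative sign noise-dominated
  (empirically, recall on synthetic sessions drops from 0.99 to 0.62 with
  the band-passed input). Both channels are kept in the table and
  `detect_mos(st_source =)` switches between them. Note also that two
  zero-phase passes of the 0.05 Hz high-pass attenuate a canonical SCR to
  roughly 40% of its injected amplitude; the rules are sign- and
  slope-based, so detection survives, but R4 typically scores 0.5 rather
  than 1 on phasic input.

## Synthetic sessions

`generate_session()` emulates the calibration protocol: a 900 s session
with ten auditory-style stimuli at random times at least 60 s apart (to
avoid overlapping responses), or at explicit pre-determined times. GSR is
a tonic baseline (default 2 μS) with slow drift plus the sum of event
waveforms plus i.i.d. Gaussian sensor noise; each SCR rises linearly over
its rise time and decays exponentially at rate
$\ln 2 / t_{1/2}$, so the value at peak + half-recovery is *exactly* half
the amplitude. ST sits in the plausible wrist range (default 33 °C within
32–35 °C) and drops linearly (default 0.3 °C over 5 s) starting 3 s after
each conductance rise onset, recovering slowly. Successive amplitudes decay
by a habituation factor (default 1 = off). Defaults for noise are 0.02 μS
and 0.02 °C — the scale of the sensor's resolution.

What the generator does **not** model: motion and pressure artifacts,
thermoregulatory and environmental temperature drift, non-stationary tonic
dynamics, and quantisation. Its noise is i.i.d. per sample, which has one
important consequence for interpreting tests: the sign of a derivative of
pure i.i.d. noise is random *at any noise amplitude*, so rule coincidences
(a 2–5 s noise rise plus a chance 3 s temperature decline; pattern
$(1,1,1,0,1) = 85 \ge 75$) occur at a rate that does not shrink with the
noise SD. On default-noise sessions the detector consequently emits a few
extra MOS per 15-minute session alongside near-perfect recall — the same
qualitative behaviour the method shows on real laboratory data, where
induced stimuli are recovered alongside extra detections attributable to
unscheduled stress. The parameter-recovery property (recall and precision
≥ 0.9) is therefore stated and tested at the zero-noise limit, where it
isolates the detection mechanism itself; passing it says the machinery is
correct, not that field precision will reach 0.9.

`generate_track()` adds a GPS track (one fix per second, eastbound walk at
1.4 m/s) with designated stress zones: time windows in which the walker
slows down, so stimuli scheduled inside a zone's window yield MOS located
inside the zone's polygon.

## Hotspot mapping

Located seconds and events are aggregated on a square metric grid
(half-open cells, default 50 m) in a local equirectangular tangent-plane
projection about the data centroid — over the few kilometres of a walking
or cycling session this is metrically indistinguishable from a conformal
projection, and it keeps the package free of external CRS machinery. Each
cell's **MOS ratio** $x_j = n_{mos} / n_{seconds}$ standardises event
counts by exposure time.

The Getis–Ord $G_i^*$ statistic is computed over a binary fixed distance
band that includes the focal cell (default band = 2 × cell size):

$$ z_i = \frac{\sum_j w_{ij} x_j - W_i \bar{x}}
{S \sqrt{\left[ n S1_i - W_i^2 \right] / (n-1)}} $$

with $W_i = \sum_j w_{ij}$, $S1_i = \sum_j w_{ij}^2$ and $S$ the
*population* standard deviation of $x$. The statistic is already a
z-score; cells are classed hot / cold / not-significant by a two-sided
normal test at `alpha` (default 0.05, critical value 1.96). No
multiple-testing correction is applied by default; p-value adjustment can
be layered on by the user since raw z-scores are returned. Degenerate
fields (constant $x$, a single cell, or a band covering every cell) raise
errors rather than returning NaNs. Note that with a binary band the
maximal $z$ can land on a band-neighbour of the event-bearing cells: the
statistic localises clusters at band resolution, not cell resolution.

## Problem sizes and tolerances in the test-suite

The suite generates everything it needs at run time: 900 s lab-protocol
sessions for recovery (20 zero-noise sessions), 100 randomized 300 s
sessions for the score-floor and gap contracts, series of ≤ 60 s and grids
of ≤ 50 cells for brute-force oracle equivalence (agreement to 1e−10), and
an analytic Butterworth magnitude check at 5% relative tolerance (the
digital filter's bilinear warping accounts for under 1% at the probe
frequency used). The phasic/tonic identity is exact to 1e−9.

## Known limitations

* The critical values are tailored to this sensor configuration and are
  not global constants; transfer to other devices needs recalibration.
* Binary output only: no stress-intensity levels.
* No exertion/motion handling; physical activity will be scored like
  stress.
* The weights' provenance is a design judgement; published weights for the
  original calibration do not exist, so numerical reproduction of any
  specific field study's scores is not claimed.
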