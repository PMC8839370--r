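---
title: "IMU gait assessment and its reliability: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{IMU gait assessment and its reliability: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitreliab)
```

# What the package computes

`gaitreliab` turns a standardised two-minute walking assessment, recorded
by three inertial measurement units (IMUs; one on each foot, one at
L5/S1), into a catalogue of 166 gait features, and quantifies how
reproducible each feature is across repeated assessments (test–retest
reliability). The intended population is people after stroke in clinical
rehabilitation, which dictates two design constraints throughout: the
event-detection algorithm must tolerate very slow, weak and asymmetric
gait, and the feature set must remain computable from short walks.

The pipeline has five stages:

1. **Preprocessing** (`preprocess()`): every channel is resampled from
   104 Hz to exactly 100 Hz, the gyroscope is corrected by a constant
   bias estimated from a stationary recording, the first and last two
   seconds are discarded, and the pre-/post-walk standstill periods are
   located by thresholding rolling-mean signal magnitudes. A measurement
   whose residual walking duration deviates from the expected duration
   by strictly more than 10 s is excluded (`validate_length()`).
2. **Orientation** (`orient()`): a gradient-descent (Madgwick-class)
   quaternion filter tracks the sensor attitude from gyroscope and
   accelerometer; acceleration is rotated into the earth frame, gravity
   subtracted, and the axes relabelled vertical (VT, up +),
   medio-lateral (ML, right +) and anterior–posterior (AP, forward +).
3. **Event detection** (`detect_strides()`, `detect_lowback_events()`):
   foot contacts from vertical-acceleration peaks, with a stride-time
   prior from the FFT of ML acceleration, a false-negative repair pass,
   stance/swing segmentation from stationary periods, and a
   false-positive removal pass; lumbar events by integrating and
   band-passing the AP acceleration and matching the foot-derived
   inter-contact template.
4. **Spatial reconstruction** (`zupt_stride_displacement()`):
   zero-velocity-update double integration between mid-stance anchors
   yields per-stride displacement and stride length.
5. **Features and reliability** (`run_assessment()`,
   `reliability_table()`): the 166-feature vector per assessment, and
   per-feature ICC(2,1) with 95% CI, SEM, MDC and relative MDC over a
   two-session cohort.

# The feature catalogue

The catalogue (`feature_catalogue()`) is fixed at 166 uniquely named
features: 56 spatio-temporal, 26 frequency, 63 complexity and 14
asymmetry features, plus 7 general walk descriptors (total distance,
gait speed, overall cadence, and so on). The four named domain counts
sum to 159, so a catalogue of 166 features cannot consist of those four
domains alone; the 7 general descriptors close that gap explicitly
rather than inflating one of the named domains. Per sensor the split is
46 features from each foot, 54 from the low back and 20 combined. The
exact definitions per domain:

* *Spatio-temporal*: per foot, stride/stance/swing/step times, stride
  length and stride velocity, summarised as the mean of per-10-stride
  block means (with block SD and block CV as companion features, the
  final partial block dropped); height-normalised length and velocity;
  cadence. The low back contributes per-foot stride and step times from
  its own matched events.
* *Frequency*: Welch-periodogram dominant frequency, dominant amplitude,
  half-power width and dominant-band power density (feet: VT axis;
  low back: all three axes), plus the index of harmonicity and the
  even/odd harmonic ratio for the lumbar sensor.
* *Complexity*: sample entropy and approximate entropy (m = 2,
  r = 0.2 × SD), stride-lagged autocorrelation and autocovariance, and
  the largest Lyapunov exponent (Rosenstein divergence slope), per
  sensor and axis, on a fixed window of exactly 25 strides
  time-normalised to 100 samples per stride. Gyroscope axes carry
  entropy and Lyapunov features only.
* *Asymmetry*: symmetry index `SI = |P − NP| / (0.5 (P + NP)) × 100` and
  ratio `P/NP` for seven quantities, with P the paretic side and the
  left foot as reference when the paretic side is unknown or bilateral.

The appendix-level definitions of the original catalogue are not part of
the available text, so this catalogue is a reconstruction constrained by
the published totals (166; 56/26/63/14 per domain; 46/46/54 per sensor)
and the feature families named in the accompanying analyses. It ships as
code (one deterministic constructor, exportable to JSON with
`write_catalogue()`) so the manifest cannot drift from the
implementation.

# Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| target rate | 100 | Hz | fixed analysis rate after resampling |
| end trims | 2 | s | transitional movement at start/stop |
| length tolerance | 10 | s | strict exclusion boundary |
| peak distance factor | 0.75 | × stride prior | minimal contact spacing |
| peak height | mean + SD | m/s² | first-pass contact threshold |
| gap factor | 1.5 | × stride prior | triggers false-negative repair |
| repair height factor | 0.75 | × first height | relaxed second pass |
| minimal stance | 0.2 | s | stationary-period definition |
| summary block | 10 | strides | spatio-temporal averaging |
| complexity window | 25 | strides | fixed nonlinear-dynamics window |
| band-pass | 0.25–15 | Hz | lumbar event chain, 2nd order |
| filter gain (beta) | 0.05 | – | attitude correction weight |

All of these surface in `default_config()` and can be overridden from a
YAML file (`load_config()`), which makes the constants auditable and
sweepable. The detection thresholds (mean + SD for acceleration, mean
for gyroscope) are computed over the walking span only; including the
standstill bookends would depress them. The gyroscope stationarity
threshold deliberately omits the +SD term, mirroring the asymmetric
acceleration/gyroscope rule of the original procedure.

# The synthetic-gait generator

Real recordings from the clinical cohort are not distributable, so the
package ships a fully parameterised simulator (`walk_spec()`,
`generate_walk()`) whose outputs carry exact ground truth. Per foot and
stride it synthesises, in the earth frame: a stride-periodic vertical
pedestal peaking exactly at the contact instant plus a sharp 50 ms
contact transient (together `impact_amplitude`, default 10 m/s², with
the transient carrying 30% — sharp enough that sensor noise cannot move
the peak by more than the event-matching tolerance); a biphasic
swing-phase pitch-rate burst whose angle integral returns to zero at
contact; the anterior acceleration of a smooth swing velocity profile
whose integral is the stride length; a small vertical foot-lift with
zero net displacement; and an ML sway sinusoid at stride frequency that
feeds the FFT prior. Stance phases carry zero angular velocity by
construction. The lumbar stream carries a biphasic AP pulse per foot
contact — generated as the derivative of a *zero-mean* velocity
fluctuation, so the integrated, band-passed detection signal has no
onset step and peaks at the contacts — plus vertical step-frequency and
ML stride-frequency components, the latter positive (rightward) during
right steps, which is what lateralisation reads.

Signals are synthesised together with the instantaneous sensor attitude
(swing pitch, lumbar roll, mounting yaw) and rotated into the sensor
frame, so accelerometer, gyroscope and gravity are mutually consistent
for the fusion filter. Gravity, constant gyroscope bias and white noise
are added last. Both feet share one gait-cycle sequence (cycle time =
mean of the per-foot stride times) with the right contact placed
`step_phase` into each cycle: the feet of a walking human are
mechanically coupled, and independently drawn per-foot stride sequences
would drift apart in phase, break contact alternation, and make step
times ill-defined. Gait asymmetry is therefore expressed through
per-foot stance fractions (swing-time ratios) and the step phase, not
through diverging stride-time means.

What the generator does **not** emulate: turns around the walking-path
cones (a flag exists, default off, and its implementation is an
approximation), walking-aid artefacts, soft-tissue and clothing noise,
non-stationary fatigue drift, and genuinely pathological waveform shapes
(clonus, foot drop). Passing tests therefore demonstrate algorithmic
correctness under controlled morphology, not clinical validity on
stroke data.

Two generator-level experiments are worth noting. The *attenuation
experiment* scales the vertical contact waveform of selected strides by
0.4, placing those peaks just below the first-pass mean + SD height
threshold but above 0.75 × of it, which is exactly the regime the
false-negative repair pass exists for; at 0.6 (a value one might guess
first) the attenuated peaks still clear the first-pass threshold and
the repair never triggers. The *test–retest cohort generator*
(`cohort_spec()`, `generate_cohort()`) draws feature values as subject
effect + session noise with known variance components, so the analytic
ICC is available in closed form for parameter-recovery checks.

# Numerical choices

* **Resampling**: rational 104→100 Hz resampling by FIR anti-aliasing
  plus windowed-sinc interpolation, with the FIR group delay
  compensated explicitly; event timing is preserved to the sample and
  band-limited (<40 Hz) energy to within 1%.
* **Peak detection** re-implements the familiar height + distance
  semantics (local maxima, then pruning closer than the minimal
  distance in order of decreasing height); it is verified against an
  independent brute-force selector in the tests.
* **"Integrated and filtered twice"** for the lumbar chain is read as
  one time-integration followed by a zero-phase (forward–backward)
  second-order Butterworth band-pass: double integration would yield
  position, inconsistent with peak-based contact detection, and the
  two-pass filtering keeps event peaks unshifted. Both halves of that
  reading matter for timing.
* **ZUPT**: velocity is integrated trapezoidally between consecutive
  mid-stance anchors, linearly de-drifted to be exactly zero at both
  anchors, and integrated again; a constant accelerometer bias cancels
  exactly under this de-drift.
* **Heading**: the anterior axis is the principal horizontal
  acceleration direction, signed by the skewness of the band-passed
  integrated acceleration along it — forward pushes make that velocity
  positively skewed, whereas slow attitude-drift leakage does not. A
  static pose cannot fix heading, and a raw double-integral sign is
  dominated by gravity-leak drift on the low-power lumbar signal.
* **Stance selection**: when a between-contact gap holds several
  qualifying quiescent spans, the longest is taken (the most stable
  choice); when it holds none, the lower bounding peak is removed and
  the merged gap re-examined.
* **Low-back template matching** projects all targets cumulatively from
  the anchor (consecutive template intervals telescope), so each
  projected contact inherits only the anchor error instead of chained
  snap errors; snapping tolerance is ±25% of the local interval, which
  tolerates stride-time variability up to roughly 15% while excluding
  the contralateral pulse.
* **ICC(2,1)** is computed from the two-way ANOVA mean squares
  (Shrout–Fleiss), its CI by the McGraw–Wong F construction; negative
  estimates are reported as-is, classed "poor", with SEM suppressed.
  Pooled SDs use denominator n − 1 over all test and retest values.

# Problem sizes in the shipped checks

The test-suite and the acceptance script exercise: one full two-minute
assessment (104 Hz, three sensors); a sweep of 50–100 one-minute walks
spanning stride times 0.9–2.5 s, swing-time asymmetry ratios up to 1.4
and accelerometer noise up to ~0.1 g; noise-free walks for ZUPT
accuracy; 200-replicate cohorts of 29 subjects at analytic ICCs 0.3,
0.5, 0.8 and 0.95; and 300-sample entropy fixtures compared against
naive quadratic-time reference implementations. These sizes were chosen
to give stable statistics (Monte-Carlo standard errors well below the
assertion tolerances) while keeping a full run in the minutes range on
one core.

# Known limitations

* The catalogue definitions are a constrained reconstruction, not the
  original appendix; individual feature definitions may differ from the
  source study even though the counts and families match.
* The stride-detection thresholds assume the mean + SD of vertical
  acceleration sits below the contact-peak height; signals whose
  contact peaks barely exceed the background (severe pedal weakness)
  rely on the repair pass, which only reaches down to 75% of the
  first-pass threshold.
* Low-back event detection inherits its stride template from the feet;
  it cannot run stand-alone, and a wrong first-contact anchor shortens
  the matched series by one stride at most under clean conditions.
* The Madgwick-class filter runs without a magnetometer: absolute
  heading is unobservable and is reconstructed from the data, so purely
  lateral or in-place stepping would leave the AP/ML axes undefined.
* Reliability statistics assume the two-way random-effects model;
  heavy-tailed feature distributions or session-by-subject interactions
  are not separately modelled.
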