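---
title: "Methods: dual-sensor pulse-wave analysis and Moens–Korteweg pressure estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-sensor pulse-wave analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsewave)
```

## Overview

`pulsewave` processes two-channel arterial pulse waves recorded by
piezoelectric contact sensors placed 2.5 cm apart along the radial artery.
The chain is: FIR band-pass filtering → dynamic-threshold peak detection →
proximal/distal peak pairing into pulse transit time (PTT) and pulse wave
velocity (PWV) → interval-based ectopic (PAC/PVC) flagging → Moens–Korteweg
mean-arterial-pressure (MAP) estimation. A seeded synthetic generator stands
in for the sensor hardware so every stage can be verified against ground
truth.

Conventions used throughout: sample indices are 1-based (native R), time is
`(index − 1) / fs` seconds, amplitudes are millivolts at the ADC input, and
the sampling rate defaults to 5 kHz from a 12-bit converter.

## FIR band-pass design

Taps are the product of an ideal band-pass impulse response and a Kaiser
window:

* ideal response: difference of two sinc low-passes centred at `N/2`, with
  cut-offs `ω_i = 2π f_ci / fs` in radians/sample (defaults 0.7 and 9.5 Hz);
* window: `w[n] = I0(β√(1 − (2n/N − 1)²)) / I0(β)`, with `I0` the order-zero
  modified Bessel function of the first kind evaluated by its power series
  (truncated at a 1e-16 relative term), and `β = 6` by default (≈ −63 dB
  sidelobes once the band is resolved; every property asserted in the test
  suite holds for β between 4 and 9).

Two printed-formula degeneracies are corrected in this implementation: the
sinc must be centred at `N/2` (the value claimed at the centre tap is
otherwise inconsistent), and the Bessel series must start at the zeroth term
(starting at one would give `I0(0) = 0` and a division by zero in the
window). Both corrections restore the standard textbook forms.

### The short-filter caveat

The design-chain default keeps the published window size `N = 128`. A filter
of 128 taps at 5 kHz spans 25.6 ms, so its frequency resolution is of order
`fs / N ≈ 40 Hz` — wider than the whole 0.7–9.5 Hz pass band. The realised
response is therefore not a resolved band-pass but a nearly flat gain of
about 0.22 across 0–10 Hz, with `Σb = 0.222` (no DC rejection) and a gentle
roll-off above ~25 Hz. The same design procedure does realise the corners at
band-resolving lengths: at `N = 16384` (3.3 s of taps), `|Σb| < 10⁻³`,
`|H(5 Hz)| = 0.9999` and `|H(25 Hz)| < 10⁻⁴`; the test suite demonstrates
both regimes.

The short default is kept deliberately: the detection threshold's operating
point (next section) scales with the cube of the filtered amplitude, and the
whole published system is only self-consistent with the ~0.22 in-band gain
the 128-tap filter provides. Swapping in a resolved unit-gain band-pass
would push the threshold far above the pulse amplitude and silence the
detector. Users filtering for other purposes should raise `N`.

Filtering is causal with zero-padded history; symmetric taps delay the
signal by exactly `N/2` samples, which the pipeline subtracts from every
detected index before pairing or scoring.

## Dynamic-threshold peak detection

At each sample the threshold ("gradient") is recomputed over the trailing
window of `fs/2` samples (0.5 s):

```
gradient = RMS · CV / 100 · gain,    CV = Σ(x − mean)² / N,   RMS = √(Σx² / N)
```

`CV` is implemented literally as the population variance (units mV²), so the
gradient carries units mV³/100 and scales with the cube of the signal
amplitude; the constant 100 and the `gain` (default 1) absorb the scale. An
alternative `cv_mode = "std"` (square root of the variance) is provided but
is not the default. The detector itself is a two-state hysteresis machine:
rising mode tracks the running maximum and emits a `peak` (at the maximum)
plus a `fall_onset` (at the current sample) once the signal drops `gradient`
below it; falling mode mirrors this for troughs. Start-up is undecided, with
both running extrema initialised at the first sample and the first
hysteresis crossing deciding the mode; plateaus resolve to their first
sample; events inside the warm-up prefix (threshold window + filter group
delay) are flagged and excluded from scoring.

### Operating-point analysis

Because the gradient is cubic in amplitude, its dynamic range across the
cardiac cycle is the cube of the signal's. With a 100 mV first peak filtered
to ≈ 22 mV, windows containing a systolic complex carry a gradient of a few
mV — comfortably below the ≈ 20 mV peak prominence (detection works) and
above the ≈ 1–2 mV filtered dicrotic rise (the second peak is correctly
swallowed). In late diastole, however, the windowed variance collapses and
the gradient floor is only ~0.03 mV. Three conditions follow, and they
define the regime in which the published detector functions:

1. **the waveform must be AC-coupled with a continuous diastolic runoff**
   (as a real pulse is) so the trailing window always contains signal
   energy; isolated bumps on a dead-flat baseline drive the threshold to
   zero between beats;
2. **interference at the ADC must sit near the quantization floor**
   (≲ 1–2 LSB ≈ 0.1–0.2 mV): any residual ripple above the diastolic
   gradient floor is detected as a train of false peaks between beats.
   This is precisely the regime the analog front end is designed to
   deliver — its 0.58 Hz high-pass removes wander and its second-order
   10.6 Hz low-pass attenuates 60 Hz mains roughly thirtyfold;
3. **the dicrotic notch prominence must stay below the in-phase gradient**,
   else the dicrotic peak is emitted as a separate beat. Strongly notched
   waveforms would be double-counted by this algorithm.

The synthetic generator's defaults (below) emulate a subject inside this
regime; the test suite also probes outside it (see Limitations).

## Beat pairing, PTT/PWV and ectopic flagging

Proximal and distal peak trains are matched greedily: each proximal peak
takes the earliest unused distal peak strictly after it within `max_lag`
(default half the median inter-beat interval). PTT resolution is one sample
(0.2 ms at 5 kHz, i.e. 5% of a typical 4 ms transit); no sub-sample
interpolation is attempted, matching the index-based definition of a peak.

A beat is flagged ectopic when the interval it terminates deviates more than
`relative_tolerance` (default 0.25 — the source method never quantifies
"much larger or smaller", so the tolerance is exposed) from the reference
interval. The reference defaults to the **median** of all intervals, which
is robust to the ectopic intervals themselves; `reference = "mean"`
reproduces the literal "average" wording. A long interval immediately after
a short one is recognised as the compensatory pause following a premature
beat and is not itself flagged (only the premature beat is), matching PAC
physiology; `compensatory_pause = FALSE` restores the plain rule.

## Moens–Korteweg pressure estimation

`PWV² = E·h/(D·ρ)` is inverted for the incremental modulus, and
`E = E₀·exp(ξP)` for pressure, with E₀ = 1428.7 and ξ = 0.031 per mmHg. The
physical units of E₀ are not stated by its source; solving the exponential
law for two independent subjects (D = 1.75/2.35 mm, h = 0.39/0.47 mm, mean
normal-beat PWV 6.34/7.14 m/s, tabulated MAP 83.7/94.8 mmHg) shows the SI
modulus must be divided by 10.00 ± 0.02 in both cases before inversion. That
factor is stored explicitly as `artery_model(unit_scale = 0.1)` — a
documented unit-convention calibration, not physics. With it, both subjects'
tabulated MAPs are reproduced within 0.1 mmHg.

Subject-level MAP is the mean of per-beat estimates (each PWV converted,
then averaged). Since pressure is concave in PWV, this per-beat mean is
always at or below the MAP of the mean PWV (Jensen), which the suite
asserts. A beat whose implied modulus falls at or below E₀ (a grossly
mis-paired PTT) gets `NA` instead of a negative pressure and is excluded
from summaries.

The cuff reference uses `MAP = (SBP + 2·DBP)/3`. Note the source table's
reference MAPs (86.54, 99.2 mmHg) differ slightly from this formula applied
to its own printed SBP/DBP (86.67, 99.33); the package computes, it does not
force agreement.

## Detection scoring

A ground-truth peak is a true positive when an unused detected peak lies
within ±3 samples (0.6 ms); otherwise a false negative. Sensitivity and
accuracy are both `TP/(TP+FN)·100` (no true negatives exist for a continuous
beat stream) and are **truncated**, not rounded, to one decimal:
186/187 = 99.465 → 99.4 and 17/19 = 89.47 → 89.4, which rounding cannot
produce — truncation is the only rule consistent with the published tables.
Detections matching no truth beat are counted separately as false positives
and never mixed into Se/Ac.

## The synthetic generator

`generate_subject()` emulates the acquisition chain end to end: a jittered
sinus beat train, ectopic beats, a fixed integer-sample inter-channel
transit delay, common-mode interference, independent white sensor noise, and
12-bit quantization. Ground truth records each beat's pre-noise first-peak
index and label. Defaults, chosen once on physiological/hardware grounds:

| parameter | default | rationale |
|---|---|---|
| duration, rate | 60 s at 5 kHz | one-minute recordings, ADC rate |
| heart rate, jitter | 60 bpm, 2% SD | resting sinus rhythm |
| first peak | 100 mV | amplified piezo signal at the ADC |
| dicrotic ratio | 0.45 | typical radial reflection peak |
| beat morphology | Gaussian systolic peak (SD 0.07 of a 0.42 s complex), Gaussian-rise dicrotic peak (SD 0.16) with exponential diastolic runoff (τ = 0.8·width) | AC-coupled pulse with continuous runoff; notch prominence inside the detector's working regime (see operating-point analysis) |
| PAC | prematurity 0.6, compensatory pause | premature beat, sinus grid restored |
| PVC | first peak ×0.5, timing normal | first peak attenuated to near the dicrotic peak |
| ectopic rate | 0.05/beat | sporadic ectopy |
| transit delay | 20 samples (4 ms) | 6.25 m/s over 2.5 cm |
| white noise | 0.1 mV SD/channel | ~1 LSB: front end delivers noise at the quantization floor |
| drift | 2 mV at 0.25 Hz | residual wander after the 0.58 Hz analog high-pass |
| mains | 0.1 mV at 60 Hz | pickup after ~32× attenuation by the 10.6 Hz analog low-pass |
| ADC | 12 bits over ±200 mV | LSB ≈ 0.1 mV |

Drift and mains are common-mode across the two channels (they couple through
the shared front end of one wearable device); only the white noise is drawn
independently per channel. The transit delay is applied to the clean signal
before any corruption, so the distal channel is an exact delayed copy up to
noise — in the noise-free configuration the whole pipeline recovers the
programmed delay exactly, which the suite asserts. Quantization is mid-tread
(zero maps to zero, idempotent, error ≤ half a step) with symmetric clipping
at ±(2^(b−1) − 1) steps.

What the generator does **not** emulate: hemodynamic changes of PWV during
ectopic beats (the programmed transit delay is constant, so ectopy does not
perturb synthetic PWV the way it perturbs a patient's), beat-to-beat
morphology variability, motion artifacts, sensor coupling changes, or
respiratory modulation. Passing parameter-recovery tests therefore
demonstrates the correctness of the computation chain, not clinical
performance on real arrhythmia recordings.

## Numerical and design choices

* The analog-front-end calculators implement the standard Helmholtz form of
  the cavity restoring law, `a(x) = −(γSP_A/ρVL)x`; the printed final line
  of that derivation conflates the displacement with the neck length and is
  internally inconsistent, while the chain it summarises is not.
  `ρ_air` defaults to 1.2 kg/m³ (unstated in the source; standard
  conditions, configurable).
* The amplifier-gain calculator returns the plain ratio `R2/R3` as printed,
  without assuming a topology.
* Gradient recomputation is sliding (every sample, incremental cumulative
  sums); block-wise recomputation per window is available as an option. The
  vectorised series is verified against a naive per-sample oracle.
* Warm-up events (first `window + N/2` samples) are excluded from scoring
  and pairing: neither the threshold nor the filter history is settled.
* The detector's streaming state machine is verified against an
  independently written offline hysteresis oracle on randomized smooth
  signals (identical peak sets, 100 trials in the acceptance suite).
* Test problem sizes: synthetic studies use 60 s subjects and 20 seeds;
  oracle equivalence uses 1000-sample signals. The full suite runs in well
  under a minute.

## Known limitations

* **Sub-sample PTT is out of reach at realistic noise.** The filtered
  systolic apex is ~30 ms wide, essentially flat over ±10 samples at 5 kHz.
  Under 2 mV white noise (2% of the first peak) the argmax-based peak
  location jitters with an SD above one sample per channel, so only ~a third
  of beats land within ±1 sample of the true PTT; reaching 95% would require
  sub-sample interpolation, which the index-based peak definition excludes
  by design. The corresponding acceptance expectation is asserted at its
  specified level and fails, documented here. Averaged over a record, mean
  PWV still recovers the programmed value closely (see the README example).
* **The 128-tap default filter is not a band-pass** (analysis above); the
  DC-rejection and unit-mid-band acceptance expectations fail at the printed
  length and pass at band-resolving lengths.
* Beat-level sensitivity at the strict ±3-sample criterion degrades under
  noise for the same apex-flatness reason; the clean-signal case is exact.
* End-of-record diastole (after the final beat's complex) can contribute a
  few spurious detections in the last second of a record, as the threshold
  decays with no further beats arriving.
* Interval-based flagging cannot see PVCs whose timing is normal — they are
  a morphology anomaly; only their amplitude distinguishes them, and
  amplitude-based classification is deliberately out of scope.
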