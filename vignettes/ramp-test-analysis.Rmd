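---
title: "Ramp-test analysis: methods and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ramp-test analysis: methods and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxyramp)
```

## The measurement problem

Exhaustive incremental (ramp) cycling tests are the workhorse assessment of
cardiovascular rehabilitation. A patient sits at rest for 3 minutes, pedals
against a load that starts at 25 W and climbs by 5 W every 20 s (15 W/min)
until volitional exhaustion, then rests for 8 minutes. Three uniformly
sampled channels — muscle oxygen saturation (SmO2, %) from a near-infrared
sensor on the vastus lateralis, oxygen uptake (VO2, L/min) and heart rate
(HR, bpm) — and three discrete series measured every 2 minutes (blood
lactate, systolic and diastolic blood pressure) are recorded throughout.

`oxyramp` turns one such session into a reproducible parameter set:

* **SmO2 landmarks** — baseline, exercise minimum, deoxygenation
  delta/time/slope, recovery maximum, half-reoxygenation level/time/slope,
  and overshoot;
* **cardiorespiratory peaks** — VO2peak (highest 30-s average), HRpeak
  (highest 5-s average), peak aerobic power, and the discrete peaks;
* a **work-matched concentric/eccentric interval-training prescription**
  derived from peak power;
* leg-press **power-test aggregates** and **PRE/POST percentage-change
  reports**.

A synthetic session generator with analytic ground truth closes the loop:
every stage of the pipeline is validated end to end against trajectories
whose landmark values are known exactly.

## SmO2 processing

### Filtering

SmO2 is filtered with a second-order Butterworth low-pass at 0.03 Hz applied
forward and backward (`lowpass_filter()`). The two passes cancel the phase
response exactly — landmark *times* are not delayed — and square the
magnitude response, so the gain at the cut-off is 1/2 rather than
1/sqrt(2). Two implementation details matter at the record edges:

* the record is extended by **point-mirrored reflection** over three
  characteristic periods of the cut-off (100 s at 0.03 Hz) before
  filtering, because the 3-minute rest window sits at the edge of the
  record;
* each pass filters **deviations from the edge value** rather than the raw
  signal, so the start-up transient of the zero-state filter acts on a
  signal of near-zero amplitude. Without this, a constant 70% trace comes
  back off by about 1e-4 even with generous padding; with it, the DC error
  is at rounding level.

The cut-off and order are arguments; `cutoff_hz = NULL` skips filtering
entirely, which is the appropriate setting for noise-free input (see
*Validation design* below).

### Landmark definitions

With the ramp starting at t = 0:

* **baseline** — mean of the filtered signal over the rest window
  `[-180, 0)` s;
* **minimum** — the *last local minimum prior to reoxygenation*. A local
  minimum on the grid is a sample strictly below its left neighbour and not
  above its right neighbour; plateaus take their earliest sample.
  Reoxygenation onset is operationalised as the start of the first rise of
  the filtered signal sustained for at least 30 s **and** gaining at least
  2 percentage points. The amplitude guard exists because residual ripple
  after a 0.03-Hz low-pass drifts slowly: it can rise for longer than 30 s,
  but only by a fraction of a percent, whereas true reoxygenation climbs by
  tens of percent. If no qualifying rise exists (a non-recovering signal),
  the search window extends to the end of the record, where the fallback —
  the global minimum — is the right answer anyway;
* **maximum** — the largest filtered value strictly after exhaustion and
  within the 8-minute recovery window;
* **half-reoxygenation time** — the first crossing of
  `min + (max - min)/2` after the minimum, located by linear interpolation
  between the bracketing samples. If the signal never reaches that level
  the time and its slope are reported missing (flag), never imputed;
* **slopes** — delta over time, reported in %·min⁻¹ (the conventional NIRS
  unit). Both the delta and the time are also reported, so any other unit
  is recomputable.

The derived fields honour their defining identities exactly by
construction: `delta_deoxy = baseline - min`,
`half_level - min = (max - min)/2`, `overshoot = max - baseline`.

### Windowed peaks

`vo2_peak()` and `hr_peak()` slide a window of `window_s * rate` samples
(30 and 5 samples at 1 Hz) across the uniform grid and return the largest
window mean. Irregular input (breath-by-breath VO2) is linearly resampled
to 1 Hz first, with a message. Peak aerobic power is the power of the
*stage in progress* at exhaustion, `p0 + dp * floor(t_exh / step)` — at
the default protocol an exhaustion time of 500 s gives 150 W — not an
interpolated ramp power; stage powers land on the ergometer's 5-W grid,
which is what testing labs report.

## Training prescription

`con_schedule()` emits the 8-week concentric progression: 65% of peak power
with 10 one-minute work intervals (weeks 1–2), 15 intervals (weeks 3–4),
70% (weeks 5–6) and 75% (weeks 7–8), always with one-minute passive rest
between intervals. `ecc_schedule()` multiplies every load by 1.4 (eccentric
pedaling tolerates substantially higher loads at lower metabolic cost) and
trims the interval count to `round_half_up(n_con / multiplier)` so the
external work per session stays matched: 10/1.4 → 7 and 15/1.4 → 11. The
rounding rule generalises to other multipliers and reduces to the identity
at multiplier 1. `work_match_ratio()` makes the residual mismatch explicit:
1.4·7/10 = 0.98 and 1.4·11/15 ≈ 1.027, within 5% of perfect matching for
every week and any peak power (loads scale linearly, counts do not change).

## The synthetic generator

`simulate_session()` emulates the session the pipeline expects
(`kinetics_params()` holds the dials):

* **SmO2**: constant baseline during rest; a normalised logistic decline on
  `(0, t_min)` that hits the baseline at 0 and the minimum at `t_min`
  exactly, with its steepest phase two logistic widths before the nadir
  (desaturation accelerates through the second half of the ramp); then
  exponential reoxygenation `min + (max - min)(1 - exp(-dt/tau))`;
* **VO2/HR**: affine in the instantaneous stage power, frozen at their
  exhaustion values during recovery; an optional first-order lag is
  available but defaults to zero — kinetic realism of these channels is
  not what the generator is for;
* **blood lactate**: quadratic rise from rest to peak on the 2-minute grid
  plus a terminal sample at exhaustion; blood pressure rises linearly on
  the same grid;
* **noise**: additive i.i.d. Gaussian noise, `noise_sd` in SmO2 percentage
  points; every other channel receives noise scaled by the ratio of its
  trajectory excursion to the SmO2 excursion, so one number sets a common
  relative noise level. SmO2 is clipped to [0, 100] after noise.

Defaults portray a deconditioned cardiac patient: baseline 65%, minimum
30% at exhaustion after 500 s of ramping (peak stage power 150 W), recovery
asymptote 70% (5% overshoot), reoxygenation time constant 60 s
(half-recovery ≈ 42 s — recovery kinetics are slowed in cardiac
populations), logistic width 60 s, resting VO2 0.4 L/min with a
10 mL·min⁻¹·W⁻¹ gain, resting HR 70 bpm with 0.5 bpm/W, lactate 1 → 8
mmol/L, 1 Hz sampling, noise 1 percentage point.

Alongside the session the generator returns the **analytically implied
ground truth**: every SmO2 landmark (the recovery maximum accounts for the
finite recovery window, `max_achieved = min + (max - min)(1 - e^{-T/tau})`,
and the half-time for the correspondingly lowered half level), VO2peak and
HRpeak (closed form at zero lag: the post-exhaustion plateau fills a whole
averaging window), stage peak power, and the discrete peaks.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real recordings: physiologically autocorrelated
noise, movement artefacts and optode coupling loss, breath-by-breath
variability, HR/VO2 on-kinetics (by default), device firmware smoothing,
and any plateau or secondary dip around the SmO2 nadir.

## Validation design and a known limitation

Two regimes are tested, deliberately distinct:

* **Noise-free sessions are analysed with filtering disabled.** A filter
  has one job — removing measurement noise — and on noise-free input it
  can only distort. In this regime the landmark definitions recover the
  analytic truth exactly: everything to 1e-3 or better, the half-recovery
  time to within one sample interval of `tau * ln 2` (its crossing falls
  between grid samples; linear interpolation on a curved exponential
  leaves ~2 ms).

* **Noisy sessions run the full default pipeline**, 100 seeded replicates
  at 1% SmO2 noise. Baseline recovers within ±0.25, the minimum within
  +1.1, its time within −9…−5 s.

The half-reoxygenation time is the pipeline's known weak point, and the
cause is structural. The reoxygenation model (and, plausibly, real
recoveries) has a derivative kink at the nadir: the decline flattens into
the minimum at a few %/min while the recovery leaves it at ~40%/min. A
zero-phase low-pass smooths that kink over roughly ±30 s and pulls the
filtered minimum *earlier* — by the upper quantile `b/(a+b)` of the
smoothing kernel, where `a` is the decline slope into the nadir and `b`
the recovery slope. The half-crossing *time* itself is nearly unbiased, so
the half-recovery interval (crossing minus minimum) inherits the whole
minimum-time shift: +6…+12 s at the default kinetics. The trade-off is
intrinsic: sharpening the nadir enough to pin its time inflates the
filtered minimum *value* by `(a+b)` times the kernel's one-sided first
moment instead. Filtered half-recovery times should therefore be read as
systematically long by up to one smoothing half-width whenever the nadir
is kinked; comparisons *between* filtered sessions are unaffected to first
order, since the bias is a property of the trajectory shape, not of the
noise. The test suite asserts the unbiased regimes and documents this one
honestly rather than relaxing it.

Problem sizes throughout were chosen to make the whole suite cheap: 100
replicate sessions of ~1160 samples for recovery, 200 random traces (up to
10⁴ samples) against brute-force window enumeration, 100 filtered traces
against an exhaustive local-minima scan.

## Numerical choices, degenerate inputs, edge behaviour

* Non-uniform sampling is resampled to 1 Hz by linear interpolation,
  always with a message, never silently.
* Ties at the minimum (plateaus) resolve to the earliest sample.
* A flat SmO2 trace yields its first sample with a `degenerate` flag and a
  warning, not an error — downstream code decides what to do.
* A never-recovering signal flags `t_half`/`slope_half` missing; all other
  landmarks are still returned.
* `percent_change()` with a zero PRE value returns `NA` (undefined), never
  an exception and never zero; missing values propagate as missing.
* Session serialisation writes numbers at 17 significant digits; a
  write/read cycle is lossless for doubles, and reports are byte-stable
  for identical inputs.
* Schedule loads are reported to full precision and printed to 0.1 W; no
  rounding to device-settable steps is attempted.

## Limitations

The package computes measurement values and their changes; it performs no
inferential statistics (the study designs this feeds use mixed repeated-
measures models, which belong in a statistics package, not here). Power-
test attempts are opaque scalars — knee-angle trajectories and attempt
validity are judged upstream on the training device and enter only as a
per-attempt validity flag. The generator is a validation instrument, not a
physiological model: conclusions about device firmware, optode physics or
gas-exchange kinetics are out of its reach.
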