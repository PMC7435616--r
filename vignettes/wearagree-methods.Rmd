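---
title: "Methods: posture classification and device-agreement statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: posture classification and device-agreement statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wearagree)
```

`wearagree` implements a counter-based decision-rule classifier for
thigh-worn triaxial accelerometry, the weighted time-reconciliation that
repairs Bluetooth-dropout losses, and the full method-comparison protocol
used to validate one activity monitor against a criterion posture device.
This vignette is the package's account of the underlying model, the choices
that were genuinely open, and what the synthetic-data tests do and do not
demonstrate.

## The classification model

A sensor strapped to the anterior thigh measures gravity plus movement. With
the x axis along the thigh and z normal to it, the **normalized z value**

$$z = \frac{|a_z|}{\lVert \mathbf a \rVert} \in [0, 1]$$

is the gravity projection on the thigh-normal axis: 0 for a vertical thigh
(standing), 1 for a horizontal thigh (sitting), $|\sin\varphi|$ at
inclination $\varphi$ under pure gravity. Only the endpoint semantics pin
this index down; we compute it as the ratio of low-pass-filtered $|a_z|$ to
low-pass-filtered magnitude (causal moving average, `z_smooth_s = 1` s by
default) because that reproduces both endpoints and is robust to the
dynamic acceleration superimposed during movement. Setting `z_smooth_s = 0`
classifies raw readings.

Classification is gated twice: readings outside the configured recording
window (working hours) and readings outside connected Bluetooth intervals
are never classified; they are labelled `unmonitored` and excluded from
totals.

Each monitored reading then drives a small state machine:

* a reading whose dynamic acceleration exceeds `step_trigger_g` (default
  0.2 g above the local gravity baseline) counts as a detected acceleration:
  stepping time accrues and both posture counters reset to 0;
* otherwise the z rule increments exactly one counter — sitting if
  $z > 0.8$, standing if $z \le 0.8$ (the boundary value belongs to
  standing) — and zeroes the other;
* when a counter reaches `counter_limit = 75` readings, the step counter
  stops and the span covered by those readings is committed to that posture.

Several semantic gaps in the decision rules had to be closed:

* **Commit attribution.** Whether the 75 committing readings themselves
  belong to the committed posture is not stated. We attribute them
  retroactively: while the step counter runs, readings are provisionally
  stepping, and a commit relabels the last 75 readings to the posture. This
  is the only choice that conserves time exactly: every monitored reading
  carries exactly one label, so sitting + standing + stepping equals
  monitored duration to the reading.
* **Counter units.** The commit limit is a count of readings, not a
  duration, so `counter_limit` stays in readings (75) and
  `sampling_rate_hz` is configurable independently; at the default 6.25 Hz
  a posture change is recognised after 12 s, and the conservation tolerance
  quoted in the tests ("one counter-commit span") is 75 readings. Firmware
  that polls faster than the accelerometer's nominal rate can be emulated
  by raising the rate.
* **The smoothing question.** The 0.8 rule could apply to raw or to
  smoothed readings; we apply it to the smoothed index (see above) since
  raw 6.25 Hz readings during gait swing through the whole z range. A
  constant stream is unaffected, so the threshold semantics remain exact.
* **Stepping onset.** Stepping time accrues from the first triggered
  reading, with no minimum run: a single spurious trigger costs one reading
  span (0.16 s) before the posture counters rebuild, which is negligible
  against the 12 s commit scale, and robustness to isolated transients is
  the step *detector*'s job, not the state machine's.

State is deliberately forgotten across disconnection gaps: a commit never
reaches back across time the device did not observe.

### The step detector

The commercial firmware's detector is proprietary; `detect_steps()` is an
honest reimplementation of its stated interface: three sensitivity modes,
normal balancing false positives against false negatives. The gravity
baseline (2 s causal moving average of the magnitude) is subtracted, the
positive residual's local maxima are pruned to a 0.3 s refractory spacing
(highest peak first; 0.3 s caps cadence at 200 steps/min), and a preset
threshold then selects events: 0.08 g (sensitive), 0.15 g (normal), 0.30 g
(robust). Candidates and refractory pruning are computed once, independent
of the preset, so the event sets are nested by construction — robust ⊆
normal ⊆ sensitive — which is exactly the ordering the three sensitivity
modes are meant to express. A seated leg stretch produces a sub-0.30 g
transient and is rejected in robust mode.

### Weighted time-reconciliation

When the summed behavior counters disagree with elapsed recording time —
in practice because of temporal sensor disconnections — each behavior is
rescaled by elapsed/recorded time and rounded to whole minutes. The rule is
anchored by its defining example (75/10/15 min counters, 115 elapsed
minutes → 86/12/17), which fixes two details:

* **Trigger.** The discrepancy rule is often phrased as a difference
  *greater than* 15 minutes, yet the anchoring example adjusts at a
  difference of exactly 15; the example wins, and the adjustment triggers
  at $|{\rm elapsed} - {\rm recorded}| \ge$ `adjustment_threshold_min`.
* **Rounding.** The example implies 86.25 → 86, 11.5 → 12, 17.25 → 17,
  i.e. not plain half-even rounding. Largest-remainder rounding is the
  standard scheme that reproduces it while forcing the components to sum
  exactly to the (rounded) elapsed time; ties go to the larger fractional
  remainder, then the larger component, then column order.

A session with zero recorded time but an above-threshold elapsed time is
unadjustable and raises an error rather than inventing totals.

## The agreement protocol

`full_agreement_analysis()` runs, per behavior (sitting, standing, stepping,
plus the per-subject composites stationary = sitting + standing, upright =
standing + stepping, recording = all three):

* **Difference test.** Shapiro–Wilk on the paired differences at
  $\alpha = 0.05$ selects paired t (normal) or Wilcoxon signed-rank
  (otherwise). The level and the gate are overridable; Shapiro–Wilk is
  standard practice at the n ≈ 20 scale this protocol targets. Identical
  differences are reported as degenerate with no p-value.
* **Correlation.** Pearson with the Fisher-z 95% CI when both margins pass
  the same screen; Spearman otherwise, with a Fisher transform of the rank
  correlation and SE $1/\sqrt{n-3}$ (no CI method is prescribed for the
  rank case; this is the simplest defensible one).
* **Lin's CCC**, computed from biased (1/n) sample moments,
  $\rho_c = 2 s_{xy} / (s_x^2 + s_y^2 + (\bar x - \bar y)^2)$, with the
  Fisher-z CI using Lin's asymptotic variance — the most widely used CCC
  interval. Interpretation uses McBride's bands: poor < 0.90 ≤ moderate
  < 0.95 ≤ substantial < 0.99 ≤ almost perfect.
* **Bland–Altman**: mean bias and limits of agreement at bias ± 1.96 SD of
  the differences. The multiplier is fixed at 1.96 (the Bland–Altman
  convention) rather than a small-sample t quantile, keeping the limits
  symmetric and comparable with published tables.
* **TOST equivalence**: the 90% CI for the mean paired difference (two
  one-sided tests at 5%) must lie within ±half-width. The default region is
  15% of the **criterion mean**, rounded half-up to whole minutes. Published
  regions in this literature are stated in whole minutes and are not exactly
  15% of any single printed statistic, so the fractional rule is kept honest
  and an `regions =` absolute override lets a user apply pre-specified
  regions verbatim. Escalation re-tests at 10%, 15%, ... (5% steps) and
  reports the first passing fraction.
* No multiple-testing adjustment is applied, matching per-behavior
  reporting conventions for this protocol.

## The synthetic-data generators

`generate_signal()` emulates exactly the features the classifier keys on:
gravity orientation per posture (sitting $\varphi = 90°$, standing
$\varphi = 0°$, stepping $\varphi = 20°$ from vertical), a linear
orientation ramp of `transition_s = 1` s at bout boundaries (instantaneous
flips would never stress the counter logic), one acceleration burst per
stride (half-sine along the thigh axis, peak `stride_amp_g = 0.8` g,
duration ≤ 0.35 s) at the scripted cadence (default 100 steps/min, ordinary
walking), orientation jitter on the projection scale (SD 0.02) and white
dynamic noise per axis (SD 0.03 g — chosen so that clean sitting/standing
never crosses the 0.2 g step trigger, a > 6 SD event per reading), and
Bluetooth dropouts as a Poisson process of exponential gaps (off by
default). Under this Boolean dropout model the expected monitored fraction
is $e^{-\lambda \mu}$ for rate $\lambda$ and mean gap $\mu$, which is what
the tests check.

`generate_paired_measurements()` draws criterion session totals per behavior
around population means (defaults on the scale of a 3–8 h office workday:
180.5 / 75.4 / 24.0 min for sitting / standing / stepping, with
between-subject SDs 92.1 / 36.1 / 10.5) and sets the test value to criterion
+ bias + Gaussian noise; default biases (−1.66 / −4.85 / +1.15 min) and
disagreement SDs (14.65 / 13.50 / 8.30 min, back-computed from
limits-of-agreement widths of that magnitude) give a realistic
mixed-verdict study. A lognormal criterion option produces the skewed regime
in which the protocol switches to rank-based tests. Negative draws are
truncated at zero; at the default means truncation is negligible.

What the generators do **not** emulate: biomechanically realistic gait
(double support, heel-strike transients, asymmetry), postural fidgeting,
slouched sitting near the 0.8 boundary, sensor reattachment or axis
miscalibration, and correlated (non-white) sensor noise. Passing the
recovery tests therefore shows the decision rules are implemented correctly
and are robust to moderate noise and dropouts — not that the classifier
achieves any particular accuracy on human free-living data; that is what
criterion-device studies are for.

## Numerical choices

* The posture threshold comparison inside the classifier uses a relative
  guard of 256 machine epsilons, so a constant stream exactly at 0.8 stays
  standing despite round-off in the moving average; a genuine excess of
  $10^{-9}$ is still sitting.
* Largest-remainder rounding targets the rounded elapsed time when the
  elapsed value is fractional.
* The causal moving averages use expanding means over the first window, so
  no reading is dropped at stream start.
* Degenerate inputs fail loudly: zero acceleration vectors, non-monotone
  timestamps, zero-variance margins for correlation/CCC, zero recorded time
  in an adjustable session. Readers reject malformed files with the first
  offending line rather than repairing them.

## Problem sizes in the test suite

The suite validates recovery on twenty 240-minute seeded sessions at
6.25 Hz (90,000 samples each), bias recovery on 500-subject simulated
studies, dropout coverage on twenty 2-hour sessions, and exact-oracle
statistics on fixed tables of ≤ 10 pairs — sizes chosen to mirror a
realistic single-workday study while keeping the whole suite under a
minute. The per-reading state machine is compiled (Rcpp), as is usual for
per-sample passes in accelerometry packages; an independent plain-R walk of
the decision rules serves as its oracle in the tests.

## Known limitations

* The classifier recognises posture changes only after 75 quiet readings,
  so bouts shorter than the commit span (12 s at 6.25 Hz) merge into their
  neighbours; the criterion-device epoch representation (15 s) has a
  similar floor.
* Stepping during monitored time that never exceeds the trigger (very slow
  shuffling) classifies as standing; conversely sustained non-gait movement
  (cycling) would classify as stepping. These are properties of the
  decision rules, not of this implementation.
* The CCC interval relies on Lin's asymptotic variance and is approximate
  below n ≈ 10.
* Lying is not distinguishable from sitting with a single thigh sensor; the
  sitting label covers both.
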