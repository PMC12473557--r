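---
title: "Methods: evaluating wireless vital-sign sensors against a wired reference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evaluating wireless vital-sign sensors against a wired reference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neowear)
```

## The evaluation problem

A wireless pulse oximeter can only replace the wired bedside monitor in a
NICU if it is judged on three axes simultaneously: *feasibility* (how much
of the planned monitoring period actually produced signal, how long the
interruptions were, and why they happened), *safety* (whether days of wear
change the skin under the sensor), and *accuracy* (whether its SpO₂ values
would lead a clinician to the same decision as the reference). `neowear`
operationalizes each axis over one common data model — the
`dual_day_recording`, holding five uniform-rate channels with explicit
missingness, bedside annotations, device alert flags and a planned duration
(8 h by default) — so that the three analyses always refer to the same
synchronized time base.

Two representation rules keep the downstream arithmetic unambiguous. Time is
seconds from the recording epoch with half-open sample intervals
`[t, t + 1/rate)`, so gap durations and coverage sum exactly. And
missingness is an explicit per-sample marker (`NA`), never a sentinel value:
a gap analysis must be able to distinguish "the device said 0" from "the
device said nothing".

## Pre-processing

Channels are ingested at their device rates (wired PPG nominally 75 Hz,
wireless PPG 64 Hz, SpO₂ and FiO₂ 1 Hz) and analysed on a common grid
(64 Hz for PPG comparisons, 1 Hz for SpO₂). `resample_channel()`
interpolates PPG linearly between valid neighbouring samples and assigns
SpO₂/FiO₂ by nearest neighbour within ±0.5 s — half the 1 Hz sample
interval. Crucially, *no value is ever synthesized across missing data*: an
output point whose bracketing input samples include a missing sample stays
missing, so resampling can never shrink a gap.

`synchronize_recording()` estimates a single constant wired-wireless clock
offset as the lag (±120 s searched at 1 s resolution) maximizing the
cross-correlation of the mean-removed SpO₂ traces, and shifts the wireless
channels and flags by it. A constant-offset model (no drift term) is
deliberate: the acquisition platforms this package targets discipline their
sample clocks upstream, and the synthetic generator uses a common clock, so
a drift model would add parameters the data cannot identify. Flat traces
have no correlation peak and raise an error instructing the caller to pass
the offset explicitly.

## Feasibility

A **gap** is a maximal missing run whose duration *strictly* exceeds the
channel threshold — 31.25 ms (two 64 Hz samples) for PPG, 2 s for SpO₂ —
the strict inequality being the literal reading of "exceeding". Leading and
trailing missing time counts toward gaps relative to the planned duration,
because coverage is defined against the monitoring period a clinician
planned, not against whatever the device happened to record; long start-up
outages are precisely what this choice surfaces. Missing runs separated by
a single valid sample remain distinct gaps (no bridging): determinism and a
trivially checkable conservation law — `coverage_pct` plus gap-time
percentage equals 100 to 1e-9 — were preferred over cosmetic merging.

**SNR estimation.** PPG quality is scored in 30 s windows with 50% overlap.
Per window, the periodogram of the mean-removed valid samples is searched
for its cardiac peak in 1–4 Hz (90–240 bpm, the neonatal range); signal
power is the power within ±0.3 Hz of the fundamental and its first
harmonic, noise power is the rest of 0.1–10 Hz, and SNR is their ratio in
dB capped at ±40. Windows under 50% valid are skipped. The estimator is
scale-invariant (both powers scale together) and its parameters are
arguments, not constants: the bands, window and cap are this package's own
documented choices for a quality score whose only downstream use is the
0 dB decision threshold ("noise exceeds signal").

**Attribution.** Each gap gets one cause, first matching rule wins:
overlap with a padded `BT_DISCONNECT` flag → `BD`; overlap with a padded
SR/SA annotation → `SR_SA`; mean SNR below 0 dB over the windows whose
centers lie within one window length of the gap → `LOW_SNR`; else the
fallback (`UNKNOWN`, or `CABLE` for wired channels, whose residual gaps are
cable disconnections). The precedence BD > SR/SA > LOW_SNR > fallback orders
the rules by evidence specificity — a hardware flag is direct evidence, an
annotation is an observer's report, low SNR is circumstantial. The ±5 s
context padding absorbs small timing disagreements between flags,
annotations and the snapped gap boundaries, and is configurable. The SNR
rule deliberately includes windows *inside* the gap: when a low-quality PPG
suppresses the derived SpO₂, the PPG itself keeps streaming, and those
windows carry the evidence. Activity context is the annotated care activity
(KC/RC/PAU/O) covering the gap midpoint.

## Safety

Before/after NSCS assessments are paired per (infant, day);
`wilcoxon_signed_rank()` tests the paired changes. Its defaults — zeros
dropped, mid-ranks on tied absolute differences, normal approximation with
neither tie correction nor continuity correction, direction
before − after — are the unique common convention set under which the
canonical worked distribution (3 decreases, 63 no-changes, 7 increases of
one point) gives z = −1.12; each convention is an argument with the
alternative (Pratt zero handling, tie-corrected variance, continuity
correction, either direction) implemented and documented. Note the
two-sided normal p for that z is 0.26; the frequently quoted 0.13 is the
one-sided value. Day-level pairs are treated as independent observations, as
a pooled n = 73 test implies; a per-infant aggregation is a caller-side
`aggregate()` away but is not the default.

## Accuracy

`pair_samples()` keeps exactly the 1 Hz instants where both devices report
a valid SpO₂. Differences are `wired − wireless`, so a *positive* bias
means the wireless sensor reads lower — the orientation under which a
positive published bias and the narrative "wireless tended to read lower"
agree. `bland_altman()` reports the mean bias, the sample SD of differences,
limits of agreement at bias ± 1.96 SD (the conventional multiplier; no
repeated-measures adjustment is made because days are summarized first and
aggregated by median/IQR, not pooled), MoE = 1.96 SD and MAE.
`aggregate_daily()` uses linear-interpolation quantiles.

The **modified Clarke error grid** classifies each pair from the clinical
states of the two values. Room-air days have two states (alarm at ≤ 91%,
else normal); supplemental-oxygen days have three (low at ≤ 88%, high above
95%, else in range) — the boundary placement reads "target > 91%" as alarm
*at* 91 and "> 88% and ≤ 95%" as low at 88, high strictly above 95. Same
state and |difference| ≤ 5 percentage points → A; same state but further
apart → B; reference alarming while the test device reads acceptable → D
(failure to treat); the reverse → C (false alarm); opposite alarm states →
E. Two resolutions the region table leaves implicit are fixed here: "within
5%" is an absolute band in percentage points (SpO₂ grids are conventionally
absolute, and an inclusive ≤ keeps integer data off knife edges), and state
agreement takes precedence over the numeric band, so near-threshold pairs in
different states are C/D/E however close their values. With two states,
region E is geometrically unreachable on room air — asserted by brute-force
enumeration in the tests. Oxygen grouping is per recording day, not per
infant, since a single infant can cross the FiO₂ > 0.21 majority criterion
between days.

The per-metric "effect size" sometimes printed beside such tables has no
standardized definition; `mdd()` implements one candidate — the minimally
detectable difference `(z₀.₉₇₅ + z₀.₉₀)·SD/√n` at α = 0.05 and 90% power —
as an explicitly experimental helper that no default report includes.

## The synthetic generator

`simulate_day()` produces a `dual_day_recording` plus ground truth. It
emulates the *statistical structure the analysis assumes*, not physiology:

* **PPG**: a periodic pulse (fundamental at the heart rate, default
  150 bpm, plus one harmonic at half amplitude) in white Gaussian noise
  whose variance is set per schedule segment so that the band-power SNR
  seen by `estimate_snr()` matches the scheduled value — white noise spreads
  evenly across the Nyquist band, so the variance is scaled by the ratio of
  the half-band to the estimator's 0.1–10 Hz noise band.
* **SpO₂**: a mean-reverting (Ornstein–Uhlenbeck-style) baseline around 97%
  with a 5 min relaxation time and small innovations, chosen to mimic the
  autocorrelation of monitor-averaged saturation; raised-cosine
  desaturations (default 2/h, depth 10 points, 60 s); the wireless trace is
  the wired trace minus the device bias (default 1.34 points) plus Gaussian
  sample noise (default SD 2.0 points), both clipped to [0, 100]. Because
  the wireless trace is built from the wired one, the baseline cancels in
  the differences and the Bland–Altman estimator must recover exactly the
  injected bias and noise — the basis of the recovery tests.
* **Gaps**: Bluetooth dropouts as a Poisson process (default 2/h,
  exponential 30 s durations) applied to both wireless channels with
  matching `BT_DISCONNECT` flags; listed SR/SA intervals applied to the
  wireless channels with matching annotations; a sparse cable process
  (default 0.07/h) on the wired channels; and wireless SpO₂ additionally
  loses every period whose scheduled wireless SNR is below 0 dB — the
  dominant gap mechanism in real wireless recordings. The default wireless
  SNR schedule alternates +4/−4 dB with 30% of time low, yielding wireless
  SpO₂ coverage around 70%. All injections are snapped to the sample grid
  and recorded half-open in the ground truth, so gap recovery can be tested
  for *exact* boundary equality; injections of different mechanisms are
  kept at least twice the context padding apart so each cause remains
  identifiable by the attribution tree — the generator's job is to make
  attribution testable, not to model pathological coincidences.
* **Skin scores**: before-scores concentrated on 3 (96%) and 4 (4%), with a
  change of −1/0/+1 drawn with probabilities 3/73, 63/73, 7/73 and clamped
  to the 3–9 support.

One seed drives every draw of a simulated day. What the generator does
*not* emulate — motion-artifact waveform morphology, clock drift, jitter in
the nominal 75 Hz wired rate, correlated bias that varies with saturation
level — bounds what the closed-loop tests can show: they validate the
estimators' correctness, not any device's field performance.

## Problem sizes and numerical choices

The recovery tests run at full 8 h scale (one day: 28,800 SpO₂ pairs,
~1.8 M wireless PPG samples) where the contract demands it — bias within
±0.1 points, MoE within 5% relative, SNR within ±1 dB — and at 10–30 min
scale elsewhere; the pipeline tests use a handful of 20 min days, which
exercise every code path identically. Tolerances of 1e-9 guard exact
conservation identities; grid snapping uses 1e-9 epsilons against binary
floating-point time arithmetic; the SNR cap of ±40 dB keeps noise-free
windows finite. Degenerate inputs are contracts, not accidents: all-zero
delta vectors return a structured "no information" result, empty pair sets
are errors for summaries but valid (empty) for pairing, and constant SpO₂
traces refuse to synchronize rather than return an arbitrary lag.

## Known limitations

Coverage medians, gap counts and error-grid percentages of any real study
depend on its non-public recordings and are not reproduced here; the package
reproduces the *methods* and validates them against ground truth it
controls. The SNR estimator stands in for proprietary quality indices; only
its 0 dB decision threshold is treated as meaningful. The synchronizer
assumes a constant offset. Parquet support requires the optional `arrow`
package; the CSV dialect is self-contained and bit-exact.
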