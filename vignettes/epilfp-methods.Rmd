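---
title: "Detection and synchrony analysis of epileptiform spikes in LFP recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detection and synchrony analysis of epileptiform spikes in LFP recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(epilfp)
```

epilfp analyzes local field potential (LFP) recordings from epilepsy animal
models. Its core is an automatic detector for epileptiform spikes — transient
sharp deflections above the recording baseline, 20–80 ms long, often followed
by a slow wave — together with the analyses a synchronization study builds on
top of detected spikes: waveform morphology, inter-channel coincidence, and
Pearson correlation. Everything is scriptable: recordings come in as CSV,
HDF5 or EDF files (or straight from the bundled simulator), results go out as
tidy tibbles and self-describing JSON documents.

## The three-threshold spike detector

The detector classifies a sample run as a spike when it clears all three of:

1. **A moving amplitude threshold.** The recording is partitioned into
   contiguous analysis windows of `win_len` seconds (default 1 s), and each
   window's threshold is `percent`% of the maximum rectified amplitude
   observed inside that window. With `percent = 60` and a window maximum of
   1 mV, that window's threshold is 0.6 mV. Recomputing the threshold every
   second tracks the large amplitude variation of epileptiform spikes within
   and across recordings — a single global threshold would either drown in
   high-amplitude segments or fire constantly in quiet ones.
2. **A fixed amplitude floor** `fixed_thr` (mV), guaranteeing a minimum
   acceptable spike amplitude in windows where the moving threshold alone
   would sink into the noise (the per-sample effective threshold is
   `max(moving, fixed)`).
3. **A temporal (refractory) threshold** `min_dist` (s): the minimum allowed
   distance between two accepted spikes, so a polyphasic complex is counted
   once rather than once per deflection.

Candidate events are maximal runs of consecutive suprathreshold samples, each
reduced to its extremum sample. The temporal threshold is enforced by greedy
selection in descending amplitude order (ties go to the earlier time): a
candidate survives iff no already-accepted spike lies within `min_dist` of
it. The greedy rule implements a definite policy for conflicts inside a
polyphasic complex — keep the dominant deflection — and on small instances it
provably equals exhaustive enumeration under the same priority order (the
test suite checks this against a brute-force oracle).

Detection reports the spike count, the maximum/mean/minimum spike amplitude,
the maximum/mean/minimum inter-spike interval, and the firing rate (spikes
per second of analyzed span). With fewer than two spikes the ISI statistics
are undefined and reported as `NA`, never as 0.

Two conventions the field leaves open are fixed here and exposed as
parameters:

* **Polarity.** LFP spikes can be negative-going, so the default rectifies
  the signal (`polarity = "both"`) and detects on `|x|`; `"positive"` and
  `"negative"` restrict to one sign.
* **Window anchoring.** Analysis windows are anchored at `t_start` of the
  analyzed span, not at the recording origin, so an analysis of [30, 90) s
  behaves identically to an analysis of the same data shifted to [0, 60).

## Zero-phase bandpass filtering

Detection usually improves on recordings bandpassed to 10–100 Hz, which
removes slow oscillations and high-frequency content. Two designs are
available:

* **FIR** (`design_bandpass("fir", ...)`): a linear-phase filter obtained by
  least-squares approximation of the ideal bandpass amplitude over the
  passband and stopbands, then smoothed with a Hann window. The normal
  equations are solved in closed form (the Gram matrix of the cosine basis
  over a union of bands has analytic entries), so no frequency grid is
  involved. Transition bands of ±5 Hz around each edge are left
  unconstrained. The default length is the smallest odd integer ≥ `fs` — a
  one-second impulse response, which a credible 10 Hz edge requires; when a
  recording is too short for that, `filter_recording()` caps the length at a
  quarter of the signal with a warning.
* **IIR** (`design_bandpass("iir", ...)`): a Butterworth bandpass, default
  order 4 per pass (effective order 8 after the two zero-phase passes).
  Stability is verified at design time from the pole radii.

`apply_zero_phase()` applies the filter forward, reverses the filtered
sequence, applies the filter again, and reverses back. The two passes cancel
the phase response exactly — spike peaks stay where they are, which matters
because every downstream analysis keys on peak times — at the cost of
squaring the magnitude response (a 0.95 single-pass gain becomes 0.90).
Edge transients are handled by odd-reflection padding of `3 × numtaps` (FIR)
or `9 × order` (IIR) samples per side, trimmed after filtering; the padding
length bounds the start-up transient of either filter comfortably.

## Morphology of the average spike

`spike_morphology()` cuts a window of ±`half_width` seconds around each
detected peak (default 40 ms, matching the upper bound of the 20–80 ms spike
duration definition, deliberately excluding the trailing slow wave), averages
the epochs into the representative average epileptiform spike, and computes
three slope metrics:

* `rising_slope` = (peak − onset value) / (peak − onset time), ≥ 0;
* `descent_slope` = (end value − peak) / (end − peak time), ≤ 0;
* `overall_slope` = mean absolute per-sample slope over the onset-to-end
  support.

The onset is the last local minimum before the central peak and the descent
end the first local minimum after it, falling back to the window edges when
none exists. Because the averaged waveform still carries residual noise, the
local minima are located with a slope tolerance: scanning outward from the
peak, the segment continues while the per-sample slope exceeds
`rel_tol × max|Δw|` (default `rel_tol = 0.05`). With `rel_tol = 0` this is
the exact local-minimum rule; with the default it is robust to the
sample-scale wiggles that would otherwise stop the scan one or two samples
early and bias the rising slope downward by ~10% per sample on a 10-ms rise.
The "overall spike" slope has no single established definition; the mean
absolute instantaneous slope over the spike support is used because it
reduces to the duration-weighted mean of the rising and descent magnitudes
for piecewise-linear spikes and is insensitive to the rise/fall asymmetry.

Epochs whose centre sample is negative are sign-flipped before averaging so
negative-going detections do not cancel positive ones; the result reports how
many were flipped. A flat average waveform (no identifiable peak) is an
error, not a zero-slope result.

## Spike coincidence between channels

`spike_coincidence()` quantifies ictal coincidence between a reference and a
comparison channel: a reference spike is coincident when a comparison spike
lies within `window` seconds of it (symmetric window — the analysis has no
preferred direction). Matching is one-to-one and greedy by ascending |Δt|,
so a dense comparison train cannot certify several reference spikes with one
event; on small instances the greedy matching attains maximum cardinality
(checked against a brute-force matcher in the tests). The headline number is

    percent = 100 · n_matched / n_ref

with the reference spike count as denominator. Because "per analyzed period"
is an equally natural normalization, the matched-event rate per second of
analyzed span is reported alongside. A span with no reference spikes is an
explicit error — an undefined percentage is not 0%.

## Pearson correlation

`pearson_components()` evaluates the defining formula
`r = Σ(aᵢ−â)(bᵢ−b̂) / ((n−1)·σA·σB)` with sample (n−1) standard deviations and
returns the components (means, SDs) alongside `r`, which ranges from −1
(inverse correlation) through 0 (no linear interdependence) to 1.
`correlation_matrix()` generalizes the two-substrate comparison to all
channel pairs of a recording over a chosen span: a symmetric matrix with unit
diagonal, computed once over the full span (not windowed). A zero-variance
channel makes the coefficient undefined; such entries are flagged `NA`,
never silently zeroed.

## The synthetic LFP generator

Real validation recordings for this kind of detector are expert-annotated
and not generally available, so the package ships a generator whose ground
truth is exact by construction. `simulate_channel()` produces:

* **Baseline**: white Gaussian noise of SD `noise_sd` (mV), low-pass shaped
  below 30 Hz with a Butterworth filter and *not* renormalized — the shaped
  baseline has a smaller SD, as a broadband amplifier noise floor would after
  the same filtering. SNR is defined as `amp / noise_sd`.
* **Spikes**: a piecewise-linear sharp transient (default 10 ms rise to
  `amp`, 20 ms fall — inside the 20–80 ms definition, with the asymmetric
  rise typical of epileptiform spikes), optionally followed by a half-sine
  slow wave (`slow_wave = list(amp =, duration =)`; off by default). Spike
  times come from a Poisson process (default 0.5 spikes/s) thinned to a
  minimum gap of `max(min_gap, template width + 20 ms)`; the default
  `min_gap = 0.12` s keeps planted spikes individually resolvable by a
  detector using the standard 0.1-s temporal threshold with margin for the
  ±10 ms matching tolerance. Per-spike amplitude jitter (`amp_jitter_sd`,
  default 0.1 mV) emulates the amplitude variability the moving threshold
  exists to absorb.
* **Pairs** (`simulate_pair()`): each reference spike recurs on the
  comparison channel with probability `coincidence_p` (default 0.6) at its
  time plus `Normal(0, time_jitter_sd)` jitter (default 10 ms); independent
  comparison-only spikes are added at rate `spike_rate · (1 − coincidence_p)`.
  Recurring spikes lost to refractory thinning or edge clipping have their
  coincidence flag cleared, so the recorded flags are exactly what a perfect
  detector could recover.

All randomness flows from the single `seed`; identical specs produce
bit-identical recordings. `score_detection()` closes the loop, matching
detected to planted times one-to-one within a tolerance and reporting
precision, recall and F1 (the precision of an empty detection is `NA`, its
recall 0).

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: 1/f background structure, ictal or state-dependent
dynamics, artifacts (movement, line noise), electrode drift, spike-shape
families, or rate non-stationarity. Validation here demonstrates that the
implementation is faithful to its definitions, not that the default
thresholds are optimal for any particular preparation.

## Numerical choices and degenerate inputs

* Time is seconds from recording start, samples are 0-based in exported
  tables, and all analysis spans are half-open `[t_start, t_end)`.
* Storage unit is mV throughout; CSV/HDF5 samples are divided by the
  amplification gain at load time, EDF uses its header calibration.
* Suprathreshold runs use `≥`, so `percent = 100` admits exactly the window
  maxima and `percent = 0` admits every sample.
* Ties in the greedy refractory rule go to the earlier time; ties in
  coincidence matching go to the earlier reference, then earlier comparison
  time.
* Undefined statistics (empty event lists, single events, zero-variance
  channels, zero reference spikes) are `NA` flags or explicit errors, never
  silent zeros.
* Results serialize to JSON with full double precision and round-trip
  losslessly through `read_result()`.

## Validation scale

The test suite validates on synthetic recordings sized so the full suite
runs in about a minute: 60-s single-channel recordings (fs 1 kHz, ~30
planted 1-mV spikes on 0.05-mV noise) for detection and morphology recovery,
a 420-s pair (~200 reference spikes) for coincidence recovery, and 1,000
randomized 2-s recordings for the refractory invariant. The acceptance
script (`scripts/acceptance.R`) re-derives the moving-threshold reference
value from a freshly generated window at run time.

## Known limitations

* The greedy one-to-one coincidence matcher maximizes cardinality on all
  instances we can construct, but greedy-by-|Δt| is not guaranteed optimal
  in general; the brute-force comparison in the tests covers instances up to
  8 spikes per channel.
* Count monotonicity in the thresholds holds for spike-like signals (short
  suprathreshold runs); a signal staying above threshold for longer than
  `min_dist` can split into two candidates when a threshold rises.
* No seizure (ictal-period) detection, spike subtype classification, lagged
  cross-correlation, coherence, or streaming mode.
* HDF5 input is bridged through a `python` interpreter with `h5py`; EDF
  support assumes a uniform sampling rate across signals.
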