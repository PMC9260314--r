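---
title: "Decomposing slow-wave activity by spindle coupling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing slow-wave activity by spindle coupling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swacomp)
```

# The problem

Slow-wave activity (SWA) in NREM sleep EEG is not a single phenomenon. Slow
oscillations couple to sleep spindles of two distinct frequency classes —
*late-fast* spindles (10–13.5 Hz), which dominate deep N3 sleep and frontal
derivations, and *early-fast* spindles (14.5–18 Hz), which favor N2 sleep and
central derivations. Because the two coupled subtypes wax and wane in
opposite phase across NREM cycles, any analysis that treats SWA as
homogeneous averages over physiologically distinct events. `swacomp`
implements the full decomposition pipeline: slow-wave detection, band-split
spindle detection, trough-locked coupling classification, time-resolved and
stage-resolved composition summaries, peri-event wavelet power, and the
group-level statistics for channel, stage and age contrasts — plus a seeded
synthetic polysomnography generator so the whole chain is testable without
any recording data.

# Detection pipeline

## Slow waves

1. **Sliding detrend** — consecutive non-overlapping 3 s windows, per-window
   least-squares line removal (`detrend.window_s`). A shorter tail window is
   detrended on its own. Note that a per-window linear fit deterministically
   removes part of an oscillation whose period is commensurate with the
   window (about 26% RMS of a 1 Hz sine at 3 s windows); the zero-crossing
   structure the detector consumes is unaffected, which is why the window is
   matched to the artifact ceiling rather than minimized.
2. **Artifact ceiling** — any detrend window containing a sample with
   |x| > 900 µV (strict inequality, `artifact.threshold_uv`) is excluded
   wholesale. Exclusion granularity is the detrend window because the
   ceiling is defined on the detrended trace.
3. **Stage restriction** — only N2/N3 epochs are analyzable
   (`sw.keep_stages`); unscorable epochs are never analyzable. No masked
   sample enters any percentile or SD estimate anywhere downstream.
4. **Slow band-pass** — zero-phase (forward–backward) 6th-order Butterworth,
   0.16–4 Hz. The 12-pole band-pass is numerically unstable in single
   transfer-function form at these sampling rates, so the design is done
   analytically in second-order sections (analog prototype poles →
   band transform → per-biquad bilinear transform) and applied with
   odd-reflection padding sized to the slowest section pole. The resulting
   magnitude equals the squared analog Butterworth response (−6 dB at the
   band edges after the two passes), and the phase is identically zero.
5. **Zero-crossing half-wave pairing** — a candidate is a negative half-wave
   immediately followed by a positive half-wave (three consecutive zero
   crossings), with full-wave duration in 0.25–2.5 s, i.e. a 0.4–4 Hz
   full-wave frequency. The duration is read as *full-wave* (configurable
   `sw.min_dur_s`/`sw.max_dur_s`); a per-half-wave reading is the other
   defensible interpretation and can be emulated by halving the bounds.
   Candidates touching a masked range are dropped; the pair is anchored
   trough-first because all downstream timing is trough-locked.
6. **Amplitude selection** — in order: (i) the top-50% rule: keep candidates
   whose |trough| *and* peak both reach the respective medians over all
   candidates (inclusive boundary, so median ties survive); (ii) the
   ±200 µV ceiling on trough and peak; (iii) rejection of candidates whose
   trough or peak lies more than 4 SD from the respective mean of the
   *selected* population, computed once without re-iteration. Running the
   4-SD gate on the selected population (not the raw candidate pool)
   matters: genuine slow waves are a minority of all slow-band half-wave
   pairs, and an outlier gate computed over the raw pool would reject
   precisely the highest-amplitude true events.

Events are stamped with the stage of the epoch containing the trough.

## Spindles

Per band (late-fast 10–13.5 Hz, early-fast 14.5–18 Hz; 3rd-order zero-phase
Butterworth; the 13.5–14.5 Hz gap is excluded from identification by
construction): the analytic-signal upper envelope is thresholded at the 75th
percentile (linear-interpolation definition) of a 0.5 s moving-RMS of the
envelope over analyzable samples (`spindle.rms_window_s`,
`spindle.threshold_quantile`). Supra-threshold runs separated by gaps under
0.1 s are bridged (`spindle.merge_gap_s`), then gated to 0.5–3.0 s duration,
a ≤ 40 µV band-passed peak-to-trough range (`spindle.max_range_uv`), and an
8-SD peak-envelope outlier rejection (`spindle.reject_sd`; switchable to the
per-event mean envelope via `spindle.reject_on`).

Two readings were genuinely open. The threshold statistic ("75th percentile
of the RMS value") is implemented as the percentile of a moving-RMS series
with the window tied to the minimum event length, applied to the envelope —
the most literal composition that yields a scalar; both the window and the
quantile are configuration keys so a replication run can state its reading.
The early-fast band is 14.5–18 Hz by default; 14–18 Hz appears in some
descriptions of the same methodology, and the band is configurable rather
than silently harmonized.

A percentile threshold is *relative* by construction: on stationary
background it is exceeded a fixed fraction of the time, so some
supra-threshold runs of background sigma activity always qualify as events.
This is a property of the methodology, not a defect of the implementation;
see *Limitations*.

## Coupling classification

A slow wave is coupled when a spindle's reference time falls in the
trough-locked window [trough + 0.2 s, trough + 1.5 s]; the 0.2 s buffer
excludes pre-trough slow-spindle activity. The reference time is the spindle
*onset* by default (`coupling.reference`): the buffer's purpose is an
onset-timing argument, and an envelope-peak reference is available as a
configuration switch. Three deliberate rules keep the partition exact
(LF + EF + unclassified = total slow waves, asserted property):

* a slow wave matched by spindles of *both* bands is left unclassified
  rather than double-counted;
* each spindle is consumed by at most one slow wave, the earliest trough
  claiming it;
* slow waves with no qualifying spindle are unclassified.

Cross-channel pairing (slow waves from one derivation, spindles from
another) is supported; both channel labels are carried on every coupled
event.

## Peri-event time–frequency maps

Troughs are centered in 5 s segments of the *unfiltered* signal; each
segment is matched to the 5 s baseline immediately preceding it, discarded
if that baseline contains any detected slow-wave trough. Complex Morlet
wavelets (8 cycles) on a 4–20 Hz axis in 0.25 Hz steps (65 rows) yield
amplitude (not power), scaled so a unit sinusoid at an axis frequency maps
to 1. The mean event map is divided, per frequency, by the baseline mean
over time and baselines; the result is therefore 1 under self-normalization
and invariant to global amplitude rescaling. ROI power is the mean over an
inclusive frequency × time rectangle. The default ROI rectangles mirror the
detection bands crossed with the coupling window; they are placeholders for
externally defined ROIs and must be set in configuration for any replication
of published ROI magnitudes.

## Composition summaries

* **Wall-clock histogram**: 2 min left-closed right-open bins anchored at
  t = 0; an event belongs to the bin containing its trough; empty bins carry
  an undefined (not 0%) late-fast percentage and are rendered as gaps.
* **Stage summary**: counts and late-fast percentage per N2/N3, with events
  assigned by trough epoch.
* **Normalized NREM axis**: the night's N2+N3 epochs concatenated and
  rescaled to unit length, split into exactly 100 bins (1% of NREM time
  each). The wall-clock and normalized axes are distinct operations and are
  never mixed.
* **High-LF bin count**: bins whose defined late-fast percentage is ≥ 80%
  (inclusive). Undefined bins can never satisfy the threshold — the choice
  for zero-event bins is undefined-composition, recorded here because the
  alternative (0%) would silently deflate the count.

# Group-level statistics

* **Event-count-weighted t-test** — two-sample, two-sided, Welch degrees of
  freedom, with frequency-weight semantics: weights are rescaled within each
  group to sum to the group size, making the result invariant to weight
  rescaling and exactly equal to the unweighted Welch test under equal
  weights. The weights are per-participant detected-event counts, under
  which a participant's percentage has sampling variance inversely
  proportional to its weight; the test is calibrated under exactly that
  regime (type-I error ≈ 0.05 in the null simulations of the test suite).
* **Clustered negative-binomial count ratio** — log-link count regression
  with the NB dispersion estimated by method of moments and held fixed,
  fitted under working independence, with cluster-robust (sandwich)
  standard errors and a t(G−1) reference for G clusters. This is a marginal
  GEE-type estimator; an exchangeable working correlation would require GEE
  machinery not available here, and under cluster-robust inference the
  working-correlation choice affects efficiency, not validity. The
  exponentiated coefficient is the condition ratio; percent differences are
  reported as 100 × (ratio − 1). The method string on every result records
  all of this.
* **Repeated-measures ROI contrast** — subject-blocked within-subject
  contrast; with one observation per condition per subject this is the
  paired t contrast, reported with the raw difference and the
  percent-difference parameterization 100 × mean(a−b) / mean((a+b)/2).
* Degenerate zero-variance inputs return the exact estimate with p = 0 (or
  1 when the estimate is also 0) and a warning, so toy fixtures keep
  pipelines running. No multiple-testing adjustment is applied anywhere;
  every comparison is reported at face value.

# The synthetic generator

`sim_config()` defaults define the study conditions; they are chosen once,
for realism and internal consistency with the pipeline's own gates, and the
tests run against them unchanged:

| Parameter | Default | Rationale |
|---|---|---|
| duration, rate, cycles | 8 h, 200 Hz, 4 NREM cycles | an ordinary clean overnight recording |
| slow-oscillation rate | N3 12/min, N2 6/min | dense-SWA end of reported discrete SO densities; N3 > N2 |
| trough depth | −80 ± 10 µV | typical scalp SO amplitude, well under the ±200 µV ceiling |
| SO duration | uniform 0.8–1.6 s | comfortably inside the 0.25–2.5 s acceptance band |
| spindle bursts | 11 ± 2.5 µV envelope (clipped 8–16), 1.2 ± 0.25 s (clipped 0.8–2.0), 12 / 16 Hz carriers | peak-to-peak stays inside the 40 µV artifact range gate (larger bursts would be self-rejected as artifacts); durations sit above the 0.5 s minimum because thresholding shortens measured durations, making shorter bursts intrinsically borderline |
| coupling probabilities | N3: LF 0.45 / EF 0.20; N2: LF 0.25 / EF 0.35 | N3 biased late-fast, N2 biased early-fast; drawn mutually exclusively per slow wave |
| coupling lags | uniform 0.25–1.4 s | strictly inside the 0.2–1.5 s classification window so boundary effects do not confound recovery |
| background | 1/f (β = 1), 15 µV total RMS | pink broadband floor |
| `lf_shift` | 0 (aging knob) | adds to the late-fast coupling probability in both stages, capped so stage totals stay ≤ 1 |

The generator writes standard EDF (16-bit) plus a plain-text hypnogram, so
tests exercise the pipeline through its real file I/O path, and it is
bitwise deterministic under its seed without touching the caller's RNG
state.

What it deliberately does *not* emulate: K-complexes and arousals, spindle
frequency chirp, topographic gradients across channels, EOG/EMG
contamination, the steeper (β ≈ 2–3) spectral slope of real NREM sleep, or
within-night homeostatic decline of SWA. Passing the recovery tests
therefore demonstrates that the pipeline is a faithful implementation of the
stated rules and recovers known structure under clean conditions — not that
its absolute event counts on real polysomnography are unbiased.

# Numerical choices

* Percentiles use R's default linear-interpolation definition (type 7),
  stated so other implementations can match it.
* Filters are designed in second-order sections; zero-phase filtering uses
  odd-reflection padding of at least six time constants of the slowest
  pole.
* The Hilbert envelope is computed by FFT zeroing of negative frequencies;
  Morlet convolution pads segments by reflection to control edge effects.
* Event tables are written at full double precision and round-trip exactly.
* Half-open, 0-based sample ranges everywhere in masks; times are seconds
  with sample 1 at t = 0.
* Scoring of detections against ground truth uses greedy globally-nearest
  one-to-one matching. Slow waves are matched on trough times (±0.25 s);
  spindles are matched on interval midpoints (±0.5 s) because envelope
  thresholding delays the detected onset by a systematic 0.2–0.4 s.

# Desk-scale test conditions

The test suite runs the generator at reduced problem sizes chosen as the
package's own desk-scale defaults: 0.3–2 h nights at 128 Hz for the
property and recovery tests (20 seeds for the ordering and aging-shift
recoveries, 50 short nights for the partition invariant), one 8 h night at
200 Hz for the default-condition detection check, and 1000-replicate null
simulations for the statistics. `scripts/acceptance.R` re-runs the same
computations from scratch at the same sizes.

# Limitations

* **Rank-based selection bounds precision against injected truth.** The
  top-50% amplitude rule returns, by construction, about half of *all*
  slow-band half-wave pairs. In the synthetic conditions the pinned 15 µV
  1/f background contributes several times more candidate waves than any
  physiologically plausible discrete SO injection rate, so a majority of
  selected waves are background waves and precision against injected ground
  truth plateaus near 0.2–0.5 while recall exceeds 0.95. The same arithmetic
  applies to the reference methodology on real data (its per-night slow-wave
  counts, ≈ 7 000, correspond to roughly half of all detected half-wave
  pairs in N2+N3); "detected slow wave" should be read as "above-median
  slow-band wave", not "certified discrete slow oscillation".
* **The percentile spindle threshold is permissive.** On stationary
  background it yields several supra-threshold events per minute per band
  regardless of the noise scale, so spindle precision against injected
  bursts is similarly bounded (~0.3–0.4), again mirroring the permissive
  event counts of the underlying methodology. Detection of clear bursts is
  reliable (recall ≥ 0.9); individual low-amplitude events are not
  certifiable.
* **The 13.5–14.5 Hz exclusion is a filter-level guarantee.** A 14 Hz burst
  is attenuated about five-fold in both bands, but its residual can still
  cross the *relative* threshold by riding on a background excursion, so
  end-to-end "yields neither" holds as a rate statement, not per burst.
* Composition percentages are undefined (not zero) in event-free bins;
  studies comparing high-LF bin counts must use the same convention on both
  arms.
* The GEE working correlation is independence (with robust SEs), not
  exchangeable; estimates are consistent either way but not identical.
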