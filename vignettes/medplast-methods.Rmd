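---
title: "medplast: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{medplast: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medplast)
```

# Scope

`medplast` analyses evoked field potentials recorded on an 8×8 planar
multielectrode array (MED64-style dish: 50 µm electrodes, 150 µm pitch)
placed over a cortical slice, with stimulation delivered through one
deep-layer electrode. The pipeline covers the standard plasticity workflow —
per-sweep fEPSP feature extraction, channel/slice quality control, baseline
normalization, LTP/LTD quantification, paired-pulse ratios, recruited- and
silenced-channel detection, layer-resolved spatial maps, and group
statistics — plus a synthetic recording generator whose presets make the
whole chain testable by parameter recovery. It does not model biophysics
(no conductance-based neurons, no stochastic vesicle release) and does not
read vendor-native acquisition formats.

# Measurement model

## Trace conventions

Traces are stored in µV at a declared sampling rate (default 20 kHz), with
the stimulus onset marked as a 0-based sample index. fEPSPs are
negative-going; all amplitudes and slopes are reported as positive
magnitudes, so "increase" always means a larger response.

Per sweep and channel:

1. **Artifact blanking.** The biphasic stimulus artifact is removed by
   linear interpolation over the first 1 ms after each stimulus onset
   (configurable).
2. **Baseline reference.** The mean of the 5 ms immediately preceding the
   stimulus. A short pre-window tracks slow drift better than a whole-sweep
   mean.
3. **Smoothing.** A 0.4 ms boxcar is applied before peak search and slope
   fitting. Without it, the amplitude statistic (an extremum) carries an
   extreme-value noise bias of several µV at the 2 µV noise level, which
   would distort the recruited-channel amplitudes (~11–19 µV) most.
4. **Amplitude** = |most negative excursion from the baseline reference|
   within 2–50 ms post-stimulus (the 2 ms guard excludes residual artifact).
5. **Slope** = |least-squares line| through the samples between 20 % and
   80 % of peak amplitude on the initial downstroke, in µV/ms. The window
   bounds are located to sub-sample precision by linear interpolation of the
   threshold crossings and the two interpolated boundary points are included
   in the fit; otherwise the fitted value jitters by ±2 % with the sample
   grid, which would dominate the stability statistics. The 20–80 % window
   is a common field-potential convention; the acquisition literature rarely
   states an exact window, so it is a documented, configurable default.

For paired-pulse sweeps the first response is measured with its search
window truncated before the second stimulus; the first response's decay
tail is then fitted log-linearly (from 12 ms after the first stimulus up to
the second stimulus) and the extrapolated tail is subtracted before the
second response is measured against its own pre-stimulus baseline. Without
this, the 25 ms interval ratio is biased by ~9 % (the second response rides
on the first's tail); with it, noise-free ratios are exact to <0.1 %.

## Quality control

* **Activated channel**: median baseline amplitude strictly above 10 µV.
  The median (not a single sweep) makes the call robust to one noisy sweep.
* **Stable channel**: the coefficient of variation (population SD / mean)
  of baseline slopes over the final 15 min of baseline is strictly below
  5 %. "Variation" is operationalized as CV because it is scale-free and
  matches a percentage criterion; a max-drift alternative could be slotted
  in via the same interface.
* **Slice exclusion**: strictly more than 10 % unstable among activated
  channels, or no activated channels at all (such a slice carries no
  analyzable signal and is excluded with an explicit reason).

## Plasticity quantification

Each `active_stable` channel's slope series is normalized to 100 × slope /
(channel's baseline mean). The channel outcome is the mean over the **final
10 min of the recording** (anchored to the recording end, not to
induction). Channels are labelled `potentiated` (≥ 115 %), `depressed`
(≤ 85 %) or `unchanged`; because figure-level "channels with LTP"
selections in the field rarely state their criterion (group means near
108 % still appear in such selections), both the raw per-channel means and
the thresholded labels are emitted, and the labels are configurable.

Group summaries use the **channel as the unit of analysis** (mean ± SEM
over channels per layer), matching how channel-level t-tests are reported
in MEA studies; slice-level aggregation is available by averaging the calls
per slice first. Channels called **silenced are excluded from the layer
LTD mean**: silencing is reported separately (counts and amplitude time
courses), and folding responses that collapse to ~0 µV into a "LTD
magnitude" mean would conflate two phenomena — a cohort cannot
simultaneously show a ~70–85 % LTD plateau and contain silenced channels in
the same average. Recruited channels are never in the normalized series in
the first place (they are not baseline-activated).

## Recruitment and silencing

Both detectors reuse the 10 µV activation threshold with median statistics:
a channel is **recruited** (TBS protocols) when its baseline median
amplitude is ≤ 10 µV and its median amplitude over the final 10 min exceeds
10 µV; **silenced** (LFS protocols) when it was activated and its final
median falls to ≤ 10 µV. Using one threshold for activation, recruitment
and silencing keeps the three classifications mutually consistent
(recruited ⇒ not baseline-activated; silenced ⇒ baseline-activated; never
both).

A recruited cell is an **edge** channel when at least one of its
8-connected neighbours (off-grid sides count as outside) is not in the
baseline-activated set; 4-connectivity is available. The 8-connected
reading matches the visual notion of "the edge of the activated area" on a
square grid.

## Group statistics

`welchT()` wraps the standard unpaired Welch t-test;
`twoWayAnovaPosthoc()` fits `response ~ A * B` and runs pairwise
comparisons of the group factor within each level of the second factor via
estimated marginal means with Sidak or Tukey adjustment. ANOVA F-tests are
inherently one-sided on the F distribution; no separate "one-tailed ANOVA"
variant exists or is provided. The test suite checks both routines against
explicit formula evaluation (Welch statistic/df, balanced-design sums of
squares) rather than against another library call.

# The synthetic generator

## What it emulates

* 8×8 grid with one `outside` column, three superficial (II–III) and four
  deep (V–VI) columns; stimulation at 0-based (row 3, column 5), in a deep
  column.
* Sweeps every 0.5 min: 15 min baseline, induction, 60 min post by default
  (the post duration is a configurable default — acquisition protocols
  differ and published time courses rarely fix it — chosen so the final
  10-min window sits ≥ 7 plasticity time constants after induction).
* Each trace: biphasic artifact (±200 µV, 0.4 ms) + dual-exponential fEPSP
  (τ_rise 1 ms, τ_decay 8 ms, latency 2 ms) + white Gaussian noise
  (SD 2 µV). The dual exponential is the standard analytic field-EPSP
  shape and makes peak time and slope checkable in closed form.
* Baseline amplitudes decay exponentially with grid distance from the
  stimulation electrode (length constant 300 µm), truncated to 0 below the
  activated floor, giving a contiguous activated disc spanning both layers
  (~8 superficial + ~26 deep channels).
* Plasticity: per-channel plateau drawn from Normal(layer plateau, 0.05),
  approached as `m(t) = 1 + (P − 1)(1 − e^{−(t−t₀)/τ})`, τ = 5 min. The
  mono-exponential approach makes the last-10-min mean equal the plateau to
  ~10⁻⁵, so the presets are recoverable parameters.
* Recruited channels: inactive cells adjacent to the activated disc (hence
  on its edge by construction), baseline response 0 µV + noise, rising to
  the preset amplitude with the same kinetics after TBS. Silenced channels
  (LFS only): activated cells, drawn with a bias toward the outer half of
  the disc, whose response decays to ~0. Expected per-slice counts are
  preset-specific and may be fractional (realized as floor + Bernoulli
  remainder).
* Paired-pulse sweeps: two pulses per sweep at 25/50/75/100 ms with
  facilitation ratios 1.40/1.20/1.10/1.05 by default.

The condition presets (`naive`, `observer`, `demonstrator`) hard-code
layer-specific LTP plateaus (154.1/148.9, 128.8/132.2, 107.8/107.6 % of
baseline), LTD plateaus (67.4/69.6, 84.6/78.9, 83.8/80.5 %),
recruited-channel amplitudes and expected recruited/silenced counts; the
demonstrator presets generate no recruited and no silenced channels. These
numbers are the generative truth the acceptance checks recover.

## Calibration of the amplitude scale

The preset amplitude field (500 µV at the stimulation site, 90 µV activated
floor) was set from the recording conditions the pipeline assumes: baselines
of analyzable slices satisfy the < 5 % variation criterion. Under 2 µV white
noise at 20 kHz, the per-sweep slope estimate at the activated floor has a
CV of ~3 %, comfortably inside the criterion, while a 50 µV floor would push
rim channels past 5 % and exclude essentially every slice. The resulting
active-channel counts per slice and layer (≈ 4–8 channels showing LTP per
layer per slice) are of the order reported for MED64 cortical recordings.
Real amplitudes reach the activation threshold more gradually; the truncated
field instead gives unambiguous activation truth, which is what the
recovery tests need.

## What it does not emulate — and what passing tests show

The generator uses white noise (no 50 Hz hum, no correlated LFP
background), a deterministic radial amplitude field (no per-channel
amplitude heterogeneity beyond the plateau spread), a single fixed waveform
shape for all channels (no latency or kinetics gradients with distance),
and no electrode failures, drift or re-referencing artifacts. Passing the
recovery suites therefore shows that the estimators are unbiased and
consistent under the stated statistical structure — not that they are
robust to every pathology of real recordings. The QC stage is the intended
guard for such pathologies, and its rules are tested on constructed
fixtures independently of the generator.

# Numerical choices and degenerate inputs

* Thresholds are strict where the criterion says "above"/">": a 10.0 µV
  median is inactive; exactly 10 % unstable is retained; CV exactly 5 % is
  unstable.
* Slope fits need ≥ 3 points (including the interpolated window bounds);
  otherwise a degenerate-window error (per-trace failures become flagged
  rows in `extractFeatures()`, never slice aborts).
* Channels with non-positive baseline mean slope cannot be normalized and
  are dropped with a logged reason; zero-mean baselines are flagged
  "degenerate baseline" and unstable.
* Input–output calibration returns the smallest intensity in the 40–60 %
  band of the maximum slope; when no tested intensity lands in the band it
  falls back to the intensity closest to 50 % with a warning; an all-zero
  curve is an error.
* Peak search ties resolve to the earliest sample; all randomness flows
  from one root seed through deterministic per-slice sub-seeds, making
  cohorts byte-reproducible.

# Problem sizes used in the checks

The recovery suites simulate the cohort sizes of the study design the
presets encode (7/13/6 TBS slices, 8/12 LFS slices, 6-slice recruitment
cohort) at the full default protocol; unit tests use shortened protocols
(3 min baseline, 12–40 min post) that preserve every code path. The
paired-pulse check pools ≥ 500 pairs per interval from one slice with 15
repeats per interval. The edge-flag oracle comparison enumerates 1,000
random 8×8 maps.

# On-disk formats

Bundles are plain-text CSV directories (`metadata.json`, one
`sweep_%04d.csv` per sweep with channels in columns, and `truth.csv` for
synthetic bundles, kept separate so analyses can run blinded). Voltages are
µV, times minutes, sample indices 0-based. All tabular results are tidy
CSV; the pipeline writes a JSON manifest recording seed, thresholds,
versions and every excluded slice with its reason.

# Known limitations

* The silenced-channel exclusion from LTD group means is a reporting
  convention; with it enabled the LTD mean tracks the surviving channels'
  plateau, and analysts wanting the pooled quantity can average
  `summarizeLastWindow()` output directly.
* PPR tail subtraction assumes a mono-exponential late decay; waveforms
  with slow secondary components would need a longer fit window.
* `twoWayAnovaPosthoc()` uses Type I (sequential) sums of squares via
  `aov()`, exact for the balanced designs the pipeline produces; strongly
  unbalanced designs would need a Type II/III variant.
* The generator's noise is white; stability CVs on real, band-limited noise
  will differ from the simulated ones at equal RMS.
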