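---
title: "Methods: quantifying spontaneous activity in the pre-hearing auditory system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying spontaneous activity in the pre-hearing auditory system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Background

Before hearing onset, the cochlea generates spontaneous electrical activity
without any acoustic input. Inner supporting cells (ISCs) of Kölliker's organ
spontaneously release ATP, which triggers a purinergic signalling cascade:
intracellular Ca²⁺ rises in ISCs, Ca²⁺-activated Cl⁻ channels open, K⁺
follows Cl⁻ out of the cells, and the accompanying osmotic water loss
transiently shrinks the supporting cells (*crenation*, visible as a
transmitted-light change). The released K⁺ depolarizes nearby inner hair
cells (IHCs), which fire Ca²⁺ spikes and drive bursts of action potentials in
spiral ganglion neurons (SGNs). This burst activity propagates through the
auditory pathway and appears in the inferior colliculus (IC) as stationary
bands of correlated activity aligned with the future tonotopic map, while the
neighbouring superior colliculus (SC) carries retinal waves from the eye.

`otowave` implements the complete measurement stack for this system:

* **ephys, spikes** — burst detection in SGN spike trains by interspike-interval
  (ISI) classification, plus burst metrics and ISI histograms;
* **ephys, currents** — spontaneous inward-current event statistics,
  holding-current summaries, and tail-current series for voltage-clamp data;
* **imaging core** — ΔF/F₀ normalization, photobleaching correction,
  difference movies, thresholding, region areas, 1-D peak detection;
* **cochlea imaging** — crenation frequency/area, per-compartment Ca²⁺
  transient statistics, pairwise IHC correlation;
* **midbrain imaging** — IC event detection, bilateral pairing, tonotopic
  line scans and band peaks, retinal-wave detection;
* **stats** — D'Agostino K², Bonferroni-corrected comparisons, one-way
  ANOVA + Tukey, and the two-mean sample-size calculation;
* **synthetic data** — generators for all of the above with ground-truth
  logs, so the entire stack is testable without recordings.

## Burst detection in SGN spike trains

Consecutive ISIs are classified into three classes: **mini-burst**
(< 30 ms), **burst** (30 ms – 1 s, closed at both ends so the partition of
the positive reals is total), and **non-burst** (> 1 s). A *burst* is a
maximal run of intervals free of non-burst labels containing at least 10
burst-class intervals. Mini-burst intervals neither break a run nor count
toward the 10, but the spikes they contribute are included in the burst span
and spike count; runs may begin or end with mini-burst intervals (the
symmetric reading of "ignored for detection, included for counting").

Burst metrics report burst frequency (min⁻¹), mean burst duration, mean
spikes per burst, mean action-potential frequency over the analysis window,
and the coefficient of variation of ISIs. The CV is computed over **all**
ISIs in the window by default (a `burst_only_cv` flag restricts it to
within-burst ISIs); window-wide is the reading consistent with "for all ISIs
measured". A homogeneous Poisson train has CV → 1 and a perfectly periodic
train exactly 0, which the tests verify.

Spike detection for juxtacellular traces uses a zero-phase 2nd-order
Butterworth high-pass (default cutoff 10 Hz — no filter is canonical for
this step, so it is configurable), a threshold of `threshold_k` (default 5)
times the robust noise SD (1.4826 × MAD of the filtered trace), and a 1 ms
refractory merge. These defaults assume the noise floor is estimable from
the majority of samples; a strictly noise-free trace has no meaningful MAD
scale, so the tests use a realistic small noise floor.

## Voltage-clamp event statistics

Spontaneous inward currents ride on a slowly drifting holding current.
The detector subtracts a 10 s rolling-median baseline (computed on a ~100 Hz
decimated grid and linearly interpolated back — the baseline is slow by
construction, and this keeps the filter O(n)), estimates the noise SD
robustly, and takes threshold crossings below `-threshold_k × SD` as events.
Crossings are merged within `min_separation` (50 ms) and must persist for
`min_width_s` (5 ms) to exclude isolated noise samples. Each event reports
its signed peak (`peak_amp`, negative for inward), positive magnitude
(`amplitude`), and charge transfer `integral = ∫(baseline − I) dt` from the
crossing until the trace first returns within one noise SD of baseline —
positive for inward events (a −100 pA × 1 s square event transfers 100 pC).

The holding current of a period is summarized as the **95th percentile** of
its samples (linear interpolation between order statistics). For a cell held
below its reversal potential with inward events, this is the upper envelope
of the trace and is insensitive to events occupying < 5 % of the period.
Measurement periods default to five minutes. Tail currents are measured as
the mean current in a window at the end of the −70 mV step (default choice:
mean, with `statistic = "min"` for peak measurements; the measurement window
is marked, not specified, in the source protocol) and normalized so the mean
over the designated baseline sweeps is 0 pA.

## Imaging primitives

* **ΔF/F₀** — F₀ is the per-pixel 5th percentile over time; ΔF/F₀ =
  (F − F₀)/F₀ exactly. Stacks with non-positive baselines are rejected with
  instructions to offset. Values are dimensionless fractions; functions with
  percent-scale thresholds (2 %, 3 %) convert internally.
* **Bleach correction** — a single exponential `a + b·exp(−t/τ)` is fitted
  to the frame-mean trace (Levenberg–Marquardt, with a self-starting
  asymptotic fit as fallback) and the decaying component is subtracted from
  every pixel, anchored at the fitted t = 0 level so the corrected baseline
  stays on the pre-bleach scale; this keeps later ΔF/F₀ amplitudes
  comparable. Subtractive correction preserves absolute, not fractional,
  amplitudes: under strong bleaching late events are still attenuated by the
  bleach factor, so amplitude comparisons should be restricted to recordings
  where total decay is modest (the tests use τ ≈ 10 × movie length, ≤ 10 %
  total decay). Non-decaying traces are returned unchanged with a warning.
* **Difference movies** — frame k of the output is `F(k+L) − F(k)` with
  `L = round(lag × frame_rate)` (default lag 5 s), indexing slow
  transmittance change.
* **Thresholding** — default is the global mean + 3 SD over all pixels and
  frames (a `per_pixel` flag switches to per-pixel temporal statistics).
  On pure Gaussian noise the suprathreshold fraction matches the normal
  tail, which the tests check against binomial error.
* **Region areas** — the binary mask is Gaussian-smoothed (σ = 2 px),
  re-binarized at 0.5, and labelled with 8-connectivity (the behaviour of
  the standard `bwlabel` border-detection step); area = pixel count ×
  (µm/px)². The labelling is a 4-connected pass with a diagonal-adjacency
  label merge.
* **1-D peaks** — local maxima above a fixed threshold; plateaus count once
  (centre sample); minimum separation is enforced greedily, keeping the
  larger of two conflicting peaks.

## Cochlear analyses

**Crenations**: difference movie (lag 5 s) → global 3 SD threshold → the
per-frame count of suprathreshold pixels is the whole-field trace → peaks in
that trace give event times. The peak threshold for the count trace is
median + 3 × 1.4826 MAD of the counts, which adapts to the noise-driven
baseline count while staying far below genuine events. Event area is the
largest labelled region of the thresholded difference frame at the peak.

**Ca²⁺ transients**: per-ROI mean ΔF/F₀ traces, thresholded at each trace's
mean + 3 SD (computed on the ΔF/F₀ trace — raw vs normalized is not
specified in the source; normalized chosen so thresholds are commensurable
across cells); frequency per minute per compartment; event area by
thresholding the peak frame per pixel (temporal mean + 3 SD) within the ROI.
This fixed mean + 3 SD rule assumes transients occupy a minority of the
trace; at event duty cycles above roughly 25 % the SD inflates and
sensitivity drops — the generator's default schedules stay well below that.

**IHC correlations**: Pearson correlation between raw per-cell ΔF/F₀ traces
(not event-binarized), every pair; each cell is summarized by the mean
coefficient over its 4 nearest neighbours (centroid distance, ties by ROI
order; edge cells use the neighbours they have), and the group mean averages
those. Zero-variance traces yield undefined coefficients and are excluded
and reported.

## Midbrain analyses

**IC events** are peaks of the per-lobe mean ΔF/F₀ trace above a fixed 2 %
threshold (fixed across conditions because the traces are normalized).
Amplitude is the baseline-subtracted peak, with the local baseline taken as
the median of the 5 s preceding event onset (last upward threshold
crossing); half-width is the full width at half of (peak − baseline) with
linear interpolation. **Bilateral pairing** greedily matches left/right
events by minimal time difference within ±0.5 s (ties to the earlier event;
each event used once); the bilateral amplitude ratio is weak/strong ∈ (0, 1],
1 meaning complete interlobe symmetry. Events whose suprathreshold coverage
of their lobe exceeds 80 % at the peak frame are excluded as global
(cortex/SC-driven) events; the boundary is strict, coverage exactly at the
threshold is retained.

**Tonotopic line scans** sample a 125 × 50 px rectangle rotated ±55° with
bilinear interpolation, average across the 50 px width, and stack the
125-sample profiles over time. Band peaks are regional maxima of the
position × time matrix (strictly greater than all 8 neighbours) above a
constant 3 % threshold. Spatial histograms use exactly 25 µm bins; events
below the split position are lateral (high-frequency zone), at or above it
medial. The split is a required input — the midpoint between the lateral
edge and the single-band locus, which is identified per recording — and an
optional exclusion zone (default half-width 50 µm) removes
bifurcation-edge events around that locus.

**Retinal waves**: each SC lobe ROI (200 × 150 px required) is block-mean
downsampled ×5, normalized to ΔF/F₀ (5th-percentile F₀), the per-frame
all-pixel mean is subtracted to remove whole-sample fluctuations, and a
pixel is active when it exceeds its temporal mean + 3 SD (computed over the
full recording after mean subtraction). A wave is a maximal run of frames
with **more than five** active pixels lasting **strictly more than 1 s**;
its duration is the run length. Both boundary cases (exactly five pixels;
1 s or less) are rejected, which the tests force explicitly.

## Statistical toolbox

`normality_k2()` implements the D'Agostino K² omnibus test (D'Agostino's
skewness transformation plus the Anscombe–Glynn kurtosis transformation,
K² ~ χ²(2)); it is validated against values frozen from an independent
implementation. `compare_groups()` routes two groups to Student's t
(paired or unpaired) with Bonferroni adjustment `min(1, p × m)`, and three or
more to one-way ANOVA with Tukey's HSD. `sample_size_two_means()` uses the
two-sided normal-approximation formula
`n₁ = (z₁₋α/₂ + z_power)² σ² (1 + 1/ratio) / Δ²`, rounded up, floored at 1;
for (µ₁ = 10, µ₂ = 7, σ = 2, ratio = 1, power 0.8, α 0.05) it returns 7 per
group. The approximation is the model under which the formula is derived, so
its Monte-Carlo check uses a known-variance z-test; an exact noncentral-t
calculation would demand one more subject at unit effect size.

## The synthetic-data generator

The generators emit the study conditions directly and log every scheduled
event so detectors can be scored against ground truth:

* **Spike trains** — bursts arrive as a Poisson process (default 2/min,
  thinned so bursts cannot overlap), spikes per burst `11 + Pois(mean−11)`
  (mean 15; the floor guarantees every generated burst meets the ≥ 10
  interval definition), intra-burst ISIs uniform on 75–125 ms (the IHC Ca²⁺
  spike rate band), mini-burst doublets with probability 0.05 per interval,
  tonic Poisson background 0.2 Hz.
* **Current traces** — instantaneous-onset, single-exponential-decay inward
  events (τ = 0.2 s), log-normal amplitudes (mean 100 pA, σ_log 0.4, the
  heavy-tailed size distribution seen in such recordings), Poisson onsets
  thinned to ≥ 1.5 s separation, linear drift, Gaussian noise (default
  4 pA), baseline −50 pA at 1 kHz.
* **Movies** — events are injected multiplicatively, `F = B(1 + S)`, so
  event sizes are fractional ΔF/F₀ by construction; bleaching is a
  multiplicative single exponential; noise is additive Gaussian. IC bands
  are Gaussian profiles along the tonotopic axis (FWHM default 100 µm) times
  a temporal alpha function, with an automatic contralateral partner scaled
  by `bilateral_ratio`; SC waves drive the `n_px` downsampled blocks nearest
  a drifting centre for exactly the scheduled duration; cochlear movies
  support scheduled compartment transients plus equicorrelated smoothed
  Gaussian per-IHC traces with exact target pairwise correlation ρ;
  crenations are discs with a linear rise (40 % of the duration) and decay.

Each generator owns an isolated RNG stream (seeded locally and restored on
exit), so adding one generator call does not shift another's output, and a
fixed seed reproduces stacks bitwise.

What the generators deliberately do **not** emulate: biophysics (P2RY1
signalling, K⁺ diffusion, osmotic volume dynamics), optics (PSF, scattering,
vignetting), motion, correlated or non-Gaussian camera noise, and the real
recordings' unknown noise statistics — the defaults are plausible
placeholders and every one is configurable. Passing tests therefore
demonstrate that the analysis code implements its definitions correctly and
recovers known truth under clean conditions, not that it is robust to every
artefact of real data.

## Numerical choices and problem sizes

Percentiles use linear interpolation between order statistics throughout.
Class boundaries: ISI burst class closed at both ends; event exclusion
coverage strict (>); wave thresholds strict (> 5 pixels, > 1 s); split
assignment `position < split` lateral, else medial. Ties in peak separation
resolve toward the larger peak, in bilateral pairing toward the earlier
event, in nearest-neighbour selection toward lower ROI index.

The test and acceptance workloads were sized to exercise every code path at
desk scale while keeping statistical checks meaningful: 1,000 random label
sequences against the burst oracle; 20 seeds × 10 min for rate-recovery
checks; 50 paired events per bilateral-ratio setting (48 × 64 px lobes at
10 Hz); 40 band events on a 160 × 160 px field at 2 Hz; 20 scheduled waves
on a 200 × 150 px ROI at 5 Hz; 10⁴ ISIs for the CV checks. These sizes give
sampling errors comfortably inside the tolerances they are tested against.

## Known limitations

* Subtractive bleach correction preserves absolute amplitudes only;
  strongly bleached recordings need a multiplicative model.
* The mean + 3 SD threshold rules degrade at high event duty cycles.
* Bilateral pairing is greedy, not globally optimal; at event rates where
  the ±0.5 s windows overlap, pairing may differ from exhaustive matching.
* The SGN spike detector assumes single-unit recordings; no spike sorting.
* `run_pipeline()` covers the common synthetic/end-to-end stage layouts;
  bespoke analyses should call the module functions directly.
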