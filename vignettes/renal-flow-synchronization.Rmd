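---
title: "Methods: frequency locking and phase waves in renal microcirculatory blood flow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: frequency locking and phase waves in renal microcirculatory blood flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(renalsync)
```

## The problem

Each nephron regulates its own blood supply through tubuloglomerular
feedback (TGF), a delayed negative feedback loop that makes afferent
arteriolar flow oscillate slowly (roughly 0.015–0.05 Hz, periods of
30–60 s), on top of a faster myogenic rhythm (0.1–0.2 Hz). Nephrons are
not independent: they share vasculature and electrical signaling, and
neighboring units can lock to a common TGF frequency. `renalsync`
implements a full analysis chain for quantifying that locking across the
many microcirculatory vessels visible in high-resolution laser speckle
contrast imaging (LSCI) of the renal surface: how strongly the field
synchronizes, how synchronization clusters, how long vessel pairs stay
locked as a function of distance, and whether the phase within a locked
cluster is spatially organized as a traveling plane wave.

Because raw recordings of this kind are large and not bundled with a
package, every stage is paired with a synthetic-scene generator that
produces the same kinds of data with known ground truth; the test suite
and the acceptance script quantify each stage against that truth.

## From raw frames to flow traces

**Registration.** Raw speckle frames have no stable intensity landmarks,
so registration keys on a dark U-shaped fiducial marker resting on the
cover glass. `segment_marker()` thresholds each frame (after a small box
smoothing, default 3 px, without which the marker's partially covered
edge pixels flicker across the threshold frame by frame), keeps the
largest below-threshold component, and returns a darkness-weighted
centroid — continuous in sub-pixel motion, unlike the centroid of the
binary mask. `estimate_translation()` reports per-frame offsets against
frame 1 at sub-pixel precision; `apply_registration()` shifts frames
back by the rounded offset (interpolation would blur the speckle
statistics that the next step depends on) and flags pixels not observed
in every frame. Offsets larger than half the field abort with an error:
that much motion means the recording cannot be used.

**Temporal contrast and flow.** `temporal_contrast()` computes, per pixel
and per window of 25 frames, K = sample SD / mean of intensity; faster
flow blurs speckle and lowers K. Windows are non-overlapping by default
(50 fps → 2 Hz flow sampling), the stride is configurable. The sample
(n−1) SD is used; with 25-frame windows the difference from the
population SD is a fixed factor absorbed into the relative index.
`contrast_to_bfi()` applies BFI = 1/K², flooring K at `k_floor` (default
0.01) so static pixels saturate at `bfi_cap` = 1/k_floor² instead of
overflowing. BFI is a relative index, not an absolute velocity.

**Vessels.** Vessels stand out as bright elongated structures in the
time-averaged BFI map. `segment_vessels()` applies a local-mean adaptive
threshold (odd block, default 51 px at acquisition resolution; the
original workflow's interactive clean-up is replaced by a deterministic
exclusion-mask file) and keeps connected components with areas between
`min_area` and `max_area` — the lower bound drops speckle-scale
artifacts, the upper bound drops occasional large surface vessels.
`extract_traces()` averages BFI over each label and normalizes each
trace by its own time mean (relative blood flow, rbf).

## Dominant-frequency tracking

`cwt_tgf()` computes a continuous wavelet transform of each rbf trace at
18 fixed, logarithmically spaced analysis frequencies spanning
0.015–0.05 Hz. The grid is part of the method: two vessels count as
synchronized when their dominant bins coincide exactly, so the band and
bin count are frozen (both are constructor arguments of `tgf_grid()`,
but the defaults define the analysis).

The wavelet is a generalized Morse wavelet with γ = 3 and β = 20
(time-bandwidth P² = 60, the default shape of the major wavelet
toolboxes). The shape matters: with a much shorter wavelet (e.g. β = 3)
the per-sample magnitude profile across the grid is noisy enough that
the argmax flips between adjacent bins vessel by vessel, and exact-bin
matching collapses even for perfectly locked oscillators. β = 20 holds a
stable dominant bin under 10% multiplicative trace noise while still
resolving two tones at opposite ends of the band. Coefficients are
amplitude-normalized (peak filter response 2, so a unit sinusoid gives
ridge magnitude ~1 at any bin): the across-bin argmax is not biased by
scale. Samples closer to a record edge than the wavelet's e-folding
half-width at that frequency (computed numerically once per shape) are
outside the cone of influence and marked accordingly.

`dominant_track()` then takes, per time sample, the argmax bin (ties
toward the lower bin), the coefficient's argument as the phase, and
declares the sample **valid** when three conditions hold:

1. the sample is inside the cone of influence at the dominant bin;
2. the normalized topographic prominence of the peak across the 18-bin
   profile (band ends treated as walls, prominence divided by peak
   height) is at least `prominence_min` = 0.10;
3. the peak magnitude is at least `snr_min` = 2 times the expected
   white-noise coefficient magnitude at that bin, with the trace's noise
   level estimated from its first differences (slow TGF/myogenic
   components contribute almost nothing to lag-1 differences at 2 Hz)
   and the per-bin noise gain of each wavelet filter computed exactly.

The third condition deserves a note. Prominence alone does not separate
"no TGF activity" from "TGF activity": for a pure-noise trace the
magnitude profile across a 1.7-octave band wanders enough that its
argmax is prominent most of the time (measured ≈ 94% of samples at the
0.10 threshold). The noise floor is what makes the activity criterion
discriminating — and it is scale-free, because both the dominant
magnitude and the estimated floor scale with the trace's noise level.
With the default settings a noise-only vessel is valid ≈ 10% of the
time, while vessels with ≥ 5% TGF flow modulation are valid essentially
everywhere in-cone. One known limitation: an oscillation within about
one bin of the band edge loses prominence (the profile cannot descend
on the wall side) and is often discarded; frequencies near the band
center are unaffected.

## Synchronization statistics

`match_state()` forms the boolean pair-match array (valid + equal bins;
a ±1-bin tolerance is available but off by default). From it:

- `sync_degree()`: S(t) = L(t)/(N(N−1)) with L the ordered matching
  pairs. All vessels matching gives S = 1 exactly. N stays at the full
  segmented count even when some vessels are invalid at t (the
  alternative, N = valid count, is selectable); times with fewer than
  two valid vessels are NA.
- `run_length_filter()`: erases locked runs shorter than `min_periods`
  (default 3) divided by the run's mean shared frequency — at 0.03 Hz a
  120 s lock survives, a 90 s lock does not. The filter never adds
  locked time and is idempotent. Unfiltered and filtered match states
  are both kept, because the membership histogram is reported in both
  conventions.
- `cluster_membership_probability()`: the histogram, over valid
  vessel-times, of "matching vessels / (N−1)" in 5%-wide bins.
- `duration_vs_distance()`: per-pair locked fraction (matched samples /
  total observation samples) averaged in 0.1 mm distance bins over
  [0, 1.5] mm; empty bins are NA, not zero.
- `phase_class_fractions()`: in-phase |Δ| ≤ π/12, anti-phase
  |Δ| ≥ 11π/12, intermediate otherwise, over all matched pair-samples.
- `phase_slope_vs_distance()`: least-squares slope of per-pair mean |Δ|
  against pair distance, in rad/mm.

**Nulls.** Two complementary nulls are computed. `null_calibration()`
assigns each vessel an independent uniform random bin; the expected S is
exactly 1/n_bins (≈ 0.056 for 18 bins), independent of the number of
vessels. `noise_trace_null()` pushes pure-noise traces through the
whole wavelet stage instead; its value depends on the validity rule (with
the defaults almost all noise samples are discarded, so S is near 0 and
mostly undefined). Both are reported by the acceptance script; neither
is a tunable target. A much larger null value would be obtained only if
noise-driven dominant bins were accepted as valid — which the validity
rule is designed to prevent.

## Phase waves

Within a locked cluster, `largest_cluster()` selects the modal dominant
bin over a window (ties toward the lower bin) and its members (modal bin
equal, valid at least half the window). `fit_phase_plane()` fits
φ_i ≈ a + g·x_i over member centroids by least squares; λ = 2π/|g| is
the spatial period and v = λ·f̄ the plane-wave propagation speed at the
cluster's mean dominant frequency. Phases are first unwrapped spatially
along a minimum spanning tree of the centroids (`ape::mst`), because a
least-squares fit on wrapped phases is biased once the field spans more
than ~π of phase; the unwrap is exact while neighbor-to-neighbor steps
stay below π, and fields with |g|·extent ≫ 2π remain out of reach.
Speed is defined kinematically as λ·f̄ and reported as such — it is a
derived quantity of the fit, not an independently tracked wavefront.
`track_wave()` repeats the fit over sliding windows (3 mean TGF periods,
stepped by 1) averaging per-sample gradients within each window, and
reports the direction change between windows; a window whose mean
gradient vanishes (|g| < 1e-9 rad/mm) reports λ as missing rather than
infinite.

## The synthetic scene generator

`make_scene()` emulates the study acquisitions: a 1.5 × 1.5 mm field,
50 fps raw rate, 25-frame contrast windows (2 Hz flow sampling), tens of
vessels drawn as random-orientation capsules (elongated segments — the
shape of microvessel fragments in a surface projection, with no attempt
at a connected vascular tree), organized into frequency-locked clusters
with per-cluster piecewise-constant frequency schedules and spatial
phase-gradient terms, so plane phase waves exist by construction.
Defaults: 128 × 128 px over the full 1.5 mm field (≈ 11.7 µm pixels —
phase-gradient recovery needs the physical extent, while
acquisition-resolution pixel geometry is exercised separately by the
speckle path at small fields), 1200 s, 30 vessels in two equal clusters
at 0.022 and 0.035 Hz carrying gradients of 0.71 and 1.59 rad/mm, TGF
modulation 0.2 (the oscillation amplitude relative to baseline is not a
published number; 20% is a configurable choice that leaves the recovery
problem non-trivial at 10% noise), myogenic modulation 0.1 at 0.15 Hz,
multiplicative noise 0.1.

Noise enters at vessel level (shared by a vessel's pixels, i.i.d. in
time): the per-vessel trace is the unit of analysis, and pixel-level
sensor noise is represented separately by the speckle sampler.
Non-oscillating vessels emit baseline + noise only, exercising the
validity filter. `render_bfi_movie()` draws the flow movie directly at
2 Hz; `render_speckle_stack()` instead draws raw-rate gamma intensities
whose per-window CV equals K = 1/sqrt(BFI) (gamma: strictly positive,
two parameters pin mean and CV), stamps the dark U marker with
anti-aliased sub-pixel coverage, and applies per-frame translations.
What the generator does **not** emulate: spatial speckle grain and
exposure-time integrals, flow heterogeneity within a vessel, vessel
curvature, non-translational motion, slow drifts of baseline flow.
Passing tests therefore demonstrate correctness of the analysis chain
under the stated signal model, not robustness to every artifact of real
recordings.

## Numerical and design notes

- Reproducibility: every scene owns a seed; renderers use derived seeds
  (`seed + 1`, `seed + 2`) under a local RNG state, so identical configs
  give bit-identical outputs and library calls never disturb the
  caller's RNG stream.
- Problem sizes: the default scene (30 vessels × 2400 samples) runs the
  full pipeline in about a minute on one CPU; unit tests use smaller
  scenes (≤ 96 px, ≤ 600 s) chosen so the whole suite stays in a few
  minutes while keeping every statistic estimable.
- Ties: argmax ties break toward the lower bin, everywhere (dominant
  bin, modal cluster bin, largest-cluster size ties).
- Degenerate inputs are errors, not guesses: empty marker masks name the
  frames, zero-mean contrast windows name the pixel, collinear centroids
  refuse a 2-D gradient, a single distance refuses a slope.
- Condition comparisons (`compare_conditions()`) treat seeds as paired
  replicates across synthetic conditions and delegate to `t.test(...,
  paired = TRUE)`; the synthetic high-/low-coupling presets differ in
  cluster structure and TGF amplitude only.
- The random-assignment minimum S reported for ~100 vessels on an
  18-bin grid is ≈ 0.05 here, not ~0.25: a uniform assignment null
  cannot exceed ~1/18 on average, and the larger published figure must
  involve a different notion of "random dominant frequencies" (plausibly
  noise pushed through a wavelet stage whose outputs are accepted as
  valid, which correlates neighboring bins). Both nulls above are
  computed so the distinction stays visible.
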