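# renalsync

Synchronization analysis of renal microcirculatory blood flow imaged
with laser speckle contrast imaging (LSCI).

Each nephron's tubuloglomerular feedback (TGF) loop makes its blood
supply oscillate slowly (~0.015–0.05 Hz). Neighboring nephrons couple —
hemodynamically and electrically — and can lock to a common TGF
frequency, forming clusters that may carry traveling phase waves. This
package implements the full analysis chain for quantifying that
behavior from time-lapse speckle recordings of the renal surface, plus a
ground-truthed synthetic-scene generator so every stage is testable
without any external data. It is aimed at renal physiologists and
biomedical-imaging researchers working with full-field flow recordings.

## The pipeline

1. **Registration** — segment the dark U-shaped fiducial marker in every
   frame by thresholding, estimate per-frame translation from its
   (darkness-weighted) centroid, shift frames back
   (`segment_marker()`, `estimate_translation()`, `apply_registration()`).
2. **Flow** — temporal speckle contrast K = sd/mean per pixel over
   25-frame windows, then blood flow index BFI = 1/K²
   (`temporal_contrast()`, `contrast_to_bfi()`).
3. **Vessels** — adaptive thresholding of the time-averaged BFI map,
   area-filtered connected components, per-vessel relative-flow traces
   (`segment_vessels()`, `extract_traces()`).
4. **Spectral tracking** — generalized Morse wavelet (γ = 3, β = 20) on a
   fixed 18-bin log grid over 0.015–0.05 Hz; per sample the dominant bin,
   its phase, and a validity flag (cone of influence, ≥ 10% normalized
   peak prominence, noise-adaptive amplitude floor)
   (`tgf_grid()`, `cwt_tgf()`, `dominant_track()`).
5. **Synchronization** — vessels are synchronized while their dominant
   bins match. Synchronization degree

   S(t) = L(t) / (N·(N−1)),

   with L the ordered frequency-matching pairs and N the segmented
   vessel count (S = 1 when the whole field locks); cluster-membership
   histograms; locking runs filtered at ≥ 3 TGF periods; locked fraction
   vs distance; in-phase (|Δφ| ≤ π/12) / anti-phase (|Δφ| ≥ 11π/12)
   fractions; |Δφ| slope vs distance
   (`match_state()`, `sync_degree()`, `run_length_filter()`, ...).
6. **Phase waves** — plane fit φ ≈ a + g·x over the largest cluster's
   centroids (phases unwrapped along a minimum spanning tree): spatial
   period λ = 2π/|g|, speed v = λ·f̄, direction tracking over time
   (`largest_cluster()`, `fit_phase_plane()`, `track_wave()`).
7. **Orchestration** — `run_all()` executes everything from a scene
   config with a full manifest; `compare_conditions()` compares
   synthetic conditions with paired t-tests across seeds.

The methods vignette (`vignettes/renal-flow-synchronization.Rmd`)
documents the model, parameter choices and limitations.

## Worked example

```r
library(renalsync)

# default study-scale scene: 1.5 x 1.5 mm, 1200 s at 2 Hz flow sampling,
# 30 vessels in two frequency-locked clusters (0.022 / 0.035 Hz) with
# phase gradients 0.71 and 1.59 rad/mm, 20% TGF modulation, 10% noise
cfg <- scene_config(seed = 1)
bundle <- run_all(cfg, use_truth_masks = TRUE)
bundle
#> run_bundle [baseline, seed 1]: 30 vessels, S = 0.450 +/- 0.058,
#>   locked 0.40, slope 0.62 rad/mm

round(bundle$metrics$S_mean, 3)
#> [1] 0.45     # configured two-cluster value: 2*15*14/(30*29) = 0.483
head(bundle$waves[, c("t_start_s", "lambda_mm", "speed_mm_per_s", "r2")], 3)
#>   t_start_s lambda_mm speed_mm_per_s        r2
#> 1         0  3.908850      0.1371732 0.9935970
#> 2        35  3.954794      0.1387808 0.9944256
#> 3        70  4.007744      0.1406313 0.9954931
# the largest cluster here is the 0.035 Hz one carrying the 1.59 rad/mm
# gradient: lambda ~ 2*pi/1.59 = 3.95 mm
```

The S(t) series, cluster histograms, per-distance locked fractions,
phase statistics and wave fits live in `bundle$sync` and
`bundle$waves`; `write_run_bundle(bundle, dir)` serializes them as CSV +
JSON. A thin CLI (`inst/exec/renalsync`) wraps `simulate` and `run-all`
behind a YAML config.

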