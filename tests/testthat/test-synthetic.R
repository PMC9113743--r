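test_that("scene generation is deterministic and builds phase waves by construction", {
  cfg <- scene_config(field_size_px = c(64, 64), pixel_size_mm = 1.5 / 64,
                      duration_s = 300, n_vessels = 6,
                      cluster_spec = list(list(frac = 1, freq_hz = 0.03,
                                               gradient = c(0.71, 0))),
                      seed = 42L)
  tr1 <- make_scene(cfg)
  tr2 <- make_scene(cfg)
  expect_identical(tr1, tr2)

  # phase difference between members equals gradient . displacement, always
  dx_mm <- tr1$centroids_mm[2, 1] - tr1$centroids_mm[1, 1]
  dphi <- tr1$phase_truth_rad[2, ] - tr1$phase_truth_rad[1, ]
  expect_equal(unname(dphi), rep(unname(0.71 * dx_mm), length(tr1$time_s)),
               tolerance = 1e-12)

  # zero gradient: shared schedule, identical phases
  cfg0 <- scene_config(field_size_px = c(64, 64), duration_s = 300,
                       n_vessels = 2,
                       cluster_spec = list(list(frac = 1, freq_hz = 0.03,
                                                gradient = c(0, 0))),
                       seed = 7L)
  tr0 <- make_scene(cfg0)
  expect_equal(tr0$phase_truth_rad[1, ], tr0$phase_truth_rad[2, ],
               tolerance = 1e-12)

  # every labeled vessel has >= 1 pixel and centroids sit inside the field
  expect_true(all(tabulate(tr1$labels[tr1$labels > 0], 6) >= 1))
  expect_true(all(tr1$centroids_px >= 1 & tr1$centroids_px <= 64))

  # plane-fit of noise-free truth phases returns the configured gradient
  fit <- fit_phase_plane(tr1$phase_truth_rad[, 100], tr1$centroids_mm)
  expect_equal(fit$gradient_rad_per_mm, c(0.71, 0), tolerance = 1e-9)
})

test_that("scene config rejects invalid study parameters", {
  expect_error(scene_config(cluster_spec = list(list(frac = 1, freq_hz = 0.08,
                                                     gradient = c(0, 0)))),
               "0.015")
  expect_error(scene_config(cluster_spec = list(
    list(frac = 0.7, freq_hz = 0.03, gradient = c(0, 0)),
    list(frac = 0.7, freq_hz = 0.04, gradient = c(0, 0)))),
    "sum")
  expect_error(scene_config(duration_s = 10.007), "integer frame count")
  expect_error(scene_config(tgf_amp = -0.1), ">= 0")
  expect_error(scene_config(myogenic_freq_hz = 0.4), "myogenic")
  # infeasible density errors out with the density in the message
  dense <- scene_config(field_size_px = c(24, 24), duration_s = 10,
                        n_vessels = 60, seed = 1L)
  expect_error(make_scene(dense), "density")
})

test_that("rendered BFI movie carries the scheduled oscillations", {
  # no modulation, no noise -> constant movie
  cfg <- scene_config(field_size_px = c(32, 32), duration_s = 200,
                      n_vessels = 3, tgf_amp = 0, myogenic_amp = 0,
                      noise_cv = 0,
                      cluster_spec = list(list(frac = 1, freq_hz = 0.03,
                                               gradient = c(0, 0))),
                      seed = 3L)
  mv <- render_bfi_movie(make_scene(cfg))
  expect_equal(max(mv$bfi) - min(mv$bfi), 3)  # two constant levels: 4 and 1
  expect_equal(diff(range(apply(mv$bfi, 3, mean))), 0, tolerance = 1e-12)

  # tgf_amp = 0.2 at 0.03 Hz, no noise -> periodogram peak at 0.03 Hz
  cfg2 <- scene_config(field_size_px = c(48, 48), duration_s = 600,
                       n_vessels = 4, myogenic_amp = 0, noise_cv = 0,
                       cluster_spec = list(list(frac = 1, freq_hz = 0.03,
                                                gradient = c(0, 0))),
                       seed = 4L)
  tr <- make_scene(cfg2)
  mv2 <- render_bfi_movie(tr)
  vt <- extract_traces(mv2, vessel_map_from_labels(tr$labels, cfg2$pixel_size_mm))
  for (v in 1:4)
    expect_equal(periodogram_peak_hz(vt$traces[v, ], vt$sample_rate_hz), 0.03,
                 tolerance = 0.002)

  # two clusters: traces correlate more within than across clusters
  sb <- small_scene_bundle()
  vt2 <- extract_traces(sb$movie,
                        vessel_map_from_labels(sb$truth$labels,
                                               sb$cfg$pixel_size_mm))
  cl <- sb$truth$cluster_labels
  cc <- stats::cor(t(vt2$rbf))
  within <- cc[outer(cl, cl, "==") & upper.tri(cc)]
  across <- cc[outer(cl, cl, "!=") & upper.tri(cc)]
  expect_gt(mean(within), mean(across))

  # determinism of the renderer
  expect_identical(render_bfi_movie(tr), render_bfi_movie(tr))
})

test_that("speckle stack realizes the prescribed temporal contrast and marker", {
  # BFI_target = 4 everywhere -> per-pixel-window temporal contrast ~ 0.5
  cfg <- scene_config(field_size_px = c(32, 32), pixel_size_mm = 0.0015,
                      duration_s = 30, n_vessels = 0, background_bfi = 4,
                      noise_cv = 0, seed = 2L)
  st <- render_speckle_stack(make_scene(cfg))
  expect_true(all(st$frames > 0))
  K <- temporal_contrast(st)$k
  expect_equal(mean(K), 0.5, tolerance = 0.02)

  # marker stamped dark: thresholding the mean frame recovers >= 95% of it
  mk <- default_marker_spec(field_size_px = c(48, 48))
  cfgm <- scene_config(field_size_px = c(48, 48), pixel_size_mm = 0.0015,
                       duration_s = 4, n_vessels = 0, background_bfi = 9,
                       noise_cv = 0, marker_spec = mk, seed = 5L)
  stm <- render_speckle_stack(make_scene(cfgm))
  mean_frame <- rowMeans(stm$frames, dims = 2)
  got <- mean_frame < 0.5 * cfgm$mean_intensity
  truth_mask <- marker_coverage(cfgm) >= 0.99
  expect_gte(mean(got[truth_mask]), 0.95)

  # motion schedule: marker centroid shifts by (3, -2) px from frame k
  n_frames <- cfgm$n_frames
  mot <- matrix(0, n_frames, 2)
  mot[101:n_frames, ] <- rep(c(3, -2), each = n_frames - 100)
  cfg_mv <- scene_config(field_size_px = c(48, 48), pixel_size_mm = 0.0015,
                         duration_s = 4, n_vessels = 0, background_bfi = 9,
                         noise_cv = 0, marker_spec = mk,
                         motion_schedule = mot, seed = 6L)
  stv <- render_speckle_stack(make_scene(cfg_mv))
  mm <- segment_marker(stv, 0.25 * cfg_mv$mean_intensity)
  shift_obs <- mm$centroids[150, ] - mm$centroids[50, ]
  expect_equal(unname(shift_obs), c(3, -2), tolerance = 0.5)

  # determinism
  trm <- make_scene(cfgm)
  expect_identical(render_speckle_stack(trm), render_speckle_stack(trm))
})
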