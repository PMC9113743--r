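test_that("temporal contrast matches the direct sd/mean formula", {
  # worked window: five frames at 200, twenty at 100
  vals <- rep(c(200, 100), c(5, 20))
  st <- frame_stack(array(vals, c(1, 1, 25)), 50, 0.0015)
  k <- temporal_contrast(st)$k[1, 1, 1]
  expect_equal(k, sd(vals) / mean(vals), tolerance = 1e-12)
  expect_equal(k, 0.3402, tolerance = 1e-4)

  # constant window -> K = 0; scale invariance of the CV
  stc <- frame_stack(array(7, c(2, 2, 25)), 50, 0.0015)
  expect_true(all(temporal_contrast(stc)$k == 0))

  set.seed(1)
  a <- array(rgamma(4 * 3 * 50, 5, 1), c(4, 3, 50))
  k1 <- temporal_contrast(frame_stack(a, 50, 0.0015))$k
  k2 <- temporal_contrast(frame_stack(3.7 * a, 50, 0.0015))$k
  expect_equal(k1, k2, tolerance = 1e-12)

  # windowed implementation equals a naive per-window loop
  naive <- array(NA_real_, c(4, 3, 2))
  for (i in 1:4) for (j in 1:3) for (w in 1:2) {
    win <- a[i, j, (w - 1) * 25 + 1:25]
    naive[i, j, w] <- sd(win) / mean(win)
  }
  expect_equal(k1, naive, tolerance = 1e-10)

  # stride shorter than the window gives overlapping samples
  k3 <- temporal_contrast(frame_stack(a, 50, 0.0015), window_len = 25, stride = 5)
  expect_equal(dim(k3$k)[3], floor((50 - 25) / 5) + 1)
  expect_equal(k3$sample_rate_hz, 10)
})

test_that("temporal contrast rejects degenerate input", {
  expect_error(temporal_contrast(frame_stack(array(1, c(2, 2, 10)), 50, 0.0015)),
               "window")
  z <- array(1, c(2, 2, 25)); z[1, 2, ] <- 0
  expect_error(temporal_contrast(frame_stack(z, 50, 0.0015)), "zero-mean")
  expect_error(frame_stack(array(-1, c(2, 2, 25)), 50, 0.0015), ">= 0")
})

test_that("BFI = 1/K^2 with the k_floor cap, strictly decreasing in K", {
  kv <- array(c(0.5, 1, 0, 0.05), c(2, 2, 1))
  cm <- structure(list(k = kv, sample_rate_hz = 2, window_len = 25,
                       stride = 25, pixel_size_mm = 0.0015),
                  class = "contrast_movie")
  b <- contrast_to_bfi(cm, k_floor = 0.05)
  expect_equal(b$bfi[1, 1, 1], 4)
  expect_equal(b$bfi[2, 1, 1], 1)
  expect_equal(b$bfi[1, 2, 1], 400)   # K = 0 absorbed by the floor
  expect_equal(b$bfi_cap, 400)
  expect_true(all(b$bfi <= b$bfi_cap))

  ks <- seq(0.02, 2, by = 0.01)
  cm2 <- structure(list(k = array(ks, c(1, 1, length(ks))), sample_rate_hz = 2,
                        window_len = 25, stride = 25, pixel_size_mm = 0.0015),
                   class = "contrast_movie")
  bf <- as.vector(contrast_to_bfi(cm2, k_floor = 0.01)$bfi)
  expect_true(all(diff(bf) < 0))
  expect_error(contrast_to_bfi(cm, k_floor = 0), "k_floor")
})

test_that("marker segmentation, translation estimation and registration recover known motion", {
  mk <- default_marker_spec(field_size_px = c(48, 48))
  n_frames <- 200L
  mot <- matrix(0, n_frames, 2)
  mot[101:n_frames, 1] <- 3
  mot[101:n_frames, 2] <- -2
  cfg <- scene_config(field_size_px = c(48, 48), pixel_size_mm = 0.0015,
                      duration_s = 4, n_vessels = 0, background_bfi = 9,
                      noise_cv = 0, marker_spec = mk, motion_schedule = mot,
                      seed = 5L)
  st <- render_speckle_stack(make_scene(cfg))
  thr <- 0.25 * cfg$mean_intensity

  # per-frame mask (unsmoothed) overlaps >= 95% of true marker pixels
  mm_raw <- segment_marker(st, thr, smooth_px = 1)
  truth_mask <- marker_coverage(cfg) >= 0.99
  overlaps <- vapply(seq_len(n_frames), function(t)
    mean(mm_raw$masks[, , t][marker_coverage(cfg, mot[t, ]) >= 0.99]),
    numeric(1))
  expect_gte(min(overlaps), 0.95)

  # centroid track: offsets match the schedule; integer shifts round exactly
  et <- estimate_translation(segment_marker(st, thr))
  expect_equal(unname(et[1, ]), c(0, 0))
  expect_true(all(abs(et - mot) < 0.5))
  expect_true(all(round(et) == mot))

  # subpixel shift recovered within 0.5 px
  mot2 <- matrix(0, n_frames, 2); mot2[101:n_frames, 1] <- 0.5
  cfg2 <- scene_config(field_size_px = c(48, 48), pixel_size_mm = 0.0015,
                       duration_s = 4, n_vessels = 0, background_bfi = 9,
                       noise_cv = 0, marker_spec = mk, motion_schedule = mot2,
                       seed = 6L)
  et2 <- estimate_translation(
    segment_marker(render_speckle_stack(make_scene(cfg2)), thr))
  expect_true(all(abs(et2[101:n_frames, 1] - 0.5) < 0.5))

  # registration with the estimated track leaves the marker stationary
  reg <- apply_registration(st, et)
  cent <- segment_marker(reg, thr)$centroids
  expect_lt(max(abs(sweep(cent, 2, cent[1, ]))), 0.5)
  expect_true(is.matrix(attr(reg, "valid_mask")))

  # zero track is the identity
  zero <- structure(matrix(0, n_frames, 2),
                    class = c("translation_track", "matrix"))
  expect_equal(apply_registration(st, zero)$frames, st$frames)

  # contract violations
  expect_error(apply_registration(st, zero[1:10, , drop = FALSE]), "frames")
  big <- zero; big[5, 1] <- 40
  expect_error(apply_registration(st, big), "implausible")
  bright <- frame_stack(array(1000, c(8, 8, 3)), 50, 0.0015)
  expect_error(segment_marker(bright, 10), "below marker threshold")
})
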