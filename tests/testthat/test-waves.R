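test_that("plane fit recovers constructed gradients and the lambda identity", {
  set.seed(17)
  xy <- cbind(x = runif(12, 0, 1.5), y = runif(12, 0, 1.5))
  f <- fit_phase_plane(0.2 + 0.5 * xy[, 1] - 0.3 * xy[, 2], xy)
  expect_equal(f$gradient_rad_per_mm, c(0.5, -0.3), tolerance = 1e-9)
  gn <- sqrt(sum(f$gradient_rad_per_mm^2))
  expect_equal(f$spatial_period_mm * gn, 2 * pi, tolerance = 1e-12)
  expect_equal(sqrt(sum(f$direction^2)), 1, tolerance = 1e-12)
  expect_equal(f$fit_r2, 1, tolerance = 1e-9)

  # |g| = 2*pi rad/mm -> lambda = 1 mm; speed = lambda * fbar
  f2 <- fit_phase_plane(2 * pi * xy[, 1], xy, fbar = 0.03)
  expect_equal(f2$spatial_period_mm, 1, tolerance = 1e-9)
  expect_equal(f2$speed_mm_per_s, 0.03, tolerance = 1e-9)

  # normal-equations oracle
  phi <- 0.1 + 0.8 * xy[, 1] + 0.2 * xy[, 2] + rnorm(12, 0, 0.01)
  A <- cbind(1, xy)
  beta_ne <- solve(t(A) %*% A, t(A) %*% phi)
  f3 <- fit_phase_plane(phi, xy, unwrap = FALSE)
  expect_equal(f3$gradient_rad_per_mm, unname(beta_ne[2:3]), tolerance = 1e-10)

  # degenerate geometry
  line <- cbind(seq(0, 1, length.out = 5), 2 * seq(0, 1, length.out = 5))
  expect_error(fit_phase_plane(rnorm(5), line), "collinear")
  expect_error(fit_phase_plane(c(1, 2), xy[1:2, ]), ">= 3")
})

test_that("fitted direction is rotation-equivariant", {
  set.seed(19)
  xy <- cbind(runif(10), runif(10))
  g0 <- c(0.9, 0.4)
  phi <- xy %*% g0
  f0 <- fit_phase_plane(as.vector(phi), xy)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  f1 <- fit_phase_plane(as.vector(phi), xy %*% t(R))
  expect_equal(f1$direction, as.vector(R %*% f0$direction), tolerance = 1e-9)
  expect_equal(f1$spatial_period_mm, f0$spatial_period_mm, tolerance = 1e-9)
})

test_that("spatial unwrapping lets steep phase ramps be fitted", {
  # 4 rad/mm over a 1.5 mm field spans ~6 rad: wrapped phases would bias a
  # naive fit, the spanning-tree unwrap restores the ramp
  gx <- 4
  xy <- as.matrix(expand.grid(x = seq(0, 1.5, by = 0.25),
                              y = seq(0, 1, by = 0.5)))
  phi_wrapped <- wrap_phase(gx * xy[, 1])
  f <- fit_phase_plane(phi_wrapped, xy)
  expect_equal(f$gradient_rad_per_mm, c(gx, 0), tolerance = 1e-6)
})

test_that("largest cluster selection counts modal bins with documented ties", {
  # single global cluster: every valid vessel is a member
  trk <- make_track_set(matrix(6L, 9, 10))
  cl <- largest_cluster(trk)
  expect_equal(cl$members, 1:9)
  expect_equal(cl$bin, 6)

  # 12 vs 8 vessels (larger cluster at the higher bin): the 12 win
  bins <- matrix(c(rep(9L, 12), rep(3L, 8)), 20, 10)
  cl2 <- largest_cluster(make_track_set(bins))
  expect_equal(cl2$members, 1:12)
  expect_equal(cl2$bin, 9)

  # exact tie in size: lower bin index wins
  bins3 <- matrix(c(rep(9L, 10), rep(3L, 10)), 20, 10)
  expect_equal(largest_cluster(make_track_set(bins3))$bin, 3)

  # members must be valid at least half the window
  v <- matrix(TRUE, 9, 10); v[1, ] <- c(rep(FALSE, 6), rep(TRUE, 4))
  cl4 <- largest_cluster(make_track_set(matrix(6L, 9, 10), valid = v))
  expect_false(1 %in% cl4$members)
  expect_error(largest_cluster(make_track_set(matrix(6L, 2, 3),
                                              valid = matrix(FALSE, 2, 3))),
               "no valid")
})

test_that("wave tracking reports direction changes and degenerate windows", {
  fs <- 2
  T0 <- 1200  # 600 s
  g <- tgf_grid()
  b <- which.min(abs(g$centers_hz - 0.03))
  f0 <- g$centers_hz[b]
  set.seed(23)
  xy <- cbind(x = runif(12, 0, 1.5), y = runif(12, 0, 1.5))
  tt <- (seq_len(T0) - 1) / fs
  base <- 2 * pi * f0 * tt

  # two epochs with the gradient rotated by 90 degrees at t = 300 s
  phase <- matrix(NA_real_, 12, T0)
  for (v in 1:12) {
    sp <- ifelse(tt < 300, 0.71 * xy[v, 1], 0.71 * xy[v, 2])
    phase[v, ] <- wrap_phase(base + sp)
  }
  trk <- make_track_set(matrix(b, 12, T0), phase = phase, fs = fs)
  tw <- track_wave(trk, xy, window_periods = 3, step_periods = 1)
  expect_equal(max(tw$direction_change_deg, na.rm = TRUE), 90, tolerance = 5)
  # away from the switch the direction is static
  early <- tw$direction_change_deg[tw$t_end_s < 290]
  expect_lt(max(early, na.rm = TRUE), 2)
  expect_equal(tw$lambda_mm[1], 2 * pi / 0.71, tolerance = 0.01)

  # vanishing gradient: lambda reported missing, not infinite
  phase0 <- matrix(rep(wrap_phase(base), each = 12), 12, T0)
  tw0 <- track_wave(make_track_set(matrix(b, 12, T0), phase = phase0, fs = fs),
                    xy)
  expect_true(all(is.na(tw0$lambda_mm)))
})
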