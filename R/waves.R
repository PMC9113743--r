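# Plane phase waves over frequency-locked clusters.
#
# Within a frequency-locked cluster the oscillation phase changes
# gradually with position: a traveling plane wave. Fitting
# phi_i ~ a + g . x_i over the member centroids gives the phase-gradient
# vector g (rad/mm); the spatial period is lambda = 2*pi/|g| and the
# propagation speed v = lambda * fbar with fbar the cluster's mean
# dominant frequency (plane-wave kinematics). Phases are spatially
# unwrapped along a minimum spanning tree of the centroids before fitting,
# since a least-squares fit on wrapped phases is biased once the field
# spans more than ~pi of phase.

#' Members of the largest frequency-locked cluster in a time window
#'
#' The cluster bin is the modal dominant bin over all valid vessel-time
#' samples in the window (ties toward the lower bin); members are vessels
#' whose own modal bin equals it and that are valid for at least half of
#' the window.
#'
#' @param tracks a `track_set`.
#' @param t_idx sample indices of the window (default: all samples).
#' @return list with `members` (vessel indices), `bin`, `freq_hz`.
#' @export
largest_cluster <- function(tracks, t_idx = NULL) {
  stopifnot(inherits(tracks, "track_set"))
  t_idx <- t_idx %||% seq_len(ncol(tracks$bin))
  b <- tracks$bin[, t_idx, drop = FALSE]
  v <- tracks$valid[, t_idx, drop = FALSE]
  if (!any(v)) stop_f("no valid vessel-time samples in window")
  counts <- tabulate(b[v], nbins = length(tracks$freqs_hz))
  cl_bin <- which.max(counts)  # ties: lower bin
  modal_bin <- apply(ifelse(v, b, NA), 1, function(z) {
    z <- z[!is.na(z)]
    if (!length(z)) return(NA_integer_)
    tb <- tabulate(z, nbins = length(tracks$freqs_hz))
    which.max(tb)
  })
  members <- which(modal_bin == cl_bin & rowMeans(v) >= 0.5)
  list(members = members, bin = cl_bin, freq_hz = tracks$freqs_hz[cl_bin])
}

# Spatially unwrap phases along the minimum spanning tree of the
# centroids: walking the tree from the first member, each node's phase is
# shifted by a multiple of 2*pi so its step from the parent is the wrapped
# difference. Exact when true neighbor-to-neighbor phase steps are < pi.
unwrap_spatial <- function(phases, centroids_mm) {
  n <- length(phases)
  if (n <= 2) return(phases)
  adj <- ape::mst(stats::dist(centroids_mm))
  out <- phases
  visited <- rep(FALSE, n)
  queue <- 1L
  visited[1] <- TRUE
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    nb <- which(adj[i, ] == 1 & !visited)
    for (j in nb) {
      out[j] <- out[i] + wrap_phase(out[j] - out[i])
      visited[j] <- TRUE
      queue <- c(queue, j)
    }
  }
  out
}

#' Fit a plane phase wave at one time sample
#'
#' Least-squares fit of phi_i ~ a + gx*x_i + gy*y_i over the member
#' centroids (phases spatially unwrapped first). Reports the gradient, its
#' direction, the spatial period lambda = 2*pi/|g|, the propagation speed
#' v = lambda*fbar, and the fit R^2.
#'
#' @param phases member phases in radians at one sample.
#' @param centroids_mm member centroid coordinates (n x 2, columns x, y).
#' @param fbar mean dominant frequency of the cluster in Hz (for speed;
#'   NA if not supplied).
#' @param unwrap spatially unwrap phases first (default TRUE).
#' @return object of class `phase_wave_fit`: list with
#'   `gradient_rad_per_mm` c(gx, gy), `direction` (unit vector, NA when
#'   |g| = 0), `spatial_period_mm` (2*pi/|g|, NA when |g| = 0),
#'   `speed_mm_per_s` (lambda*fbar), `fit_r2`, `n`.
#' @examples
#' # |g| = 0.71 rad/mm -> lambda = 2*pi/0.71 = 8.85 mm
#' xy <- cbind(x = runif(10), y = runif(10))
#' f <- fit_phase_plane(0.71 * xy[, "x"], xy)
#' f$spatial_period_mm
#' @export
fit_phase_plane <- function(phases, centroids_mm, fbar = NA_real_,
                            unwrap = TRUE) {
  centroids_mm <- as.matrix(centroids_mm)
  n <- length(phases)
  if (n < 3 || nrow(centroids_mm) != n)
    stop_f("need >= 3 phases with matching centroids, got %d", n)
  cc <- sweep(centroids_mm, 2, colMeans(centroids_mm))
  sv <- svd(cc)$d
  if (sv[2] < 1e-9 * max(sv[1], 1e-300))
    stop_f("centroids are collinear: 2-D phase gradient unidentifiable")
  if (unwrap) phases <- unwrap_spatial(phases, centroids_mm)
  fit <- stats::lm(phases ~ centroids_mm[, 1] + centroids_mm[, 2])
  g <- unname(stats::coef(fit)[2:3])
  gn <- sqrt(sum(g^2))
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((phases - mean(phases))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  lambda <- if (gn > 0) 2 * pi / gn else NA_real_
  structure(list(gradient_rad_per_mm = g,
                 direction = if (gn > 0) g / gn else c(NA_real_, NA_real_),
                 spatial_period_mm = lambda,
                 speed_mm_per_s = lambda * fbar,
                 fit_r2 = r2, n = n),
            class = "phase_wave_fit")
}

#' @export
print.phase_wave_fit <- function(x, ...) {
  cat(sprintf(
    "phase_wave_fit: |g| = %.3f rad/mm, lambda = %.2f mm, v = %.3f mm/s, R2 = %.3f (n = %d)\n",
    sqrt(sum(x$gradient_rad_per_mm^2)), x$spatial_period_mm,
    x$speed_mm_per_s, x$fit_r2, x$n))
  invisible(x)
}

#' Track the phase wave over sliding time windows
#'
#' Splits the record into windows of `window_periods` mean TGF periods
#' stepped by `step_periods`, finds the largest frequency-locked cluster
#' in each window, fits the phase plane at every sample with >= 3 valid
#' non-collinear members, and averages the per-sample gradients within the
#' window. Reports per window the gradient, direction angle, spatial
#' period, speed and mean R^2, plus the direction change between
#' consecutive windows. Windows where the mean gradient vanishes report
#' lambda as NA (missing, not infinite).
#'
#' @param tracks a `track_set`.
#' @param centroids_mm vessel centroids (n x 2) in mm.
#' @param window_periods window length in mean TGF periods (default 3).
#' @param step_periods window step (default 1).
#' @return data.frame with one row per window: `t_start_s`, `t_end_s`,
#'   `n_members`, `gx`, `gy`, `angle_deg`, `lambda_mm`, `speed_mm_per_s`,
#'   `r2`, `direction_change_deg`.
#' @export
track_wave <- function(tracks, centroids_mm, window_periods = 3,
                       step_periods = 1) {
  stopifnot(inherits(tracks, "track_set"))
  fbar_all <- mean(tracks$freq_hz[tracks$valid])
  if (!is.finite(fbar_all)) stop_f("no valid samples to define a TGF period")
  win_n <- max(8, round(window_periods / fbar_all * tracks$fs))
  step_n <- max(1, round(step_periods / fbar_all * tracks$fs))
  T0 <- ncol(tracks$bin)
  starts <- seq(1, max(1, T0 - win_n + 1), by = step_n)
  rows <- list()
  prev_angle <- NA_real_
  for (s in starts) {
    t_idx <- s:min(s + win_n - 1, T0)
    cl <- tryCatch(largest_cluster(tracks, t_idx), error = function(e) NULL)
    if (is.null(cl) || length(cl$members) < 3) next
    mem <- cl$members
    cm <- centroids_mm[mem, , drop = FALSE]
    gs <- matrix(NA_real_, 0, 2)
    r2s <- numeric(0)
    for (t in t_idx) {
      ok <- tracks$valid[mem, t] & tracks$bin[mem, t] == cl$bin
      if (sum(ok) < 3) next
      ft <- tryCatch(
        fit_phase_plane(tracks$phase_rad[mem[ok], t], cm[ok, , drop = FALSE]),
        error = function(e) NULL)
      if (is.null(ft)) next
      gs <- rbind(gs, ft$gradient_rad_per_mm)
      r2s <- c(r2s, ft$fit_r2)
    }
    if (!nrow(gs)) next
    g <- colMeans(gs)
    gn <- sqrt(sum(g^2))
    if (gn < 1e-9) gn <- 0  # numerically vanishing gradient: no wave
    fbar_w <- mean(tracks$freq_hz[mem, t_idx][tracks$valid[mem, t_idx]])
    angle <- if (gn > 0) atan2(g[2], g[1]) * 180 / pi else NA_real_
    dchg <- if (is.na(prev_angle) || is.na(angle)) NA_real_
            else abs(wrap_phase((angle - prev_angle) * pi / 180)) * 180 / pi
    prev_angle <- if (!is.na(angle)) angle else prev_angle
    lambda <- if (gn > 0) 2 * pi / gn else NA_real_
    rows[[length(rows) + 1]] <- data.frame(
      t_start_s = tracks$time_s[t_idx[1]],
      t_end_s = tracks$time_s[t_idx[length(t_idx)]],
      n_members = length(mem), gx = g[1], gy = g[2],
      angle_deg = angle, lambda_mm = lambda,
      speed_mm_per_s = lambda * fbar_w, r2 = mean(r2s),
      direction_change_deg = dchg)
  }
  if (!length(rows)) stop_f("no window produced a phase-plane fit")
  do.call(rbind, rows)
}
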