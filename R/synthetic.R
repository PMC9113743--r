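# Ground-truthed synthetic scenes.
#
# The generator emulates the study acquisitions: a ~1.5 x 1.5 mm field of
# renal surface at 50 fps, tens of microcirculatory vessels (elongated
# segments), TGF-band oscillations (0.015-0.05 Hz) organized in
# frequency-locked clusters carrying plane phase waves, a faster myogenic
# component (0.1-0.2 Hz), multiplicative flow noise, a dark U-shaped
# fiducial marker and lateral motion. Every scene is produced from an
# explicit config + seed and comes with full ground truth (masks, cluster
# labels, frequency/phase schedules, noise-free flow traces) so parameter
# recovery can be tested at every pipeline stage.

#' Synthetic scene configuration
#'
#' Collects every knob of the synthetic renderer with validation. Defaults
#' describe a desk-scale version of the study acquisition: the full
#' 1.5 x 1.5 mm field rendered at 128 x 128 px (pixel pitch ~11.7 um:
#' phase-wave recovery needs the physical extent, not the acquisition pixel
#' pitch), 50 fps raw rate, 25-frame contrast windows (2 Hz flow sampling),
#' 1200 s duration, 30 vessels split into two equal frequency-locked
#' clusters at 0.022 and 0.035 Hz carrying phase gradients of 0.71 and
#' 1.59 rad/mm, 20% TGF modulation, 10% myogenic modulation at 0.15 Hz and
#' 10% multiplicative vessel-level noise.
#'
#' @param field_size_px integer c(width, height) of the field in pixels.
#' @param pixel_size_mm pixel pitch in mm (default 1.5/128 so the default
#'   field spans 1.5 mm; use 0.0015 for acquisition-resolution stacks).
#' @param frame_rate_hz raw frame rate in Hz (default 50).
#' @param duration_s recording length in seconds; `duration_s *
#'   frame_rate_hz` must be an integer frame count.
#' @param n_vessels number of vessels to place.
#' @param vessel_diameter_px,vessel_length_px ranges (min, max) of capsule
#'   diameter and axis length in pixels.
#' @param cluster_spec list of cluster descriptions. Each element is a list
#'   with `frac` (member fraction of n_vessels), `freq_hz` (TGF frequency,
#'   scalar or one per epoch; must lie in \[0.015, 0.05\]), `gradient`
#'   (phase-gradient vector in rad/mm: c(gx, gy), or an epochs x 2 matrix),
#'   and optional `epoch_breaks_s` (interior epoch boundaries). Fractions
#'   must sum to <= 1; the remainder are non-oscillating vessels that emit
#'   baseline + noise only.
#' @param tgf_amp,myogenic_amp relative modulation amplitudes (>= 0).
#' @param myogenic_freq_hz myogenic frequency in Hz (in \[0.1, 0.2\]).
#' @param noise_cv multiplicative noise coefficient of variation. Applied
#'   at vessel level (shared by a vessel's pixels, i.i.d. in time) because
#'   the per-vessel trace is the unit of analysis; background pixels get
#'   i.i.d. pixel noise; pixel-level sensor noise additionally enters
#'   through the speckle sampler of [render_speckle_stack()].
#' @param baseline_bfi,background_bfi blood-flow-index levels of vessel and
#'   background pixels.
#' @param mean_intensity mean speckle intensity in camera counts.
#' @param marker_spec U-marker geometry: list with `center_px` c(x, y),
#'   `width_px`, `height_px`, `thickness_px`, `intensity_frac` (marker
#'   intensity relative to tissue), `contrast_k` (its near-static temporal
#'   contrast). NULL for no marker.
#' @param motion_schedule per-frame c(dx, dy) translation in px: a T x 2
#'   matrix, or NULL for a static scene.
#' @param contrast_window,contrast_stride frames per temporal-contrast
#'   window and window stride (defaults 25/25, giving 2 Hz flow sampling
#'   at 50 fps).
#' @param seed RNG seed owned by the scene.
#' @return validated list of class `scene_config`.
#' @export
scene_config <- function(field_size_px = c(128, 128),
                         pixel_size_mm = 1.5 / 128,
                         frame_rate_hz = 50,
                         duration_s = 1200,
                         n_vessels = 30,
                         vessel_diameter_px = c(2, 5),
                         vessel_length_px = c(6, 14),
                         cluster_spec = list(
                           list(frac = 0.5, freq_hz = 0.022,
                                gradient = c(0.71, 0)),
                           list(frac = 0.5, freq_hz = 0.035,
                                gradient = c(0, 1.59))),
                         tgf_amp = 0.2,
                         myogenic_amp = 0.1,
                         myogenic_freq_hz = 0.15,
                         noise_cv = 0.1,
                         baseline_bfi = 4,
                         background_bfi = 1,
                         mean_intensity = 2000,
                         marker_spec = NULL,
                         motion_schedule = NULL,
                         contrast_window = 25,
                         contrast_stride = 25,
                         seed = 1L) {
  cfg <- as.list(environment())
  if (length(field_size_px) != 2 || any(field_size_px < 8))
    stop_f("field_size_px must be two integers >= 8")
  n_frames <- duration_s * frame_rate_hz
  if (abs(n_frames - round(n_frames)) > 1e-9)
    stop_f("duration_s * frame_rate_hz = %g is not an integer frame count", n_frames)
  if (tgf_amp < 0 || myogenic_amp < 0 || noise_cv < 0)
    stop_f("amplitudes and noise_cv must be >= 0")
  if (myogenic_freq_hz < 0.1 || myogenic_freq_hz > 0.2)
    stop_f("myogenic_freq_hz %g outside [0.1, 0.2]", myogenic_freq_hz)
  fracs <- vapply(cluster_spec, function(cl) cl$frac, numeric(1))
  if (sum(fracs) > 1 + 1e-12)
    stop_f("cluster member fractions sum to %.3f > 1", sum(fracs))
  for (cl in cluster_spec) {
    if (any(cl$freq_hz < 0.015 | cl$freq_hz > 0.05))
      stop_f("cluster TGF frequency outside [0.015, 0.05] Hz")
  }
  if (!is.null(motion_schedule)) {
    motion_schedule <- as.matrix(motion_schedule)
    if (ncol(motion_schedule) != 2 || nrow(motion_schedule) != round(n_frames))
      stop_f("motion_schedule must be a %d x 2 matrix", round(n_frames))
    cfg$motion_schedule <- motion_schedule
  }
  cfg$n_frames <- as.integer(round(n_frames))
  class(cfg) <- "scene_config"
  cfg
}

# rasterize one capsule (segment dilated to radius r): logical H x W
rasterize_capsule <- function(H, W, cx, cy, theta, len, r) {
  ux <- cos(theta); uy <- sin(theta)
  hx <- ux * len / 2; hy <- uy * len / 2
  x0 <- max(1, floor(cx - abs(hx) - r - 1)); x1 <- min(W, ceiling(cx + abs(hx) + r + 1))
  y0 <- max(1, floor(cy - abs(hy) - r - 1)); y1 <- min(H, ceiling(cy + abs(hy) + r + 1))
  if (x0 > x1 || y0 > y1) return(NULL)
  xs <- x0:x1; ys <- y0:y1
  px <- matrix(rep(xs, each = length(ys)), nrow = length(ys))
  py <- matrix(rep(ys, length(xs)), nrow = length(ys))
  # distance from pixel centers to the axis segment
  vx <- px - cx; vy <- py - cy
  tproj <- pmin(pmax((vx * hx + vy * hy) / (hx^2 + hy^2 + 1e-300), -1), 1)
  d2 <- (vx - tproj * hx)^2 + (vy - tproj * hy)^2
  mask <- matrix(FALSE, H, W)
  sel <- d2 <= r^2
  if (!any(sel)) return(NULL)
  mask[cbind(py[sel], px[sel])] <- TRUE
  mask
}

#' Build a ground-truthed synthetic scene
#'
#' Places non-overlapping elongated vessels (random-orientation capsules)
#' in the field, assigns them to the configured frequency clusters, and
#' lays down per-vessel frequency and phase schedules at the flow sampling
#' rate. Cluster members share a (piecewise-constant) frequency schedule;
#' each member's phase is the running integral of 2*pi*f plus the cluster's
#' spatial term gradient . centroid, so a plane phase wave exists by
#' construction. Vessels outside any cluster have no TGF schedule.
#'
#' @param config a [scene_config()].
#' @return object of class `ground_truth`: list with `labels` (H x W
#'   integer mask), `centroids_px` / `centroids_mm` (n x 2, columns x, y),
#'   `cluster_labels` (0 = non-oscillating), `time_s`, `freq_schedule_hz`
#'   and `phase_truth_rad` (n x T matrices, NA for non-members),
#'   `bfi_truth` (noise-free per-vessel flow traces), and the config.
#' @export
make_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  with_seed(config$seed, {
    W <- config$field_size_px[1]; H <- config$field_size_px[2]
    n <- config$n_vessels
    labels <- matrix(0L, H, W)
    occupied <- matrix(FALSE, H, W)
    # keep the marker area free so vessels never hide under it
    if (!is.null(config$marker_spec))
      occupied <- occupied | (marker_coverage(config) > 0)
    centroids <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("x", "y")))
    # capsules may be clipped by the field edge; only keep centers inside
    margin <- max(config$vessel_diameter_px) / 2 + 1
    if (1 + margin >= W - margin || 1 + margin >= H - margin)
      stop_f(paste0("vessel placement infeasible: density %.2f vessels per ",
                    "1000 px^2 in a %d x %d field"), 1000 * n / (H * W), W, H)
    max_tries <- 300L
    for (v in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        cx <- stats::runif(1, 1 + margin, W - margin)
        cy <- stats::runif(1, 1 + margin, H - margin)
        theta <- stats::runif(1, 0, pi)
        len <- stats::runif(1, config$vessel_length_px[1], config$vessel_length_px[2])
        r <- stats::runif(1, config$vessel_diameter_px[1], config$vessel_diameter_px[2]) / 2
        m <- rasterize_capsule(H, W, cx, cy, theta, len, r)
        if (is.null(m)) next
        # 1-px dilation margin between vessels
        md <- m | rbind(m[-1, ], FALSE) | rbind(FALSE, m[-H, ]) |
          cbind(m[, -1], FALSE) | cbind(FALSE, m[, -W])
        if (any(occupied & md)) next
        labels[m] <- v
        occupied <- occupied | md
        idx <- which(m, arr.ind = TRUE)
        centroids[v, ] <- c(mean(idx[, 2]), mean(idx[, 1]))
        placed <- TRUE
        break
      }
      if (!placed)
        stop_f(paste0("vessel placement failed after %d tries at vessel %d/%d: ",
                      "density %.2f vessels per 1000 px^2 is infeasible"),
               max_tries, v, n, 1000 * n / (H * W))
    }
    centroids_mm <- centroids * config$pixel_size_mm

    # cluster assignment: random membership, sizes = floor(frac * n)
    sizes <- vapply(config$cluster_spec, function(cl) floor(cl$frac * n), numeric(1))
    order_v <- sample.int(n)
    cluster_labels <- integer(n)
    pos <- 0
    for (k in seq_along(sizes)) {
      if (sizes[k] > 0)
        cluster_labels[order_v[pos + seq_len(sizes[k])]] <- k
      pos <- pos + sizes[k]
    }

    fs_flow <- config$frame_rate_hz / config$contrast_stride
    Tf <- floor((config$n_frames - config$contrast_window) /
                  config$contrast_stride) + 1
    time_s <- (seq_len(Tf) - 1) / fs_flow
    dt <- 1 / fs_flow

    freq_schedule <- matrix(NA_real_, n, Tf)
    phase_truth <- matrix(NA_real_, n, Tf)
    for (k in seq_along(config$cluster_spec)) {
      cl <- config$cluster_spec[[k]]
      members <- which(cluster_labels == k)
      if (!length(members)) next
      n_ep <- length(cl$freq_hz)
      grad <- matrix(cl$gradient, ncol = 2)
      if (nrow(grad) == 1 && n_ep > 1) grad <- grad[rep(1, n_ep), , drop = FALSE]
      breaks <- c(-Inf, cl$epoch_breaks_s %||% numeric(0), Inf)
      if (length(breaks) != n_ep + 1)
        stop_f("cluster %d: %d epoch frequencies need %d interior breaks",
               k, n_ep, n_ep - 1)
      epoch <- findInterval(time_s, breaks)
      f_t <- cl$freq_hz[epoch]
      base_phase <- 2 * pi * cumsum(c(0, f_t[-Tf])) * dt
      theta0 <- stats::runif(1, -pi, pi)
      for (v in members) {
        freq_schedule[v, ] <- f_t
        sp <- grad[epoch, 1] * centroids_mm[v, 1] + grad[epoch, 2] * centroids_mm[v, 2]
        phase_truth[v, ] <- base_phase + theta0 + sp
      }
    }

    psi <- stats::runif(n, -pi, pi)  # myogenic phase, independent per vessel
    bfi_truth <- matrix(config$baseline_bfi, n, Tf)
    myo <- config$myogenic_amp *
      sin(outer(psi, 2 * pi * config$myogenic_freq_hz * time_s, FUN = "+"))
    for (v in seq_len(n)) {
      if (cluster_labels[v] > 0) {
        bfi_truth[v, ] <- config$baseline_bfi *
          (1 + config$tgf_amp * sin(phase_truth[v, ]) + myo[v, ])
      }
      # non-oscillating vessels: baseline only (noise is added at render time)
    }

    structure(list(labels = labels, centroids_px = centroids,
                   centroids_mm = centroids_mm,
                   cluster_labels = cluster_labels,
                   time_s = time_s, sample_rate_hz = fs_flow,
                   freq_schedule_hz = freq_schedule,
                   phase_truth_rad = phase_truth,
                   bfi_truth = bfi_truth, config = config),
              class = "ground_truth")
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "ground_truth: %d vessels in %d x %d px (%.2f x %.2f mm), %d clusters, %d flow samples at %g Hz\n",
    nrow(x$centroids_px), ncol(x$labels), nrow(x$labels),
    ncol(x$labels) * x$config$pixel_size_mm, nrow(x$labels) * x$config$pixel_size_mm,
    max(x$cluster_labels), length(x$time_s), x$sample_rate_hz))
  invisible(x)
}

#' Render a ground-truth scene as a blood-flow-index movie
#'
#' Pixel values of vessel `v` follow
#' `baseline * (1 + tgf_amp*sin(phase) + myogenic_amp*sin(...)) * (1 + eta)`
#' with `eta` the vessel-level multiplicative noise (sd `noise_cv`, i.i.d.
#' in time); background pixels are `background_bfi * (1 + eta_px)` with
#' i.i.d. pixel noise. Sampling rate is `frame_rate_hz / contrast_stride`
#' (2 Hz at the defaults), i.e. the rate the temporal-contrast stage would
#' deliver from a raw stack.
#'
#' @param truth a `ground_truth` from [make_scene()].
#' @param config the matching [scene_config()]; defaults to the one stored
#'   in `truth`.
#' @return object of class `bfi_movie`: list with `bfi` (H x W x T array),
#'   `sample_rate_hz`, `window_len`, `stride`, `bfi_cap` (NA: rendered, not
#'   floored), `pixel_size_mm`, `time_s`.
#' @export
render_bfi_movie <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "scene_config"))
  if (config$tgf_amp < 0 || config$myogenic_amp < 0)
    stop_f("amplitudes must be >= 0")
  with_seed(config$seed + 1L, {
    H <- nrow(truth$labels); W <- ncol(truth$labels)
    Tf <- length(truth$time_s)
    bfi <- array(config$background_bfi *
                   pmax(1 + config$noise_cv * stats::rnorm(H * W * Tf), 1e-6),
                 dim = c(H, W, Tf))
    frame_off <- (seq_len(Tf) - 1) * H * W
    for (v in seq_len(nrow(truth$centroids_px))) {
      pix <- which(truth$labels == v)
      trace <- truth$bfi_truth[v, ] *
        pmax(1 + config$noise_cv * stats::rnorm(Tf), 1e-6)
      bfi[rep(pix, Tf) + rep(frame_off, each = length(pix))] <-
        rep(trace, each = length(pix))
    }
    structure(list(bfi = bfi, sample_rate_hz = truth$sample_rate_hz,
                   window_len = config$contrast_window,
                   stride = config$contrast_stride, bfi_cap = NA_real_,
                   pixel_size_mm = config$pixel_size_mm,
                   time_s = truth$time_s),
              class = "bfi_movie")
  })
}

#' @export
print.bfi_movie <- function(x, ...) {
  d <- dim(x$bfi)
  cat(sprintf("bfi_movie: %d x %d px, %d samples at %g Hz\n",
              d[2], d[1], d[3], x$sample_rate_hz))
  invisible(x)
}

#' Sub-pixel coverage map of the U-shaped fiducial marker
#'
#' The marker (a metal thread bent into a 'U' resting on the cover glass)
#' is drawn from its continuous geometry: per-pixel coverage in \[0, 1\] with
#' a 1-px anti-aliasing ramp, so fractional `shift`s move its centroid by
#' exactly the shift. Used by the renderer and as the truth mask in
#' registration tests.
#'
#' @param config a [scene_config()] with non-NULL `marker_spec`.
#' @param shift c(dx, dy) translation in px (may be fractional).
#' @return H x W coverage matrix.
#' @export
marker_coverage <- function(config, shift = c(0, 0)) {
  ms <- config$marker_spec
  if (is.null(ms)) stop_f("config has no marker_spec")
  W <- config$field_size_px[1]; H <- config$field_size_px[2]
  cx <- ms$center_px[1] + shift[1]; cy <- ms$center_px[2] + shift[2]
  w <- ms$width_px; h <- ms$height_px; r <- ms$thickness_px / 2
  segs <- rbind(  # U: two legs opening upward + bottom bar (x1,y1,x2,y2)
    c(cx - w / 2, cy - h / 2, cx - w / 2, cy + h / 2),
    c(cx + w / 2, cy - h / 2, cx + w / 2, cy + h / 2),
    c(cx - w / 2, cy + h / 2, cx + w / 2, cy + h / 2))
  px <- matrix(rep(seq_len(W), each = H), nrow = H)
  py <- matrix(rep(seq_len(H), W), nrow = H)
  d <- matrix(Inf, H, W)
  for (i in seq_len(nrow(segs))) {
    sx <- segs[i, 3] - segs[i, 1]; sy <- segs[i, 4] - segs[i, 2]
    vx <- px - segs[i, 1]; vy <- py - segs[i, 2]
    tt <- pmin(pmax((vx * sx + vy * sy) / (sx^2 + sy^2), 0), 1)
    d <- pmin(d, sqrt((vx - tt * sx)^2 + (vy - tt * sy)^2))
  }
  pmin(pmax(r + 0.5 - d, 0), 1)
}

#' Default U-marker specification
#'
#' @param config a [scene_config()]; geometry scales with the field.
#' @param intensity_frac marker intensity relative to tissue (default 0.15:
#'   dark metal thread).
#' @return marker_spec list for [scene_config()].
#' @export
default_marker_spec <- function(config = NULL, field_size_px = c(64, 64),
                                intensity_frac = 0.15) {
  if (!is.null(config)) field_size_px <- config$field_size_px
  W <- field_size_px[1]; H <- field_size_px[2]
  list(center_px = c(W * 0.25, H * 0.25),
       width_px = W * 0.18, height_px = H * 0.18,
       thickness_px = max(4, round(W * 0.06)),
       intensity_frac = intensity_frac, contrast_k = 0.05)
}

#' Render a ground-truth scene as a raw speckle-like frame stack
#'
#' Draws, for each pixel and 25-frame contrast window, i.i.d. gamma
#' intensities with mean mu and standard deviation K*mu, where
#' K = 1/sqrt(BFI_target) is the temporal speckle contrast implied by the
#' scene's flow truth: running the temporal-contrast stage on the stack
#' recovers K (up to the 25-sample estimator noise). The gamma family gives
#' strictly positive intensities with two-parameter control of mean and CV.
#' The dark U marker is stamped with sub-pixel coverage and near-static
#' contrast; `motion_schedule` translations are applied per frame (tissue
#' shifted by the rounded offset, the marker at its exact continuous
#' position).
#'
#' @param truth a `ground_truth` from [make_scene()].
#' @param config the matching [scene_config()]; must carry a `marker_spec`
#'   if marker-based registration is to be exercised.
#' @return object of class `frame_stack`: list with `frames` (H x W x T
#'   array of intensities), `frame_rate_hz`, `pixel_size_mm`.
#' @export
render_speckle_stack <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "scene_config"))
  with_seed(config$seed + 2L, {
    H <- nrow(truth$labels); W <- ncol(truth$labels)
    n_frames <- config$n_frames
    win <- config$contrast_window
    n_win <- n_frames %/% win
    mu0 <- config$mean_intensity

    # per-window BFI target maps: background + per-vessel noisy traces
    Tf <- length(truth$time_s)
    vtr <- truth$bfi_truth * pmax(1 + config$noise_cv *
                                    matrix(stats::rnorm(length(truth$bfi_truth)),
                                           nrow = nrow(truth$bfi_truth),
                                           ncol = ncol(truth$bfi_truth)), 1e-6)
    frames <- array(NA_real_, dim = c(H, W, n_frames))
    base_bfi <- matrix(config$background_bfi, H, W)
    for (w in seq_len(n_win)) {
      bfi_map <- base_bfi
      tw <- min(w, Tf)
      for (v in seq_len(nrow(truth$centroids_px)))
        bfi_map[truth$labels == v] <- vtr[v, tw]
      k_map <- 1 / sqrt(bfi_map)
      for (fidx in ((w - 1) * win + 1):(w * win)) {
        sh <- if (is.null(config$motion_schedule)) c(0, 0)
              else config$motion_schedule[fidx, ]
        k_f <- shift_matrix(k_map, round(sh[1]), round(sh[2]))
        mu_f <- matrix(mu0, H, W)
        if (!is.null(config$marker_spec)) {
          cov <- marker_coverage(config, shift = sh)
          ms <- config$marker_spec
          mu_f <- mu0 * (1 - cov * (1 - ms$intensity_frac))
          k_f <- k_f * (1 - cov) + ms$contrast_k * cov
        }
        shape <- 1 / k_f^2
        frames[, , fidx] <- stats::rgamma(H * W, shape = shape,
                                          scale = mu_f / shape)
      }
    }
    structure(list(frames = frames, frame_rate_hz = config$frame_rate_hz,
                   pixel_size_mm = config$pixel_size_mm),
              class = "frame_stack")
  })
}

# integer-shift a matrix by (dx, dy) pixels with edge replication
shift_matrix <- function(m, dx, dy) {
  H <- nrow(m); W <- ncol(m)
  rows <- pmin(pmax(seq_len(H) - dy, 1), H)
  cols <- pmin(pmax(seq_len(W) - dx, 1), W)
  m[rows, cols, drop = FALSE]
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("frame_stack: %d x %d px, %d frames at %g fps (%.3g um/px)\n",
              d[2], d[1], d[3], x$frame_rate_hz, 1000 * x$pixel_size_mm))
  invisible(x)
}
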