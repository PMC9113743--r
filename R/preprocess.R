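# Registration and contrast analysis of raw speckle frame stacks.
#
# Raw renal LSCI frames carry lateral motion (breathing, pulse) that must
# be removed before temporal contrast is meaningful. Speckle frames have
# no stable intensity landmarks, so registration keys on the dark U-shaped
# fiducial marker resting on the cover glass: segment it in every frame by
# thresholding, take its centroid track as the translation estimate, and
# shift frames back. Windowed temporal contrast K = sd/mean over 25-frame
# windows then yields the blood flow index BFI = 1/K^2.

#' Construct a frame stack
#'
#' @param frames H x W x T array of non-negative finite intensities.
#' @param frame_rate_hz frame rate in Hz.
#' @param pixel_size_mm pixel pitch in mm.
#' @return object of class `frame_stack`.
#' @export
frame_stack <- function(frames, frame_rate_hz, pixel_size_mm) {
  frames <- as.array(frames)
  if (length(dim(frames)) != 3) stop_f("frames must be an H x W x T array")
  if (anyNA(frames) || any(frames < 0) || !all(is.finite(frames)))
    stop_f("intensities must be finite and >= 0")
  structure(list(frames = frames, frame_rate_hz = frame_rate_hz,
                 pixel_size_mm = pixel_size_mm),
            class = "frame_stack")
}

#' Segment the fiducial marker in every frame
#'
#' The marker is darker than perfused tissue, so per frame the marker mask
#' is the largest connected component of below-threshold pixels. A frame
#' with no below-threshold pixels is an error (the marker must be visible
#' throughout for registration).
#'
#' @param stack a `frame_stack`.
#' @param marker_threshold intensity threshold; pixels strictly below it
#'   are marker candidates.
#' @param smooth_px odd side of a box mean filter applied to each frame
#'   before thresholding (default 3); raw speckle frames flicker pixel by
#'   pixel, and without smoothing the marker's partially covered edge
#'   pixels cross the threshold at random, jittering the centroid.
#'   Set to 1 to disable.
#' @return object of class `marker_masks`: list with `masks` (H x W x T
#'   logical array) and `centroids` (T x 2 matrix, columns x, y).
#' @export
segment_marker <- function(stack, marker_threshold, smooth_px = 3) {
  stopifnot(inherits(stack, "frame_stack"))
  if (smooth_px < 1 || smooth_px %% 2 == 0)
    stop_f("smooth_px must be odd and >= 1")
  d <- dim(stack$frames)
  kern <- matrix(1 / smooth_px^2, smooth_px, smooth_px)
  masks <- array(FALSE, d)
  centroids <- matrix(NA_real_, d[3], 2, dimnames = list(NULL, c("x", "y")))
  empty <- integer(0)
  for (t in seq_len(d[3])) {
    fr <- stack$frames[, , t]
    if (smooth_px > 1) fr <- EBImage::filter2(fr, kern, boundary = "replicate")
    below <- fr < marker_threshold
    if (!any(below)) { empty <- c(empty, t); next }
    lab <- EBImage::bwlabel(below)
    sizes <- tabulate(lab[lab > 0])
    comp <- which.max(sizes)
    m <- lab == comp
    masks[, , t] <- m
    # darkness-weighted centroid: continuous in sub-pixel marker motion,
    # unlike the centroid of the binary mask
    w <- (marker_threshold - fr) * m
    idx <- which(m, arr.ind = TRUE)
    wv <- w[m]
    centroids[t, ] <- c(sum(wv * idx[, 2]), sum(wv * idx[, 1])) / sum(wv)
  }
  if (length(empty))
    stop_f("no pixels below marker threshold %g in frame(s) %s",
           marker_threshold, paste(utils::head(empty, 10), collapse = ", "))
  structure(list(masks = masks, centroids = centroids),
            class = "marker_masks")
}

#' Estimate per-frame translation from marker masks
#'
#' The offset of each frame is the displacement of the marker centroid
#' relative to the reference (first) frame, reported at subpixel precision.
#'
#' @param masks a `marker_masks` from [segment_marker()].
#' @return object of class `translation_track`: T x 2 matrix of (dx, dy)
#'   offsets in pixels; first row is (0, 0).
#' @export
estimate_translation <- function(masks) {
  stopifnot(inherits(masks, "marker_masks"))
  track <- sweep(masks$centroids, 2, masks$centroids[1, ])
  colnames(track) <- c("dx", "dy")
  structure(track, class = c("translation_track", "matrix"))
}

#' Apply a translation track to register a stack
#'
#' Each frame is shifted by minus its offset (rounded to whole pixels by
#' default: interpolation blurs speckle statistics, and the temporal
#' contrast that follows is computed per pixel). Out-of-field pixels are
#' filled with the edge value and flagged in a validity mask.
#'
#' @param stack a `frame_stack`.
#' @param track a `translation_track` covering all frames.
#' @param max_shift_frac error if any offset exceeds this fraction of the
#'   field size (default 0.5): such motion means registration is
#'   implausible.
#' @return registered `frame_stack` with attribute `valid_mask` (H x W
#'   logical: pixels observed in every frame).
#' @export
apply_registration <- function(stack, track, max_shift_frac = 0.5) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$frames)
  if (nrow(track) != d[3])
    stop_f("translation track has %d rows but stack has %d frames",
           nrow(track), d[3])
  if (any(abs(track[, 1]) > max_shift_frac * d[2]) ||
      any(abs(track[, 2]) > max_shift_frac * d[1]))
    stop_f("offsets exceed %g of the field: registration implausible",
           max_shift_frac)
  out <- stack$frames
  valid <- matrix(TRUE, d[1], d[2])
  for (t in seq_len(d[3])) {
    dx <- round(track[t, 1]); dy <- round(track[t, 2])
    if (dx == 0 && dy == 0) next
    out[, , t] <- shift_matrix(stack$frames[, , t], -dx, -dy)
    vm <- matrix(FALSE, d[1], d[2])
    rows <- seq_len(d[1]) + dy; cols <- seq_len(d[2]) + dx
    vm[rows >= 1 & rows <= d[1], cols >= 1 & cols <= d[2]] <- TRUE
    valid <- valid & vm
  }
  res <- frame_stack(out, stack$frame_rate_hz, stack$pixel_size_mm)
  attr(res, "valid_mask") <- valid
  res
}

#' Windowed temporal speckle contrast
#'
#' Per pixel and per window of `window_len` frames, K = sample standard
#' deviation / mean of intensity (the n-1 sample SD). Non-overlapping
#' 25-frame windows by default: at 50 fps this delivers contrast (and then
#' flow) at 2 Hz.
#'
#' @param stack a `frame_stack` with at least `window_len` frames.
#' @param window_len frames per window (default 25).
#' @param stride window stride in frames (default `window_len`:
#'   non-overlapping).
#' @return object of class `contrast_movie`: list with `k` (H x W x T'
#'   array, T' = floor((T - window_len)/stride) + 1), `sample_rate_hz`,
#'   `window_len`, `stride`, `pixel_size_mm`.
#' @examples
#' # 5 frames at 200 and 20 at 100: mean 120, sample SD 40.82, K = 0.3402
#' st <- frame_stack(array(rep(c(200, 100), c(5, 20)), c(1, 1, 25)), 50, 0.0015)
#' temporal_contrast(st)$k[1, 1, 1]
#' @export
temporal_contrast <- function(stack, window_len = 25, stride = window_len) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$frames)
  if (d[3] < window_len)
    stop_f("stack has %d frames; window needs %d", d[3], window_len)
  n_win <- floor((d[3] - window_len) / stride) + 1
  k <- array(NA_real_, c(d[1], d[2], n_win))
  for (w in seq_len(n_win)) {
    slab <- stack$frames[, , (w - 1) * stride + seq_len(window_len), drop = FALSE]
    m <- rowMeans(slab, dims = 2)
    if (any(m <= 0)) {
      bad <- which(m <= 0, arr.ind = TRUE)[1, ]
      stop_f("zero-mean window: pixel (row %d, col %d), window %d",
             bad[1], bad[2], w)
    }
    s2 <- rowSums((slab - as.vector(m))^2, dims = 2) / (window_len - 1)
    k[, , w] <- sqrt(s2) / m
  }
  structure(list(k = k, sample_rate_hz = stack$frame_rate_hz / stride,
                 window_len = window_len, stride = stride,
                 pixel_size_mm = stack$pixel_size_mm),
            class = "contrast_movie")
}

#' Convert temporal contrast to a blood flow index movie
#'
#' BFI = 1/K^2, with K floored at `k_floor` so static pixels (K near 0) do
#' not blow up: the representable ceiling is `bfi_cap = 1/k_floor^2`.
#' BFI is a relative flow index, not an absolute velocity.
#'
#' @param contrast a `contrast_movie` from [temporal_contrast()].
#' @param k_floor minimum contrast used in the division (default 0.01,
#'   i.e. bfi_cap = 1e4).
#' @return object of class `bfi_movie` (see [render_bfi_movie()] for the
#'   fields), with `bfi_cap` set.
#' @examples
#' # K = 0.5 -> BFI = 4; K = 0 -> floored to bfi_cap
#' @export
contrast_to_bfi <- function(contrast, k_floor = 0.01) {
  stopifnot(inherits(contrast, "contrast_movie"))
  if (k_floor <= 0) stop_f("k_floor must be > 0")
  structure(list(bfi = 1 / pmax(contrast$k, k_floor)^2,
                 sample_rate_hz = contrast$sample_rate_hz,
                 window_len = contrast$window_len, stride = contrast$stride,
                 bfi_cap = 1 / k_floor^2,
                 pixel_size_mm = contrast$pixel_size_mm,
                 time_s = (seq_len(dim(contrast$k)[3]) - 1) / contrast$sample_rate_hz),
            class = "bfi_movie")
}
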