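#' Fixed TGF-band frequency grid
#'
#' The dominant-frequency analysis works on a fixed, logarithmically spaced
#' grid of analysis frequencies spanning the tubuloglomerular feedback (TGF)
#' band. Two vessels are considered frequency-matched when their dominant
#' bins on this grid coincide, so the grid is part of the method definition,
#' not a tuning knob: 18 bins from 0.015 to 0.05 Hz by default.
#'
#' @param n_bins number of grid frequencies (default 18).
#' @param f_min,f_max band edges in Hz (defaults 0.015 and 0.05).
#' @return object of class `tgf_grid`: list with `centers_hz` (increasing,
#'   first and last exactly at the band edges) and `n_bins`.
#' @examples
#' g <- tgf_grid()
#' length(g$centers_hz)  # 18
#' @export
tgf_grid <- function(n_bins = 18, f_min = 0.015, f_max = 0.05) {
  if (n_bins < 2 || f_min <= 0 || f_max <= f_min)
    stop_f("invalid grid: n_bins=%d, band [%g, %g]", n_bins, f_min, f_max)
  centers <- exp(seq(log(f_min), log(f_max), length.out = n_bins))
  centers[1] <- f_min
  centers[n_bins] <- f_max
  structure(list(centers_hz = centers, n_bins = n_bins,
                 f_min = f_min, f_max = f_max),
            class = "tgf_grid")
}

#' @export
print.tgf_grid <- function(x, ...) {
  cat(sprintf("TGF frequency grid: %d log-spaced bins, %.4g-%.4g Hz\n",
              x$n_bins, x$f_min, x$f_max))
  invisible(x)
}

#' Continuous wavelet transform of a flow trace over the TGF grid
#'
#' Computes complex generalized-Morse wavelet coefficients of a relative
#' blood flow (rbf) trace at every grid frequency and every time sample.
#' The wavelet is amplitude-normalized: a unit-amplitude sinusoid at a grid
#' frequency yields ridge magnitude ~1 at any bin, so the across-bin argmax
#' is unbiased by scale. Samples closer to a record edge than the wavelet's
#' e-folding half-width at a given frequency are flagged as outside the
#' cone of influence and are not trusted downstream.
#'
#' @param x numeric trace (typically rbf, i.e. mean-normalized flow).
#' @param fs sampling rate in Hz; must be at least 4x the highest grid
#'   frequency.
#' @param grid a [tgf_grid()].
#' @param beta,gamma Morse shape parameters. Defaults beta = 20, gamma = 3
#'   (time-bandwidth P^2 = 60, the default of the major wavelet toolboxes):
#'   enough frequency concentration to hold a stable dominant bin on the
#'   18-bin grid under realistic trace noise.
#' @param detrend remove a linear trend before transforming (default FALSE;
#'   traces are already mean-normalized).
#' @return object of class `tgf_tfr`: list with `mag` and `phase`
#'   (n_bins x T matrices), `incone` (logical n_bins x T), `freqs_hz`, `fs`,
#'   `noise_sd_w` (expected per-bin coefficient sd under the trace's
#'   estimated white-noise floor), and the shape parameters.
#' @seealso [dominant_track()]
#' @export
cwt_tgf <- function(x, fs, grid = tgf_grid(), beta = 20, gamma = 3,
                    detrend = FALSE) {
  stopifnot(inherits(grid, "tgf_grid"))
  if (anyNA(x) || !all(is.finite(x))) stop_f("trace contains NA/non-finite values")
  min_len <- ceiling(3 / grid$f_min * fs)
  if (length(x) < min_len)
    stop_f("trace too short: %d samples; need >= %d (3 periods of %.4g Hz at %g Hz)",
           length(x), min_len, grid$f_min, fs)
  if (fs < 4 * grid$f_max)
    stop_f("sampling rate %g Hz < 4x highest grid frequency %g Hz", fs, grid$f_max)
  if (detrend) {
    t0 <- seq_along(x)
    x <- x - stats::fitted(stats::lm(x ~ t0))
  }
  # white-noise floor of the trace, from first differences (slow TGF and
  # myogenic components contribute little power to lag-1 differences)
  sigma <- sqrt(stats::var(diff(x)) / 2)
  cw <- morse_cwt(x, fs, grid$centers_hz, beta = beta, gamma = gamma)
  structure(list(mag = Mod(cw$coef), phase = Arg(cw$coef),
                 incone = cw$incone, freqs_hz = grid$centers_hz, fs = fs,
                 noise_sd_w = sigma * morse_noise_gain(grid$centers_hz, fs,
                                                       beta, gamma),
                 beta = beta, gamma = gamma),
            class = "tgf_tfr")
}

# normalized topographic prominence of the argmax of profile m, band ends
# treated as walls: base = the higher of the two side minima (one-sided at
# the band edges). Returns prominence / peak height in [0, 1].
peak_prominence_norm <- function(m) {
  i <- which.max(m)  # ties: lowest bin index
  h <- m[i]
  if (h <= 0) return(0)
  K <- length(m)
  l <- if (i > 1) min(m[1:i]) else NA_real_
  r <- if (i < K) min(m[i:K]) else NA_real_
  base <- max(l, r, na.rm = TRUE)
  (h - base) / h
}

#' Track the dominant TGF-band frequency and phase
#'
#' Per time sample, the dominant bin is the across-bin argmax of wavelet
#' magnitude (ties broken toward the lower bin), the phase is the argument
#' of the coefficient there, and the sample is `valid` when all of:
#' the sample is inside the cone of influence at the dominant bin's
#' frequency; the normalized topographic prominence of the magnitude peak
#' across the grid is at least `prominence_min`; and the peak magnitude
#' exceeds `snr_min` times the expected white-noise coefficient magnitude
#' at that bin (noise floor estimated from the trace's first differences).
#' The noise floor makes the activity criterion scale-free: a trace with no
#' TGF oscillation fails it most of the time regardless of its noise level,
#' mirroring the discarding of vessels without pronounced TGF activity.
#'
#' @param tfr a `tgf_tfr` from [cwt_tgf()].
#' @param prominence_min minimum normalized prominence (default 0.10).
#' @param snr_min minimum ratio of dominant magnitude to the expected
#'   noise-floor magnitude at that bin (default 2; set to 0 to disable).
#' @return object of class `dominant_track`: list of per-sample vectors
#'   `bin`, `freq_hz`, `phase_rad`, `prominence`, `snr`, `valid`, plus
#'   `fs` and `time_s`.
#' @export
dominant_track <- function(tfr, prominence_min = 0.10, snr_min = 2) {
  stopifnot(inherits(tfr, "tgf_tfr"))
  m <- tfr$mag
  T0 <- ncol(m)
  bin <- max.col(t(m), ties.method = "first")
  idx <- cbind(bin, seq_len(T0))
  h <- m[idx]
  prom <- apply(m, 2, peak_prominence_norm)
  snr <- if (all(tfr$noise_sd_w > 0)) h / tfr$noise_sd_w[bin] else rep(Inf, T0)
  valid <- tfr$incone[idx] & prom >= prominence_min & snr >= snr_min & h > 0
  structure(list(bin = bin, freq_hz = tfr$freqs_hz[bin],
                 phase_rad = ifelse(valid, tfr$phase[idx], NA_real_),
                 prominence = prom, snr = snr, valid = valid,
                 fs = tfr$fs, time_s = (seq_len(T0) - 1) / tfr$fs,
                 freqs_hz = tfr$freqs_hz),
            class = "dominant_track")
}

#' @export
print.dominant_track <- function(x, ...) {
  cat(sprintf("dominant_track: %d samples at %g Hz, %.1f%% valid\n",
              length(x$bin), x$fs, 100 * mean(x$valid)))
  invisible(x)
}

#' Dominant-frequency tracks for a set of vessel traces
#'
#' Applies [cwt_tgf()] + [dominant_track()] to each row of a trace matrix
#' and collects the results as vessel x time matrices, the layout consumed
#' by the synchronization statistics.
#'
#' @param traces a `vessel_traces` object (see [extract_traces()]) or a
#'   numeric matrix of rbf traces (vessels in rows).
#' @param fs sampling rate in Hz; taken from `traces` when available.
#' @param grid a [tgf_grid()].
#' @param ... passed to [cwt_tgf()] and [dominant_track()]
#'   (`beta`, `gamma`, `detrend`, `prominence_min`, `snr_min`).
#' @return object of class `track_set`: list with matrices `bin`, `freq_hz`,
#'   `phase_rad`, `prominence`, `valid` (n_vessels x T), `fs`, `time_s`,
#'   `freqs_hz`.
#' @export
dominant_tracks <- function(traces, fs = NULL, grid = tgf_grid(), ...) {
  dots <- list(...)
  cwt_args <- dots[names(dots) %in% c("beta", "gamma", "detrend")]
  trk_args <- dots[names(dots) %in% c("prominence_min", "snr_min")]
  if (inherits(traces, "vessel_traces")) {
    fs <- fs %||% traces$sample_rate_hz
    mat <- traces$rbf
  } else mat <- as.matrix(traces)
  if (is.null(fs)) stop_f("sampling rate required")
  n <- nrow(mat)
  T0 <- ncol(mat)
  out <- list(bin = matrix(NA_integer_, n, T0), freq_hz = matrix(NA_real_, n, T0),
              phase_rad = matrix(NA_real_, n, T0),
              prominence = matrix(NA_real_, n, T0),
              valid = matrix(FALSE, n, T0))
  for (v in seq_len(n)) {
    tfr <- do.call(cwt_tgf, c(list(x = mat[v, ], fs = fs, grid = grid), cwt_args))
    tr <- do.call(dominant_track, c(list(tfr = tfr), trk_args))
    out$bin[v, ] <- tr$bin
    out$freq_hz[v, ] <- tr$freq_hz
    out$phase_rad[v, ] <- tr$phase_rad
    out$prominence[v, ] <- tr$prominence
    out$valid[v, ] <- tr$valid
  }
  out$fs <- fs
  out$time_s <- (seq_len(T0) - 1) / fs
  out$freqs_hz <- grid$centers_hz
  class(out) <- "track_set"
  out
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("track_set: %d vessels x %d samples at %g Hz, %.1f%% valid\n",
              nrow(x$bin), ncol(x$bin), x$fs, 100 * mean(x$valid)))
  invisible(x)
}

#' Phase difference between two tracked vessels at one sample
#'
#' Defined only where both tracks are valid and sit in the same dominant
#' frequency bin (a phase difference across different frequencies is
#' meaningless). The result is wrapped into (-pi, pi].
#'
#' @param track_a,track_b `dominant_track` objects on a common time base.
#' @param t sample index.
#' @return wrapped phase difference `phase_a - phase_b` in radians.
#' @examples
#' # wrap arithmetic: 3.0 - (-3.0) = 6.0 -> 6.0 - 2*pi
#' wrap_phase(3.0 - (-3.0))
#' @export
phase_difference <- function(track_a, track_b, t) {
  stopifnot(inherits(track_a, "dominant_track"), inherits(track_b, "dominant_track"))
  if (!track_a$valid[t] || !track_b$valid[t])
    stop_f("phase difference undefined at t=%d: track not valid", t)
  if (track_a$bin[t] != track_b$bin[t])
    stop_f("phase difference undefined at t=%d: dominant bins differ (%d vs %d)",
           t, track_a$bin[t], track_b$bin[t])
  wrap_phase(track_a$phase_rad[t] - track_b$phase_rad[t])
}
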