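# Shared fixtures, all built in code.

`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal track_set from bin/valid matrices (vessels x time)
make_track_set <- function(bin, valid = NULL, fs = 2, phase = NULL,
                           grid = tgf_grid()) {
  bin <- rbind(bin)
  storage.mode(bin) <- "integer"
  if (is.null(valid)) valid <- matrix(TRUE, nrow(bin), ncol(bin))
  structure(list(bin = bin, freq_hz = matrix(grid$centers_hz[bin], nrow(bin)),
                 phase_rad = phase %||% matrix(0, nrow(bin), ncol(bin)),
                 prominence = matrix(1, nrow(bin), ncol(bin)),
                 valid = valid, fs = fs,
                 time_s = (seq_len(ncol(bin)) - 1) / fs,
                 freqs_hz = grid$centers_hz),
            class = "track_set")
}

# brute-force synchronization degree: ordered-pair double loop
brute_force_S <- function(bins, N = length(bins)) {
  n <- length(bins)
  L <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && bins[i] == bins[j]) L <- L + 1
  }
  L / (N * (N - 1))
}

# frequency of the periodogram peak (DC excluded)
periodogram_peak_hz <- function(x, fs) {
  n <- length(x)
  p <- Mod(stats::fft(x - mean(x)))[2:floor(n / 2)]
  (which.max(p)) * fs / n
}

# full default study scene (30 vessels, two clusters, 1200 s), analyzed in
# parameter-recovery mode; memoised because several checks share it
acceptance_bundle <- function() {
  if (is.null(.fixture_env$acc)) {
    cfg <- scene_config(seed = 1L)
    .fixture_env$acc <- run_all(cfg, use_truth_masks = TRUE)
  }
  .fixture_env$acc
}

# small two-cluster BFI scene used across test files (memoised)
.fixture_env <- new.env()
small_scene_bundle <- function() {
  if (is.null(.fixture_env$small)) {
    cfg <- scene_config(field_size_px = c(96, 96), pixel_size_mm = 1.5 / 96,
                        duration_s = 600, n_vessels = 14,
                        cluster_spec = list(
                          list(frac = 0.5, freq_hz = 0.022, gradient = c(0.71, 0)),
                          list(frac = 0.5, freq_hz = 0.035, gradient = c(0, 1.59))),
                        seed = 11L)
    truth <- make_scene(cfg)
    movie <- render_bfi_movie(truth)
    .fixture_env$small <- list(cfg = cfg, truth = truth, movie = movie)
  }
  .fixture_env$small
}
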