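# Generalized Morse wavelet CWT on a fixed frequency grid.
#
# The analysis needs, for every sample of a slow flow trace, the complex
# wavelet coefficient at a small set of fixed TGF-band frequencies. The
# transform is computed per frequency as a frequency-domain filter: the
# wavelet of the (beta, gamma) Morse family, scaled so its peak response
# sits at the requested frequency, multiplied onto the FFT of the
# (reflection-padded, demeaned) trace. The filter value at its peak is 2,
# so a unit-amplitude real sinusoid at a grid frequency returns ridge
# magnitude 1 at every bin (amplitude / L1-style normalization): the
# dominant-bin argmax is not biased by scale.

# peak (angular, per-sample) frequency of the Morse wavelet
morse_peak_omega <- function(beta, gamma) (beta / gamma)^(1 / gamma)

# filter values of the analytic Morse wavelet at angular frequencies `om`,
# for the scale that maps the wavelet peak onto angular frequency `om0`
morse_filter <- function(om, om0, beta, gamma) {
  wp <- morse_peak_omega(beta, gamma)
  s <- wp / om0
  so <- s * om
  out <- numeric(length(om))
  pos <- so > 0
  # log form avoids overflow of so^beta for large beta
  out[pos] <- 2 * exp(beta * log(so[pos]) - so[pos]^gamma -
                        (beta * log(wp) - wp^gamma))
  out
}

# sd of the wavelet coefficient for unit-variance white noise at sampling
# rate fs, per analysis frequency: sqrt(mean(|Psi|^2)) over the DFT bins.
# Converges quickly in n; n = 8192 is ample for TGF-band filters.
morse_noise_gain <- function(freqs_hz, fs, beta, gamma, n = 8192) {
  om <- 2 * pi * (seq_len(n) - 1) / n
  om[om > pi] <- 0
  vapply(freqs_hz, function(f) {
    sqrt(mean(morse_filter(om, 2 * pi * f / fs, beta, gamma)^2))
  }, numeric(1))
}

# e-folding half-width of the wavelet's time envelope, in units of
# oscillation periods at the analysis frequency. Computed numerically from
# an inverse FFT of the filter; memoised per (beta, gamma).
.morse_coi_cache <- new.env(parent = emptyenv())
morse_coi_periods <- function(beta, gamma) {
  key <- paste(beta, gamma, sep = "_")
  if (!is.null(.morse_coi_cache[[key]])) return(.morse_coi_cache[[key]])
  n <- 2^14
  cyc <- 64  # periods of the analysis frequency across the array
  om0 <- 2 * pi * cyc / n
  om <- 2 * pi * (seq_len(n) - 1) / n
  om[om > pi] <- 0
  psi <- Mod(stats::fft(morse_filter(om, om0, beta, gamma), inverse = TRUE)) / n
  pk <- which.max(psi)  # envelope peak is at t = 0 (index 1), symmetric wrap
  half <- which(psi[pk:(n / 2)] < psi[pk] / exp(1))[1] - 1
  out <- half * om0 / (2 * pi)  # samples -> periods of the analysis frequency
  .morse_coi_cache[[key]] <- out
  out
}

# Core transform: real trace x at rate fs, analysis frequencies freqs_hz.
# Returns complex coefficient matrix (length(freqs) x length(x)) plus the
# in-cone flags. Reflection padding suppresses circular wrap-around; the
# cone of influence marks samples closer to either record edge than the
# wavelet's e-folding half-width at that frequency.
morse_cwt <- function(x, fs, freqs_hz, beta = 20, gamma = 3) {
  T0 <- length(x)
  x <- x - mean(x)
  pad <- ceiling(T0 / 2)
  xp <- c(rev(x[seq_len(pad)]), x, rev(x[T0 - seq_len(pad) + 1]))
  n <- stats::nextn(length(xp), 2)
  xp <- c(xp, numeric(n - length(xp)))
  X <- stats::fft(xp)
  om <- 2 * pi * (seq_len(n) - 1) / n
  om[om > pi] <- 0  # analytic wavelet: no response at negative frequencies
  W <- matrix(0i, length(freqs_hz), T0)
  for (k in seq_along(freqs_hz)) {
    Psi <- morse_filter(om, 2 * pi * freqs_hz[k] / fs, beta, gamma)
    wk <- stats::fft(X * Psi, inverse = TRUE) / n
    W[k, ] <- wk[pad + seq_len(T0)]
  }
  coi_p <- morse_coi_periods(beta, gamma)
  edge_s <- pmin(seq_len(T0) - 1, T0 - seq_len(T0)) / fs
  incone <- outer(coi_p / freqs_hz, edge_s, FUN = "<=")
  list(coef = W, incone = incone)
}
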