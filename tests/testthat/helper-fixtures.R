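# Shared fixtures, built in code.

FS <- 16000

make_tone <- function(f, L = 16384, fs = FS, amp = 1) {
  gen_harmonic(harmonic_params(K = 1, amplitudes = amp, f0 = f,
                               duration = L / fs), fs)
}

make_white <- function(L = 16384, fs = FS, seed = 1) {
  band_noise(c(0, fs / 2), L, fs, seed = seed)
}

# Wrap a raw non-negative matrix as a TFD for distribution-level tests.
make_tfd <- function(values, kind = "spectrogram", fs = FS) {
  tfdinfo:::new_tfd_matrix(values, seq_len(nrow(values)),
                           seq_len(ncol(values)), kind, fs,
                           window_spec("hann", 8, 2))
}

# Random distribution on n cells (used by property tests).
rand_dist <- function(n) {
  w <- stats::runif(n)
  w / sum(w)
}

# Instantaneous-frequency oracle: phase derivative of the analytic signal
# (FFT-mask Hilbert transform), in Hz.
analytic_if <- function(x, fs) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  z <- stats::fft(X * h, inverse = TRUE) / n
  ph <- Arg(z)
  dph <- diff(ph)
  dph <- (dph + pi) %% (2 * pi) - pi    # unwrap increments
  dph * fs / (2 * pi)
}

# Ridge error of a TFD against a known instantaneous-frequency line (Hz):
# the energy-weighted mean absolute deviation of the cells from the line, a
# concentration measure that rewards energy gathered on the ridge.
ridge_error <- function(tfd, f_line) {
  dev <- abs(outer(f_line, tfd$bin_freqs, function(a, b) b - a))
  sum(tfd$values * dev) / sum(tfd$values)
}
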