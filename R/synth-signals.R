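#' Parameters of a multi-harmonic signal
#'
#' Describes a sum of `K` sinusoids with amplitudes `A_n` and frequencies
#' `f0 + n * delta_f`, `n = 0, ..., K - 1`:
#' \deqn{x(t) = \sum_{n=0}^{K-1} A_n \sin(2\pi (f_0 + n\Delta f) t + \phi_n).}
#'
#' @param K Number of harmonic components (>= 1).
#' @param amplitudes Amplitudes `A_n`; recycled to length `K`.
#' @param f0 Fundamental frequency in Hz (> 0).
#' @param delta_f Frequency step between components in Hz.
#' @param duration Signal duration `T` in seconds.
#' @param phases Per-component initial phases in radians; recycled to length
#'   `K`.  The closed-form model has zero phases; the detection harness draws
#'   them uniformly on `[0, 2*pi)`.
#' @return An object of class `harmonic_params`.
#' @export
harmonic_params <- function(K, amplitudes = 1, f0, delta_f = 0,
                            duration = 1, phases = 0) {
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  if (f0 <= 0) stop("f0 must be positive")
  if (duration <= 0) stop("duration must be positive")
  structure(
    list(K = K,
         amplitudes = rep_len(as.numeric(amplitudes), K),
         f0 = f0, delta_f = delta_f, duration = duration,
         phases = rep_len(as.numeric(phases), K)),
    class = "harmonic_params"
  )
}

#' Generate a multi-harmonic frame
#'
#' @param params A [harmonic_params()] object.
#' @param sample_rate Sampling frequency in Hz.
#' @return A [signal_frame()] of length `round(duration * sample_rate)`.
#'   Any component at or above the Nyquist frequency is rejected.
#' @examples
#' fr <- gen_harmonic(harmonic_params(K = 1, f0 = 1000), 16000)
#' sqrt(mean(fr$samples^2))  # RMS of a unit sinusoid, 1/sqrt(2)
#' @export
gen_harmonic <- function(params, sample_rate) {
  stopifnot(inherits(params, "harmonic_params"))
  freqs <- params$f0 + (seq_len(params$K) - 1) * params$delta_f
  if (any(freqs <= 0)) stop("all component frequencies must be positive")
  if (any(freqs >= sample_rate / 2)) {
    stop(sprintf(
      "frequency aliasing: component at %g Hz is at or above Nyquist (%g Hz)",
      max(freqs), sample_rate / 2))
  }
  n <- round(params$duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  x <- numeric(n)
  for (i in seq_len(params$K)) {
    x <- x + params$amplitudes[i] *
      sin(2 * pi * freqs[i] * t + params$phases[i])
  }
  signal_frame(x, sample_rate, label = sprintf("harmonic K=%d", params$K))
}

#' Parameters of a linear FM chirp
#'
#' A chirp whose instantaneous frequency follows the linear law
#' `f(t) = c t + f_start` with sweep rate `c = (f_end - f_start) / duration`,
#' i.e. `x(t) = sin(phi0 + 2 pi (c t^2 / 2 + f_start t))`.
#'
#' @param f_start Frequency at `t = 0`, Hz.
#' @param f_end Frequency at `t = duration`, Hz.
#' @param duration Duration `T` in seconds.
#' @param phi0 Initial phase in radians.
#' @return An object of class `chirp_params` with the derived sweep rate `c`
#'   (Hz per second) as element `rate`.
#' @export
chirp_params <- function(f_start, f_end, duration = 1, phi0 = 0) {
  if (f_start <= 0 || f_end <= 0) stop("chirp frequencies must be positive")
  if (duration <= 0) stop("duration must be positive")
  structure(
    list(phi0 = phi0, f_start = f_start, f_end = f_end, duration = duration,
         rate = (f_end - f_start) / duration),
    class = "chirp_params"
  )
}

#' Generate a linear FM chirp frame
#'
#' @param params A [chirp_params()] object.
#' @param sample_rate Sampling frequency in Hz; both end frequencies must be
#'   below Nyquist.
#' @return A [signal_frame()].
#' @export
gen_chirp <- function(params, sample_rate) {
  stopifnot(inherits(params, "chirp_params"))
  if (max(params$f_start, params$f_end) >= sample_rate / 2) {
    stop("chirp frequencies must be below Nyquist")
  }
  n <- round(params$duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  x <- sin(params$phi0 +
             2 * pi * (params$rate * t^2 / 2 + params$f_start * t))
  signal_frame(x, sample_rate,
               label = sprintf("chirp %g->%g Hz", params$f_start, params$f_end))
}

#' Band-limited Gaussian noise
#'
#' White Gaussian noise confined to a frequency band by a deterministic
#' spectral mask: the DFT coefficients outside the band are zeroed and the
#' signal transformed back.  This gives exact band confinement with no
#' filter-design ambiguity.
#'
#' @param band Two-element numeric `(low, high)` in Hz, inside `(0, Nyquist]`.
#'   Use `c(0, sample_rate / 2)` for full-band (white) noise.
#' @param length Number of samples.
#' @param sample_rate Sampling frequency in Hz.
#' @param seed Integer seed; the same seed reproduces the samples bit for bit.
#' @return A [signal_frame()].
#' @export
band_noise <- function(band, length, sample_rate, seed) {
  band <- as.numeric(band)
  if (length(band) != 2L || band[1] >= band[2]) {
    stop("band must be (low, high) with low < high")
  }
  if (band[1] < 0 || band[2] > sample_rate / 2) {
    stop("band must lie inside (0, Nyquist)")
  }
  n <- as.integer(length)
  w <- with_seed(seed, stats::rnorm(n))
  freqs <- (seq_len(n) - 1) / n * sample_rate          # two-sided DFT grid
  folded <- pmin(freqs, sample_rate - freqs)           # one-sided equivalents
  keep <- folded >= band[1] & folded <= band[2]
  if (!any(keep)) stop("band contains no DFT bins at this length")
  X <- stats::fft(w)
  X[!keep] <- 0
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  signal_frame(x, sample_rate,
               label = sprintf("band noise %g-%g Hz", band[1], band[2]))
}

#' Parameters of the cavitation vessel-noise model
#'
#' Models the acoustic radiation of a marine vessel as broadband cavitation
#' noise amplitude-modulated by the propeller-shaft harmonics:
#' \deqn{x(t) = \left(1 + \sum_{n=1}^{K} A_n \sin(2\pi n f_0 t)\right) w_c(t) + w_e(t),}
#' where `f0` is the shaft rotation frequency, `w_c` is band-limited Gaussian
#' cavitation noise and `w_e` is ambient (white Gaussian) sea noise.
#' The blade frequency `m * f0` (propeller blade count `m`) is emphasised by
#' boosting the default amplitude of harmonics at multiples of `m`.
#'
#' @param shaft_f0 Shaft rotation frequency in Hz.
#' @param K Number of shaft harmonics forming the modulation tonal scale.
#' @param amplitudes Modulation amplitudes `A_n`, recycled to length `K`; the
#'   default gives 0.25 to every harmonic and 0.5 to blade-rate multiples.
#' @param blade_count Number of propeller blades `m`.
#' @param cavitation_band Frequency band of the cavitation noise, Hz.
#' @param snr_db Signal-to-noise ratio of the modulated cavitation term
#'   against the ambient noise, in dB; `Inf` for no ambient noise.
#' @return An object of class `vessel_params`.
#' @export
vessel_params <- function(shaft_f0 = 10, K = 8, amplitudes = NULL,
                          blade_count = 4, cavitation_band = c(1000, 3000),
                          snr_db = Inf) {
  if (shaft_f0 <= 0) stop("shaft_f0 must be positive")
  K <- as.integer(K)
  if (K < 0L) stop("K must be >= 0")
  if (cavitation_band[1] >= cavitation_band[2]) {
    stop("cavitation_band must be (low, high) with low < high")
  }
  if (is.null(amplitudes)) {
    amplitudes <- rep(0.25, K)
    if (K >= blade_count) {
      idx <- seq(blade_count, K, by = blade_count)
      amplitudes[idx] <- 0.5
    }
  }
  structure(
    list(shaft_f0 = shaft_f0, K = K,
         amplitudes = rep_len(as.numeric(amplitudes), max(K, 1L))[seq_len(K)],
         blade_count = as.integer(blade_count),
         cavitation_band = as.numeric(cavitation_band),
         snr_db = snr_db),
    class = "vessel_params"
  )
}

#' Generate a cavitation-modulated vessel-noise frame
#'
#' The harmonic envelope `1 + sum A_n sin(2 pi n f0 t)` multiplies only the
#' cavitation noise; ambient noise is additive and scaled so that the energy
#' ratio of the modulated cavitation term to the ambient term matches
#' `params$snr_db` exactly.  An envelope that goes negative (over-modulation
#' from large `A_n`) is permitted; a message notes it.
#'
#' @param params A [vessel_params()] object.
#' @param sample_rate Sampling frequency in Hz; the cavitation band must lie
#'   below Nyquist.
#' @param length Number of samples.
#' @param seed Integer seed (cavitation and ambient noise use independent
#'   substreams derived from it).
#' @return A [signal_frame()].
#' @export
gen_vessel <- function(params, sample_rate, length, seed) {
  stopifnot(inherits(params, "vessel_params"))
  if (params$cavitation_band[2] > sample_rate / 2) {
    stop("cavitation band must lie below Nyquist")
  }
  n <- as.integer(length)
  t <- (seq_len(n) - 1) / sample_rate
  env <- rep(1, n)
  for (k in seq_len(params$K)) {
    env <- env + params$amplitudes[k] *
      sin(2 * pi * k * params$shaft_f0 * t)
  }
  if (any(env < 0)) {
    message("vessel model: modulation envelope goes negative (over-modulation)")
  }
  wc <- band_noise(params$cavitation_band, n, sample_rate,
                   substream_seed(seed, 1L))$samples
  sig <- env * wc
  e_sig <- sum(sig^2)
  if (is.finite(params$snr_db)) {
    we <- with_seed(substream_seed(seed, 2L), stats::rnorm(n))
    if (e_sig == 0) {
      x <- we
    } else {
      # scale ambient noise so 10*log10(E_signal / E_noise) = snr_db
      we <- we * sqrt(e_sig / (sum(we^2) * 10^(params$snr_db / 10)))
      x <- sig + we
    }
  } else {
    x <- sig
  }
  signal_frame(x, sample_rate,
               label = sprintf("vessel f0=%g Hz", params$shaft_f0))
}

#' Mix a signal and a noise frame at an exact SNR
#'
#' Rescales the signal so that `10 * log10(sum(s^2) / sum(w^2))` equals
#' `snr_db` exactly, and returns the two detection hypotheses: the noise-only
#' frame (hypothesis Gamma0) and the scaled-signal-plus-noise mixture
#' (hypothesis Gamma1).  `snr_db = -Inf` yields a zero-amplitude signal, so
#' both hypotheses coincide (the null case of a detection study).
#'
#' @param signal A [signal_frame()] carrying the useful signal.
#' @param noise A [signal_frame()] of the same length and rate.
#' @param snr_db Requested signal-to-noise ratio in dB.
#' @return An object of class `frame_pair`: list with `noise_frame` (Gamma0),
#'   `mixture_frame` (Gamma1), `snr_db` and the applied `scale`.
#' @export
mix_at_snr <- function(signal, noise, snr_db) {
  stopifnot(inherits(signal, "signal_frame"), inherits(noise, "signal_frame"))
  if (length(signal$samples) != length(noise$samples)) {
    stop("signal and noise must have equal lengths")
  }
  if (signal$sample_rate != noise$sample_rate) {
    stop("signal and noise must share a sample rate")
  }
  e_n <- sum(noise$samples^2)
  if (e_n <= 0) stop("noise must have positive energy")
  if (identical(snr_db, -Inf)) {
    scale <- 0
  } else {
    e_s <- sum(signal$samples^2)
    if (e_s <= 0) stop("signal has zero energy; cannot reach a finite SNR")
    scale <- sqrt(10^(snr_db / 10) * e_n / e_s)
  }
  mix <- signal_frame(noise$samples + scale * signal$samples,
                      noise$sample_rate,
                      label = sprintf("mixture @ %g dB", snr_db))
  structure(
    list(noise_frame = noise, mixture_frame = mix,
         snr_db = snr_db, scale = scale),
    class = "frame_pair"
  )
}

#' @export
print.frame_pair <- function(x, ...) {
  cat(sprintf("<frame_pair> L=%d @ %g Hz, SNR = %g dB\n",
              length(x$noise_frame$samples), x$noise_frame$sample_rate,
              x$snr_db))
  invisible(x)
}
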