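test_that("harmonic generator matches the sinusoid-sum model", {
  # unit sinusoid has RMS 1/sqrt(2)
  fr <- make_tone(1000, L = 16000)
  expect_equal(sqrt(mean(fr$samples^2)), 1 / sqrt(2), tolerance = 1e-3)

  # two equal components: the two largest one-sided DFT bins sit at 1 and 3 kHz
  fr2 <- gen_harmonic(
    harmonic_params(K = 2, f0 = 1000, delta_f = 2000, duration = 1), FS)
  F <- Mod(stats::fft(fr2$samples))^2
  half <- F[seq_len(length(F) %/% 2 + 1)]
  freqs <- (seq_along(half) - 1) / length(fr2$samples) * FS
  top2 <- sort(freqs[order(half, decreasing = TRUE)[1:2]])
  expect_equal(top2, c(1000, 3000))

  # zero amplitude gives the zero frame
  z <- gen_harmonic(harmonic_params(K = 1, amplitudes = 0, f0 = 500), FS)
  expect_true(all(z$samples == 0))

  # component at/above Nyquist is rejected
  expect_error(gen_harmonic(harmonic_params(K = 2, f0 = 7000, delta_f = 2000),
                            FS),
               "aliasing")

  # K = 1, zero phase: periodic with period 1/f0
  fr <- make_tone(1000, L = 160)
  per <- FS / 1000
  expect_equal(fr$samples[1:(160 - per)], fr$samples[(per + 1):160],
               tolerance = 1e-12)
})

test_that("chirp generator follows the linear frequency law", {
  p <- chirp_params(f_start = 100, f_end = 900, duration = 1)
  expect_equal(p$rate, 800)

  # degenerate chirp is a pure tone
  cfr <- gen_chirp(chirp_params(f_start = 500, f_end = 500, duration = 0.5),
                   FS)
  tfr <- gen_harmonic(harmonic_params(K = 1, f0 = 500, duration = 0.5), FS)
  expect_equal(cfr$samples, tfr$samples, tolerance = 1e-12)

  # instantaneous frequency from the analytic-signal phase derivative
  # matches the linear law within 1% away from the edges
  fr <- gen_chirp(chirp_params(f_start = 500, f_end = 2500, duration = 2), FS)
  f_est <- analytic_if(fr$samples, FS)
  t_mid <- (seq_along(f_est) - 0.5) / FS
  f_true <- 1000 * t_mid + 500
  core <- t_mid > 0.2 & t_mid < 1.8
  expect_lt(max(abs(f_est[core] - f_true[core]) / f_true[core]), 0.01)
})

test_that("band-limited noise is confined to its band and reproducible", {
  L <- 16384
  # full band: statistically white (lag-1 autocorrelation near 0)
  w <- make_white(L, seed = 11)
  r1 <- stats::cor(w$samples[-1], w$samples[-L])
  expect_lt(abs(r1), 4 / sqrt(L))

  # 1-3 kHz band holds >= 99.9% of the energy (periodogram oracle)
  b <- band_noise(c(1000, 3000), L, FS, seed = 12)
  F <- Mod(stats::fft(b$samples))^2
  freqs <- (seq_len(L) - 1) / L * FS
  folded <- pmin(freqs, FS - freqs)
  inband <- folded >= 1000 & folded <= 3000
  expect_gte(sum(F[inband]) / sum(F), 0.999)

  # determinism
  expect_identical(band_noise(c(1000, 3000), L, FS, seed = 5)$samples,
                   band_noise(c(1000, 3000), L, FS, seed = 5)$samples)
  expect_error(band_noise(c(3000, 1000), L, FS, seed = 1), "low < high")
})

test_that("vessel model modulates cavitation noise at the shaft rate", {
  fs <- FS
  L <- 32000  # 2 s: 0.5 Hz resolution puts the 10 Hz line on a bin
  # no modulation, no ambient noise: output is the cavitation noise alone
  p0 <- vessel_params(K = 0, snr_db = Inf)
  v0 <- gen_vessel(p0, fs, L, seed = 3)
  wc <- band_noise(c(1000, 3000), L, fs, tfdinfo:::substream_seed(3, 1L))
  expect_equal(v0$samples, wc$samples, tolerance = 1e-12)

  # envelope-spectrum oracle: the squared signal has its largest
  # low-frequency line at the shaft rate
  p1 <- vessel_params(shaft_f0 = 10, K = 1, amplitudes = 0.8, snr_db = Inf)
  v1 <- gen_vessel(p1, fs, L, seed = 4)
  E <- Mod(stats::fft(v1$samples^2))^2
  freqs <- (seq_len(L) - 1) / L * fs
  lowband <- which(freqs > 2 & freqs < 100)
  expect_equal(freqs[lowband][which.max(E[lowband])], 10, tolerance = 0.5)

  # requested SNR against ambient noise is met exactly
  p2 <- vessel_params(shaft_f0 = 10, K = 2, snr_db = -5)
  v2 <- gen_vessel(p2, fs, L, seed = 9)
  sig <- gen_vessel(vessel_params(shaft_f0 = 10, K = 2, snr_db = Inf),
                    fs, L, seed = 9)
  we <- v2$samples - sig$samples
  expect_equal(10 * log10(sum(sig$samples^2) / sum(we^2)), -5,
               tolerance = 1e-9)
})

test_that("mix_at_snr achieves the requested SNR exactly", {
  s <- make_tone(1000, L = 4096)
  w <- make_white(4096, seed = 21)
  for (snr in c(0, -20)) {
    pr <- mix_at_snr(s, w, snr)
    scaled <- pr$mixture_frame$samples - w$samples
    ratio <- sum(scaled^2) / sum(w$samples^2)
    expect_equal(ratio, 10^(snr / 10), tolerance = 1e-9)
  }
  # Gamma0 passes the noise through untouched
  pr <- mix_at_snr(s, w, -10)
  expect_identical(pr$noise_frame$samples, w$samples)
  # zero-energy signal cannot reach a finite SNR
  z <- signal_frame(numeric(16) + 0, FS)
  expect_error(suppressWarnings(mix_at_snr(z, w, 0)))
  # -Inf yields the null pair
  pr0 <- mix_at_snr(s, w, -Inf)
  expect_identical(pr0$mixture_frame$samples, w$samples)
})

test_that("frames standardize to zero mean and unit sd", {
  fr <- standardize_frame(make_white(4096, seed = 2))
  expect_lt(abs(mean(fr$samples)), 1e-9)
  expect_equal(stats::sd(fr$samples), 1, tolerance = 1e-9)
})
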