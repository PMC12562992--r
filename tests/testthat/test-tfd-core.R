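test_that("stft matches direct DFT summation and Parseval", {
  # zero signal -> all-zero matrix
  z <- signal_frame(rep(0, 2048), FS)
  expect_true(all(stft(z)$values == 0))

  # tone exactly on a bin, rectangular window, hop = N_W: magnitude N_W/2
  # concentrated in that bin (direct summation oracle)
  nw <- 256
  kstar <- 16
  fr <- make_tone(kstar * FS / nw, L = 4 * nw)
  X <- stft(fr, window_spec("rectangular", nw, nw))
  m <- Mod(X$values)
  expect_equal(unname(m[, kstar + 1]), rep(nw / 2, nrow(m)), tolerance = 1e-6)
  expect_lt(max(m[, -(kstar + 1)]), 1e-6 * nw)

  # Parseval with rectangular window, hop = N_W: two-sided |STFT|^2 equals
  # N_W * sum(x^2)
  set.seed(31)
  x <- rnorm(4 * nw)
  fr <- signal_frame(x, FS)
  X <- stft(fr, window_spec("rectangular", nw, nw))
  w2 <- c(1, rep(2, nw / 2 - 1), 1)   # fold-back weights of the one-sided grid
  e2 <- sum(sweep(Mod(X$values)^2, 2, w2, "*"))
  expect_equal(e2, nw * sum(x^2), tolerance = 1e-9 * e2)

  expect_error(stft(signal_frame(rnorm(100), FS), window_spec("hann", 512)),
               "shorter")
})

test_that("spectrogram is the squared STFT magnitude with correct peaks", {
  fr <- make_tone(1000, L = 4096)
  w <- window_spec("hann", 512, 128)
  expect_equal(spectrogram(fr, w)$values, Mod(stft(fr, w)$values)^2)

  # time-marginal argmax at the bin nearest 1 kHz
  S <- spectrogram(fr, w)
  marg <- colSums(S$values)
  expect_equal(S$bin_freqs[which.max(marg)], 1000)

  # white noise spreads: no bin holds more than 5% of the energy
  wn <- make_white(16384, seed = 41)
  Sn <- spectrogram(wn, w)
  expect_lt(max(Sn$values) / sum(Sn$values), 0.05)

  # amplitude scaling by a scales the spectrogram by a^2; sign flip is nil
  fr2 <- signal_frame(3 * fr$samples, FS)
  expect_equal(spectrogram(fr2, w)$values, 9 * S$values, tolerance = 1e-12)
  fr3 <- signal_frame(-fr$samples, FS)
  expect_equal(spectrogram(fr3, w)$values, S$values, tolerance = 1e-12)
})

test_that("reassignment centroids locate tones and impulses", {
  w <- window_spec("hann", 512, 128)
  bin_hz <- FS / 512

  # tone on a bin center: omega_hat at the peak bin equals the tone frequency
  fr <- make_tone(32 * bin_hz, L = 4096)
  rf <- reassignment_fields(fr, w)
  mid <- nrow(rf$f_hat) %/% 2
  expect_lt(abs(rf$f_hat[mid, 33] - 32 * bin_hz), bin_hz)

  # tone midway between bins: both neighbours move toward the true frequency
  f_true <- 32.5 * bin_hz
  fr <- make_tone(f_true, L = 4096)
  rf <- reassignment_fields(fr, w)
  expect_lt(abs(rf$f_hat[mid, 33] - f_true), bin_hz / 2)
  expect_lt(abs(rf$f_hat[mid, 34] - f_true), bin_hz / 2)

  # impulse: t_hat near the impulse column equals the impulse time
  x <- numeric(4096)
  x[2049] <- 1
  rf <- reassignment_fields(signal_frame(x, FS), w)
  t0 <- 2048 / FS
  col <- which.min(abs(rf$frame_times - t0))
  hop_s <- 128 / FS
  expect_lt(abs(rf$t_hat[col, 11] - t0), hop_s)
})

test_that("reassignment conserves energy and sharpens ridges", {
  w <- window_spec("hann", 512, 128)
  frames <- list(
    tone = make_tone(1000, L = 8192),
    chirp = gen_chirp(chirp_params(500, 4000, duration = 8192 / FS), FS),
    noise = make_white(8192, seed = 51))
  for (fr in frames) {
    S <- spectrogram(fr, w)
    R <- reassign(fr, w)
    expect_equal(sum(R$values), sum(S$values),
                 tolerance = 1e-9)
    expect_true(all(R$values >= 0))
  }

  # tone: the best frequency row holds strictly more energy after reassignment
  S <- spectrogram(frames$tone, w)
  R <- reassign(frames$tone, w)
  share <- function(v) max(colSums(v)) / sum(v)
  expect_gt(share(R$values), share(S$values))

  # chirp: energy gathers onto the true instantaneous-frequency line --
  # the ridge error (energy-weighted deviation from the line) shrinks
  fr <- frames$chirp
  S <- spectrogram(fr, w)
  R <- reassign(fr, w)
  f_line <- 500 + (4000 - 500) / (8192 / FS) * S$frame_times
  expect_lte(ridge_error(R, f_line), ridge_error(S, f_line))

  # drop policy discards out-of-grid energy, never exceeding the clip total
  Rd <- reassign(frames$noise, w, boundary = "drop")
  Rc <- reassign(frames$noise, w, boundary = "clip")
  expect_lte(sum(Rd$values), sum(Rc$values))
})
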