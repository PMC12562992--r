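#' Analysis window specification
#'
#' @param name Window family: `"hann"` (default; analytic derivative),
#'   `"hamming"` or `"rectangular"` (derivative by central finite
#'   differences).
#' @param length Window length `N_W` in samples.
#' @param hop Hop between consecutive windows in samples; defaults to
#'   `N_W / 4`, the overlap used throughout the detection experiments.
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(name = c("hann", "hamming", "rectangular"),
                        length = 512L, hop = NULL) {
  name <- match.arg(name)
  length <- as.integer(length)
  if (length < 2L) stop("window length must be >= 2")
  if (is.null(hop)) hop <- length %/% 4L
  hop <- as.integer(hop)
  if (hop < 1L || hop > length) stop("hop must satisfy 1 <= hop <= length")
  structure(list(name = name, length = length, hop = hop),
            class = "window_spec")
}

# Sampled window h, its time-weighted companion t*h (seconds, relative to the
# window center) and time derivative dh/dt (1/s).  The symmetric window is
# supported on [-T/2, T/2] with T = (N_W - 1)/fs, so h equals the standard
# symmetric Hann/Hamming samples.
window_samples <- function(spec, sample_rate) {
  nw <- spec$length
  j <- seq_len(nw) - 1
  center <- (nw - 1) / 2
  s <- (j - center) / sample_rate          # time rel. to window center, s
  T <- (nw - 1) / sample_rate
  if (spec$name == "hann") {
    h <- 0.5 * (1 + cos(2 * pi * s / T))
    dh <- -(pi / T) * sin(2 * pi * s / T)  # analytic derivative
  } else if (spec$name == "hamming") {
    h <- 0.54 + 0.46 * cos(2 * pi * s / T)
    dh <- central_diff(h, sample_rate)
  } else {
    h <- rep(1, nw)
    dh <- central_diff(h, sample_rate)
  }
  list(h = h, th = s * h, dh = dh, center = center)
}

central_diff <- function(h, sample_rate) {
  n <- length(h)
  d <- numeric(n)
  d[2:(n - 1)] <- (h[3:n] - h[1:(n - 2)]) / 2
  d[1] <- h[2] - h[1]
  d[n] <- h[n] - h[n - 1]
  d * sample_rate
}

# Windowed-segment STFT core shared by the three analysis windows of the
# reassignment method.  Returns an M x N complex matrix (rows = windows,
# cols = one-sided frequency bins 0..N_W/2).
stft_matrix <- function(x, win_values, nw, hop) {
  L <- length(x)
  M <- (L - nw) %/% hop + 1L
  idx <- outer(seq_len(nw), (seq_len(M) - 1L) * hop, "+")
  seg <- matrix(x[idx], nw, M) * win_values
  X <- stats::mvfft(seg)                 # nw x M
  t(X[seq_len(nw %/% 2 + 1L), , drop = FALSE])
}

#' Short-time Fourier transform
#'
#' Computes the discrete STFT on a regular time-frequency grid: column `n` of
#' the underlying transform is the DFT of the windowed segment starting at
#' `n * hop` samples.  Only the one-sided bins `k = 0, ..., N_W/2` are
#' retained (DC and Nyquist included, energies not doubled); downstream
#' distributions renormalize, so the convention is immaterial to the
#' information measures.
#'
#' @param frame A [signal_frame()] at least one window long.  The last
#'   partial window is dropped; no zero padding.
#' @param window A [window_spec()].
#' @return An object of class `complex_tfd`: list with complex `values`
#'   (M windows x N bins), `frame_times` (s, at window centers), `bin_freqs`
#'   (Hz), `window` and `sample_rate`.
#' @export
stft <- function(frame, window = window_spec()) {
  stopifnot(inherits(frame, "signal_frame"), inherits(window, "window_spec"))
  L <- length(frame$samples)
  if (L < window$length) {
    stop("frame is shorter than one analysis window")
  }
  ws <- window_samples(window, frame$sample_rate)
  vals <- stft_matrix(frame$samples, ws$h, window$length, window$hop)
  M <- nrow(vals)
  structure(
    list(values = vals,
         frame_times = ((seq_len(M) - 1) * window$hop + ws$center) /
           frame$sample_rate,
         bin_freqs = (0:(window$length %/% 2)) *
           frame$sample_rate / window$length,
         window = window,
         sample_rate = frame$sample_rate),
    class = "complex_tfd"
  )
}

new_tfd_matrix <- function(values, frame_times, bin_freqs, kind,
                           sample_rate, window) {
  structure(
    list(values = values, frame_times = frame_times, bin_freqs = bin_freqs,
         kind = kind, sample_rate = sample_rate, window = window),
    class = "tfd_matrix"
  )
}

#' @export
print.tfd_matrix <- function(x, ...) {
  cat(sprintf("<tfd_matrix:%s> %d windows x %d bins, fs = %g Hz\n",
              x$kind, nrow(x$values), ncol(x$values), x$sample_rate))
  invisible(x)
}

#' Spectrogram
#'
#' Element-wise squared magnitude of the STFT: a non-negative time-frequency
#' energy distribution.
#'
#' @inheritParams stft
#' @return A `tfd_matrix` with `kind = "spectrogram"`.
#' @export
spectrogram <- function(frame, window = window_spec()) {
  X <- stft(frame, window)
  new_tfd_matrix(Mod(X$values)^2, X$frame_times, X$bin_freqs,
                 "spectrogram", X$sample_rate, X$window)
}

#' Reassignment coordinate fields
#'
#' For every spectrogram cell, the local energy-centroid coordinates
#' `(t_hat, f_hat)` computed by the STFT route: three transforms with the
#' analysis window `h`, its time-weighted companion `t*h` and its time
#' derivative `dh/dt`, combined as
#' `t_hat = t + Re(STFT_th / STFT_h)` and
#' `f_hat = f - Im(STFT_dh / STFT_h) / (2*pi)`.
#' Cells whose STFT magnitude falls below `1e-12` of the maximum are masked
#' (their ratio is numerically meaningless) and keep their original
#' coordinates.
#'
#' @inheritParams stft
#' @return An object of class `reassignment_fields`: list with `t_hat` (s),
#'   `f_hat` (Hz), logical `magnitude_mask` (TRUE where usable), and the
#'   grid metadata.
#' @export
reassignment_fields <- function(frame, window = window_spec()) {
  stopifnot(inherits(frame, "signal_frame"), inherits(window, "window_spec"))
  L <- length(frame$samples)
  if (L < window$length) stop("frame is shorter than one analysis window")
  ws <- window_samples(window, frame$sample_rate)
  nw <- window$length
  hop <- window$hop
  Xh <- stft_matrix(frame$samples, ws$h, nw, hop)
  Xt <- stft_matrix(frame$samples, ws$th, nw, hop)
  Xd <- stft_matrix(frame$samples, ws$dh, nw, hop)
  M <- nrow(Xh)
  N <- ncol(Xh)
  frame_times <- ((seq_len(M) - 1) * hop + ws$center) / frame$sample_rate
  bin_freqs <- (0:(nw %/% 2)) * frame$sample_rate / nw
  magn <- Mod(Xh)
  mask <- magn > 0 & magn >= 1e-12 * max(magn)
  t_grid <- matrix(frame_times, M, N)
  f_grid <- matrix(bin_freqs, M, N, byrow = TRUE)
  t_hat <- t_grid
  f_hat <- f_grid
  rt <- Xt[mask] / Xh[mask]
  rd <- Xd[mask] / Xh[mask]
  t_hat[mask] <- t_grid[mask] + Re(rt)
  f_hat[mask] <- f_grid[mask] - Im(rd) / (2 * pi)
  structure(
    list(t_hat = t_hat, f_hat = f_hat, magnitude_mask = mask,
         frame_times = frame_times, bin_freqs = bin_freqs,
         window = window, sample_rate = frame$sample_rate),
    class = "reassignment_fields"
  )
}

#' Reassigned spectrogram
#'
#' Moves each spectrogram cell's energy to the grid cell nearest its local
#' energy centroid `(t_hat, f_hat)`, sharpening ridges of tonal and
#' frequency-modulated components.  Total energy is conserved: with the
#' default `boundary = "clip"` policy, out-of-grid centroids are clipped to
#' the boundary cell; `"drop"` discards their energy instead.  Exact
#' half-cell ties round toward the lower index.
#'
#' @inheritParams stft
#' @param boundary Out-of-grid centroid policy, `"clip"` (default) or
#'   `"drop"`.
#' @return A `tfd_matrix` with `kind = "reassigned"` on the same grid as
#'   [spectrogram()].
#' @export
reassign <- function(frame, window = window_spec(),
                     boundary = c("clip", "drop")) {
  boundary <- match.arg(boundary)
  S <- spectrogram(frame, window)
  rf <- reassignment_fields(frame, window)
  M <- nrow(S$values)
  N <- ncol(S$values)
  hop_s <- window$hop / frame$sample_rate
  bin_hz <- frame$sample_rate / window$length
  # nearest grid node; ties toward the lower index
  ti <- ceiling((rf$t_hat - rf$frame_times[1]) / hop_s - 0.5) + 1
  fi <- ceiling(rf$f_hat / bin_hz - 0.5) + 1
  keep <- rep(TRUE, M * N)
  if (boundary == "clip") {
    ti <- pmin(pmax(ti, 1), M)
    fi <- pmin(pmax(fi, 1), N)
  } else {
    keep <- ti >= 1 & ti <= M & fi >= 1 & fi <= N
  }
  idx <- (fi - 1) * M + ti
  v <- as.vector(S$values)[keep]
  idx <- as.vector(idx)[keep]
  acc <- rowsum(v, group = idx)
  R <- numeric(M * N)
  R[as.integer(rownames(acc))] <- acc[, 1]
  new_tfd_matrix(matrix(R, M, N), S$frame_times, S$bin_freqs,
                 "reassigned", S$sample_rate, S$window)
}
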