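#' Configuration of the Monte-Carlo detection experiment
#'
#' Defines the study conditions of the detection sweep: for each SNR grid
#' point, `q_frames` independent hypothesis pairs are generated -- Gamma0
#' (white Gaussian noise alone) and Gamma1 (random model signal mixed into
#' the same noise at the exact SNR) -- and every registered information
#' feature is scored on both.
#'
#' Randomization of the model signal per pair:
#' harmonic -- component count `K` uniform on `20..50`, unit amplitudes,
#' uniform phases, fundamental drawn in `(0.01, 0.03) * fs` and the top
#' component in `(0.25, 0.45) * fs` (equal frequency steps);
#' chirp -- start/end frequencies uniform in `(0.05, 0.45) * fs`
#' (start < end), uniform initial phase;
#' vessel -- fixed default [vessel_params()] with a fresh cavitation noise
#' seed per pair.
#'
#' @param signal_kind `"harmonic"`, `"chirp"` or `"vessel"`.
#' @param q_frames Hypothesis pairs per SNR point (production scale 20000;
#'   desk scale a few hundred).
#' @param frame_length Samples per frame; default 16384.
#' @param sample_rate Hz; default 16000.
#' @param snr_grid SNRs in dB; default `-20, -15, ..., 0`.  `-Inf` entries
#'   give the null (no-signal) case.
#' @param window A [window_spec()].
#' @param alpha Renyi order; default 3.
#' @param p_fa False-alarm rate of the detection-probability operating
#'   point; default 0.05.
#' @param master_seed Integer; every random draw derives from it.
#' @param features Subset of [feature_registry()] names to score; `NULL`
#'   for all.
#' @param with_psc Include the stochastic-matrix features?
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(signal_kind = c("harmonic", "chirp", "vessel"),
                              q_frames = 200L,
                              frame_length = 16384L,
                              sample_rate = 16000,
                              snr_grid = seq(-20, 0, by = 5),
                              window = window_spec(),
                              alpha = 3,
                              p_fa = 0.05,
                              master_seed = 1L,
                              features = NULL,
                              with_psc = FALSE) {
  signal_kind <- match.arg(signal_kind)
  if (q_frames < 2L) stop("q_frames must be >= 2")
  if (length(snr_grid) == 0) stop("snr_grid must be non-empty")
  if (p_fa <= 0 || p_fa >= 1) stop("p_fa must be in (0, 1)")
  reg <- feature_registry(with_psc)
  if (!is.null(features)) {
    bad <- setdiff(features, reg)
    if (length(bad) > 0) stop("unknown features: ", paste(bad, collapse = ", "))
  }
  structure(
    list(signal_kind = signal_kind, q_frames = as.integer(q_frames),
         frame_length = as.integer(frame_length), sample_rate = sample_rate,
         snr_grid = snr_grid, window = window, alpha = alpha, p_fa = p_fa,
         master_seed = as.integer(master_seed), features = features,
         with_psc = with_psc),
    class = "experiment_config"
  )
}

# Draw one random model signal frame for the experiment; called inside a
# seeded substream.
random_signal_frame <- function(kind, frame_length, sample_rate) {
  dur <- frame_length / sample_rate
  if (kind == "harmonic") {
    K <- sample(20:50, 1L)
    f0 <- stats::runif(1, 0.01, 0.03) * sample_rate
    f_top <- stats::runif(1, 0.25, 0.45) * sample_rate
    gen_harmonic(
      harmonic_params(K = K, amplitudes = 1, f0 = f0,
                      delta_f = (f_top - f0) / (K - 1), duration = dur,
                      phases = stats::runif(K, 0, 2 * pi)),
      sample_rate)
  } else if (kind == "chirp") {
    f <- sort(stats::runif(2, 0.05, 0.45) * sample_rate)
    gen_chirp(
      chirp_params(f_start = f[1], f_end = f[2], duration = dur,
                   phi0 = stats::runif(1, 0, 2 * pi)),
      sample_rate)
  } else {
    gen_vessel(vessel_params(snr_db = Inf), sample_rate, frame_length,
               seed = sample.int(2147483646L, 1L))
  }
}

#' Rank-based AUC-ROC of two score samples
#'
#' The probability that a Gamma1 (signal-present) score exceeds a Gamma0
#' (noise-only) score, ties counted one half -- the Mann-Whitney statistic.
#' Because entropy-type features *decrease* under signal presence, the
#' orientation is auto-flipped so the returned AUC is `>= 0.5`; the flip is
#' recorded in the `"flipped"` attribute.
#'
#' @param scores0 Numeric scores under the noise-only hypothesis.
#' @param scores1 Numeric scores under the signal-plus-noise hypothesis.
#' @param orient Auto-flip so AUC >= 0.5?  Set `FALSE` for the raw value.
#' @return AUC in `[0, 1]` with attribute `flipped`.
#' @export
auc_roc <- function(scores0, scores1, orient = TRUE) {
  n0 <- length(scores0)
  n1 <- length(scores1)
  if (n0 == 0 || n1 == 0) stop("both score sets must be non-empty")
  r <- rank(c(scores0, scores1))
  auc <- (sum(r[(n0 + 1):(n0 + n1)]) - n1 * (n1 + 1) / 2) / (n0 * n1)
  flipped <- FALSE
  if (orient && auc < 0.5) {
    auc <- 1 - auc
    flipped <- TRUE
  }
  structure(auc, flipped = flipped)
}

#' Detection probability at a fixed false-alarm rate
#'
#' Neyman-Pearson-style operating point: after orienting the scores so that
#' signal presence raises them, the threshold is the empirical `1 - p_fa`
#' quantile of the Gamma0 scores and `Prd` is the fraction of Gamma1 scores
#' beyond it.
#'
#' @inheritParams auc_roc
#' @param p_fa False-alarm rate in `(0, 1)`.
#' @param flip Orientation: `NULL` (default) decides from the rank AUC;
#'   otherwise a logical.
#' @return Detection probability in `[0, 1]`.
#' @export
detection_probability <- function(scores0, scores1, p_fa = 0.05, flip = NULL) {
  if (p_fa <= 0 || p_fa >= 1) stop("p_fa must be in (0, 1)")
  if (is.null(flip)) {
    flip <- attr(auc_roc(scores0, scores1, orient = TRUE), "flipped")
  }
  if (flip) {
    scores0 <- -scores0
    scores1 <- -scores1
  }
  thr <- stats::quantile(scores0, probs = 1 - p_fa, names = FALSE, type = 7)
  mean(scores1 > thr)
}

# Freedman-Diaconis histogram summary (diagnostics only; AUC is rank-based).
fd_hist <- function(x) {
  h <- graphics::hist(x, breaks = "FD", plot = FALSE)
  list(breaks = h$breaks, counts = h$counts)
}

#' Run the Monte-Carlo detection experiment
#'
#' For each SNR on the grid and each registered feature, scores `q_frames`
#' Gamma0/Gamma1 hypothesis pairs and derives the rank AUC-ROC and the
#' detection probability at the configured false-alarm rate.  Fully seeded:
#' the same configuration reproduces every number bit for bit.  A feature
#' that is constant across all scores carries no ranking information; its
#' AUC is reported as 0.5 with a warning.
#'
#' @param config An [experiment_config()].
#' @param keep_histograms Keep Freedman-Diaconis histogram summaries of the
#'   per-hypothesis score samples (diagnostics)?
#' @return An object of class `detection_result`: list with the `config`,
#'   a `curves` data frame (`feature`, `snr_db`, `auc`, `prd`, `n_frames`)
#'   and optionally `histograms`.
#' @export
run_detection_experiment <- function(config, keep_histograms = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  reg <- feature_registry(config$with_psc)
  sel <- if (is.null(config$features)) reg else config$features
  curves <- list()
  histograms <- list()
  for (si in seq_along(config$snr_grid)) {
    snr <- config$snr_grid[si]
    s0 <- matrix(NA_real_, config$q_frames, length(sel),
                 dimnames = list(NULL, sel))
    s1 <- s0
    for (qi in seq_len(config$q_frames)) {
      seed <- substream_seed(config$master_seed, (si - 1L) * 1000003L + qi)
      pair <- with_seed(seed, {
        noise <- signal_frame(stats::rnorm(config$frame_length),
                              config$sample_rate, "wgn")
        sig <- random_signal_frame(config$signal_kind, config$frame_length,
                                   config$sample_rate)
        mix_at_snr(sig, noise, snr)
      })
      s0[qi, ] <- feature_values(pair$noise_frame, config$alpha,
                                 config$window, sel)
      s1[qi, ] <- feature_values(pair$mixture_frame, config$alpha,
                                 config$window, sel)
    }
    for (f in sel) {
      if (stats::sd(c(s0[, f], s1[, f])) == 0) {
        warning(sprintf("feature %s is constant at SNR %g dB; AUC set to 0.5",
                        f, snr))
        auc <- 0.5
        prd <- config$p_fa
        flipped <- FALSE
      } else {
        a <- auc_roc(s0[, f], s1[, f])
        auc <- as.numeric(a)
        flipped <- attr(a, "flipped")
        prd <- detection_probability(s0[, f], s1[, f], config$p_fa,
                                     flip = flipped)
      }
      curves[[length(curves) + 1L]] <- data.frame(
        feature = f, snr_db = snr, auc = auc, prd = prd,
        flipped = flipped, n_frames = config$q_frames,
        stringsAsFactors = FALSE)
      if (keep_histograms) {
        histograms[[sprintf("%s@%gdB", f, snr)]] <-
          list(gamma0 = fd_hist(s0[, f]), gamma1 = fd_hist(s1[, f]))
      }
    }
  }
  structure(
    list(config = config, curves = do.call(rbind, curves),
         histograms = if (keep_histograms) histograms else NULL),
    class = "detection_result"
  )
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf(
    "<detection_result> %s signals, Q = %d per SNR, %d features x %d SNRs\n",
    x$config$signal_kind, x$config$q_frames,
    length(unique(x$curves$feature)), length(x$config$snr_grid)))
  invisible(x)
}

#' Entropy-complexity (H/C) plane points
#'
#' One `(H, C)` pair per frame for a chosen entropy/disequilibrium
#' combination and distribution support; the scatter of these points
#' separates signal classes that entropy alone does not.
#'
#' @param frames List of [signal_frame()]s.
#' @param entropy_kind `"shannon"` or `"renyi"`.
#' @param diseq_kind `"sq"`, `"jsd"`, `"tv"` or `"renyi_jsd"`.
#' @param support `"PF"` (spectrum), `"PS"` (spectrogram) or `"PR"`
#'   (reassigned spectrogram).
#' @param config An [info_config()].
#' @param labels Class labels passed through to the output; default each
#'   frame's own label.
#' @return A `data.frame` with columns `H`, `C`, `label`.
#' @export
hc_points <- function(frames, entropy_kind = "shannon", diseq_kind = "tv",
                      support = c("PS", "PF", "PR"),
                      config = info_config(), labels = NULL) {
  support <- match.arg(support)
  if (length(frames) == 0) stop("no frames")
  if (is.null(labels)) {
    labels <- vapply(frames, function(f) f$label, character(1))
  } else {
    labels <- rep_len(as.character(labels), length(frames))
  }
  one <- function(fr) {
    p <- switch(support,
      PF = spectrum_distribution(fr),
      PS = tfd_distribution(spectrogram(fr, config$window)),
      PR = tfd_distribution(reassign(fr, config$window)))
    h <- if (entropy_kind == "shannon") {
      shannon_entropy(p, normalized = TRUE)
    } else {
      renyi_entropy(p, config$alpha, normalized = TRUE)
    }
    c(H = h,
      C = complexity(p, entropy_kind, diseq_kind, alpha = config$alpha))
  }
  m <- t(vapply(frames, one, numeric(2)))
  data.frame(H = m[, "H"], C = m[, "C"], label = labels,
             stringsAsFactors = FALSE)
}
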