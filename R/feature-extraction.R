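#' Configuration of the information feature set
#'
#' @param alpha Renyi order used by every Renyi-family feature; default 3,
#'   the order used throughout the detection experiments.
#' @param window A [window_spec()]; default Hann, length 512, hop 128.
#' @param with_psc Include the three stochastic-matrix features (entropies of
#'   the ergodic limit `Omega` and stationary vector `Pi` of the
#'   column-stochastic spectrogram decomposition)?
#' @return An object of class `info_config`.
#' @export
info_config <- function(alpha = 3, window = window_spec(), with_psc = TRUE) {
  check_alpha(alpha)
  stopifnot(inherits(window, "window_spec"))
  structure(list(alpha = alpha, window = window, with_psc = with_psc),
            class = "info_config")
}

# Versioned registry of the canonical 30-feature set: 9 information
# characteristics per support (spectrum PF, spectrogram PS, reassigned
# spectrogram PR) -- the 4 Shannon-family and 5 Renyi-family characteristics
# -- plus 3 entropies of the ergodic pair (Omega, Pi).
FEATURE_REGISTRY_VERSION <- "1"

support_feature_names <- function(support) {
  paste0(c("H_", "CSQ_", "CJSD_", "CTV_",
           "Halpha_", "CSQalpha_", "CJSDalpha_", "CJalpha_", "CTValpha_"),
         support)
}

#' Names of the canonical feature set, in registry order
#'
#' @param with_psc Include the three stochastic-matrix features?
#' @return Character vector of feature names (30 with `with_psc = TRUE`,
#'   27 without).
#' @export
feature_registry <- function(with_psc = TRUE) {
  nm <- c(support_feature_names("PF"),
          support_feature_names("PS"),
          support_feature_names("PR"))
  if (with_psc) nm <- c(nm, "H_Omega", "Halpha_Omega", "Halpha_Pi")
  nm
}

# The 9 per-support information characteristics of one distribution.
support_features <- function(p, alpha) {
  h <- shannon_entropy(p, normalized = TRUE)
  ha <- renyi_entropy(p, alpha, normalized = TRUE)
  dsq <- disequilibrium_sq(p)
  djsd <- jsd(p)
  dtv <- disequilibrium_tv(p)
  dja <- renyi_jsd(p, alpha = alpha)
  c(h, h * dsq, h * djsd, h * dtv,
    ha, ha * dsq, ha * djsd, ha * dja, ha * dtv)
}

# Compute a subset of registry features, touching only the supports the
# selection needs (e.g. no reassignment when no _PR feature is requested).
feature_values <- function(frame, alpha, window, sel) {
  if (frame_energy(frame) == 0) stop("zero-energy frame has no features")
  vals <- stats::setNames(numeric(length(sel)), sel)
  pick <- function(support) sel[endsWith(sel, paste0("_", support))]
  want_psc <- any(sel %in% c("H_Omega", "Halpha_Omega", "Halpha_Pi"))
  if (length(pick("PF")) > 0) {
    f <- stats::setNames(support_features(spectrum_distribution(frame), alpha),
                         support_feature_names("PF"))
    vals[pick("PF")] <- f[pick("PF")]
  }
  if (length(pick("PS")) > 0 || want_psc) {
    S <- spectrogram(frame, window)
    if (length(pick("PS")) > 0) {
      f <- stats::setNames(support_features(tfd_distribution(S), alpha),
                           support_feature_names("PS"))
      vals[pick("PS")] <- f[pick("PS")]
    }
    if (want_psc) {
      dec <- column_stochastic(square_tfd(S))
      if (!isTRUE(dec$converged)) {
        stop("ergodic limit of the column-stochastic decomposition ",
             "did not converge")
      }
      M <- nrow(dec$omega)
      omega_dist <- dec$omega / M
      f <- c(H_Omega = shannon_entropy(omega_dist, normalized = TRUE),
             Halpha_Omega = renyi_entropy(omega_dist, alpha, normalized = TRUE),
             Halpha_Pi = renyi_entropy(dec$pi, alpha, normalized = TRUE))
      keep <- intersect(sel, names(f))
      vals[keep] <- f[keep]
    }
  }
  if (length(pick("PR")) > 0) {
    R <- reassign(frame, window)
    f <- stats::setNames(support_features(tfd_distribution(R), alpha),
                         support_feature_names("PR"))
    vals[pick("PR")] <- f[pick("PR")]
  }
  if (any(!is.finite(vals))) stop("non-finite feature value")
  vals
}

#' Information feature vector of one frame
#'
#' Computes the canonical feature set of a frame: the 9 information
#' characteristics (normalized Shannon and Renyi entropies and the
#' complexities built on the squared-Euclidean, Jensen-Shannon,
#' total-variation and Renyi-Jensen-Shannon disequilibria against the
#' uniform reference) on each of the three supports -- the spectral
#' distribution `P_F`, the spectrogram distribution `P_S` and the reassigned
#' spectrogram distribution `P_R` -- plus, when `config$with_psc`, the
#' normalized entropies `H(Omega)`, `H_a(Omega)`, `H_a(Pi)` of the ergodic
#' pair of the column-stochastic spectrogram (coarse-grained to a square
#' grid first; see [square_tfd()]).  All 30 values are invariant to
#' amplitude scaling of the input.
#'
#' @param frame A [signal_frame()] with non-zero energy, at least one
#'   analysis window long.
#' @param config An [info_config()].
#' @return Named numeric vector in registry order, with attributes
#'   `registry_version` and `frame_label`.
#' @export
feature_vector <- function(frame, config = info_config()) {
  stopifnot(inherits(frame, "signal_frame"), inherits(config, "info_config"))
  vals <- feature_values(frame, config$alpha, config$window,
                         feature_registry(config$with_psc))
  attr(vals, "registry_version") <- FEATURE_REGISTRY_VERSION
  attr(vals, "frame_label") <- frame$label
  vals
}

#' Feature table of a batch of frames
#'
#' One row per frame, columns in registry order, plus a trailing `label`
#' column; the tabular form consumed by external classifiers.
#'
#' @param frames List of [signal_frame()]s, all with the same sample rate.
#' @param config An [info_config()].
#' @param labels Character vector of class labels, recycled over frames;
#'   defaults to each frame's own label.
#' @return A `data.frame`.
#' @export
feature_table <- function(frames, config = info_config(), labels = NULL) {
  if (length(frames) == 0) stop("no frames")
  rates <- vapply(frames, function(f) f$sample_rate, numeric(1))
  if (length(unique(rates)) != 1L) {
    stop("all frames must share one sample rate")
  }
  if (is.null(labels)) {
    labels <- vapply(frames, function(f) f$label, character(1))
  } else {
    labels <- rep_len(as.character(labels), length(frames))
  }
  mat <- t(vapply(frames, function(f) as.numeric(feature_vector(f, config)),
                  numeric(length(feature_registry(config$with_psc)))))
  colnames(mat) <- feature_registry(config$with_psc)
  df <- as.data.frame(mat)
  df$label <- labels
  df
}
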