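#' Construct a discrete probability distribution
#'
#' The common currency of all information measures: a non-negative 1-D or
#' 2-D array of weights summing to one.
#'
#' @param weights Non-negative numeric vector or matrix; normalized to unit
#'   sum if `normalize = TRUE` (the default), otherwise required to sum to 1
#'   within `1e-9`.
#' @param support_kind One of `"spectrum"`, `"tfd_global"`,
#'   `"tfd_reassigned"`, `"column_stochastic_flat"` or `"generic"`.
#' @param normalize Divide by the total weight first?
#' @return An object of class `discrete_distribution` (the weights array with
#'   attributes); it can be used anywhere a plain numeric array is accepted.
#' @export
discrete_distribution <- function(weights, support_kind = "generic",
                                  normalize = TRUE) {
  w <- weights
  if (any(!is.finite(w))) stop("weights must be finite")
  if (any(w < 0)) stop("weights must be non-negative")
  tot <- sum(w)
  if (tot <= 0) stop("weights must have positive total mass")
  if (normalize) {
    w <- w / tot
  } else if (abs(tot - 1) > 1e-9) {
    stop("weights must sum to 1 within 1e-9")
  }
  structure(w, support_kind = support_kind,
            class = c("discrete_distribution", class(w)))
}

# Coerce to a plain numeric vector of probabilities, validating mass.
as_prob <- function(p, require_unit = TRUE) {
  w <- as.numeric(p)
  if (any(!is.finite(w)) || any(w < 0)) {
    stop("distribution weights must be finite and non-negative")
  }
  if (require_unit && abs(sum(w) - 1) > 1e-6) {
    stop("distribution must sum to 1")
  }
  w
}

n_cells <- function(p) length(as.numeric(p))

#' Spectral distribution of a frame
#'
#' The one-sided power spectrum of the whole frame normalized to unit sum
#' (`P_F[i] = F[i] / sum(F)`), the support of all spectral information
#' features.
#'
#' @param frame A [signal_frame()] with non-zero energy.
#' @return A 1-D `discrete_distribution` with `support_kind = "spectrum"`.
#' @export
spectrum_distribution <- function(frame) {
  stopifnot(inherits(frame, "signal_frame"))
  x <- frame$samples
  if (sum(x^2) == 0) stop("all-zero frame has no spectral distribution")
  F <- Mod(stats::fft(x))^2
  F <- F[seq_len(length(x) %/% 2 + 1L)]
  discrete_distribution(F, "spectrum")
}

#' Globally normalized TFD distribution
#'
#' Normalizes a time-frequency energy matrix over all `M * N` cells
#' (`P_S[n,k] = S[n,k] / sum(S)`), giving a 2-D distribution on the grid.
#'
#' @param tfd A `tfd_matrix` (from [spectrogram()] or [reassign()]) with
#'   positive total energy.
#' @return A 2-D `discrete_distribution`; `support_kind` records whether the
#'   input was a plain or a reassigned spectrogram.
#' @export
tfd_distribution <- function(tfd) {
  stopifnot(inherits(tfd, "tfd_matrix"))
  if (sum(tfd$values) <= 0) stop("TFD has zero total energy")
  kind <- if (identical(tfd$kind, "reassigned")) "tfd_reassigned" else "tfd_global"
  discrete_distribution(tfd$values, kind)
}

#' Coarse-grain a TFD to a square grid
#'
#' The column-stochastic construction yields a stochastic matrix (and hence a
#' stationary distribution) only for square TFDs.  A typical spectrogram has
#' more frequency bins than windows (or vice versa); this helper aggregates
#' the longer axis into as many contiguous equal groups as the shorter axis
#' has cells, summing energies, so that `M = N`.
#'
#' @param tfd A `tfd_matrix`.
#' @return A square `tfd_matrix` (energy preserved); grid metadata keeps the
#'   centers of the merged groups.
#' @export
square_tfd <- function(tfd) {
  stopifnot(inherits(tfd, "tfd_matrix"))
  v <- tfd$values
  M <- nrow(v)
  N <- ncol(v)
  if (M == N) return(tfd)
  group_means <- function(axis_vals, g) {
    as.numeric(tapply(axis_vals, g, mean))
  }
  if (N > M) {
    g <- ceiling(seq_len(N) / N * M)
    v2 <- t(rowsum(t(v), group = g))
    new_tfd_matrix(v2, tfd$frame_times, group_means(tfd$bin_freqs, g),
                   tfd$kind, tfd$sample_rate, tfd$window)
  } else {
    g <- ceiling(seq_len(M) / M * N)
    v2 <- rowsum(v, group = g)
    new_tfd_matrix(v2, group_means(tfd$frame_times, g), tfd$bin_freqs,
                   tfd$kind, tfd$sample_rate, tfd$window)
  }
}

#' Column-stochastic decomposition of a TFD
#'
#' Normalizes each analysis window's spectrum to unit sum and divides by the
#' number of windows: `P_SC[n,k] = (1/M) * S[n,k] / sum_k S[n,k]`, so the
#' whole matrix sums to one while `M * P_SC` is a right stochastic matrix
#' (unit row sums).  For square TFDs the ergodic limit of the stochastic
#' matrix is computed: its powers converge to a rank-one matrix whose rows
#' all equal the stationary vector `Pi`.
#'
#' An additive floor of `1e-300` is applied before normalization so that
#' all-but-zero cells never produce `0/0`; a window with no energy at all is
#' an error naming the window.
#'
#' @param tfd A `tfd_matrix`.
#' @param tol,max_iter Convergence control passed to [ergodic_limit()] when
#'   the matrix is square.
#' @return An object of class `stochastic_decomposition`: list with `psc`,
#'   `row_stochastic` (`= M * psc`), and, when square, `omega`, `pi`,
#'   `converged`, `iterations` (otherwise `NULL` / `NA`).
#' @export
column_stochastic <- function(tfd, tol = 1e-12, max_iter = 100000L) {
  stopifnot(inherits(tfd, "tfd_matrix"))
  v <- tfd$values + 1e-300
  row_tot <- rowSums(v)
  bad <- which(!(row_tot > 0))
  if (length(bad) > 0) {
    stop(sprintf("window %d has zero energy; no column-stochastic form",
                 bad[1]))
  }
  M <- nrow(v)
  A <- v / row_tot                   # right stochastic: unit row sums
  psc <- A / M
  res <- list(psc = psc, row_stochastic = A,
              omega = NULL, pi = NULL, converged = NA, iterations = NA_integer_)
  if (M == ncol(v)) {
    el <- ergodic_limit(A, tol = tol, max_iter = max_iter)
    res$omega <- el$omega
    res$pi <- el$pi
    res$converged <- el$converged
    res$iterations <- el$iterations
  }
  structure(res, class = "stochastic_decomposition")
}

#' @export
print.stochastic_decomposition <- function(x, ...) {
  cat(sprintf("<stochastic_decomposition> %d x %d%s\n",
              nrow(x$psc), ncol(x$psc),
              if (isTRUE(x$converged)) {
                sprintf(", ergodic limit converged in %d iterations",
                        x$iterations)
              } else ""))
  invisible(x)
}

#' Ergodic limit of a right stochastic matrix
#'
#' Power iteration for the stationary vector `pi` with `pi %*% A = pi`,
#' starting from the uniform vector; the limit matrix `Omega = lim A^j` has
#' every row equal to `pi` when the chain is regular.  Periodic or reducible
#' matrices (e.g. the identity, a permutation) do not converge and are
#' reported as such.
#'
#' @param A Square matrix with non-negative entries and unit row sums
#'   (within `1e-9`).
#' @param tol L1 convergence tolerance on successive iterates.
#' @param max_iter Iteration cap.
#' @return List with `omega` (matrix of identical rows), `pi`, `converged`
#'   flag and `iterations` used.
#' @export
ergodic_limit <- function(A, tol = 1e-12, max_iter = 100000L) {
  A <- as.matrix(A)
  M <- nrow(A)
  if (ncol(A) != M) stop("A must be square")
  if (any(A < 0) || any(abs(rowSums(A) - 1) > 1e-9)) {
    stop("A must be right stochastic (non-negative, unit row sums)")
  }
  iterate <- function(p) {
    it <- 0L
    while (it < max_iter) {
      it <- it + 1L
      p_new <- as.numeric(p %*% A)
      p_new <- p_new / sum(p_new)
      if (sum(abs(p_new - p)) < tol) {
        return(list(p = p_new, converged = TRUE, iterations = it))
      }
      p <- p_new
    }
    list(p = p, converged = FALSE, iterations = it)
  }
  # a fixed point of one start is not evidence of regularity (the identity
  # matrix fixes every vector); require two distinct starts to agree
  r1 <- iterate(rep(1 / M, M))
  start2 <- rep(1 / M, M)
  start2[1] <- start2[1] + 1
  r2 <- iterate(start2 / sum(start2))
  converged <- r1$converged && r2$converged &&
    sum(abs(r1$p - r2$p)) < max(1e-8, 100 * tol)
  list(omega = matrix(r1$p, M, M, byrow = TRUE), pi = r1$p,
       converged = converged, iterations = max(r1$iterations, r2$iterations))
}

#' Entropy identities of the ergodic decomposition
#'
#' For a converged decomposition, the entropies of the limit matrix `Omega`
#' (renormalized by `1/M` to a distribution on `M^2` cells) and the
#' stationary vector `Pi` are tied together:
#' normalized Shannon `H(Omega/M) = (1 + H_norm(Pi)) / 2`, and unnormalized
#' Renyi `H_a(Omega/M) = log2(M) + H_a(Pi)`; the Renyi maximum over this
#' family is `2 * log2(M)`, attained at uniform `Pi`.  Returns the two
#' absolute residuals, both of which vanish (to numerical precision) for any
#' converged decomposition.
#'
#' @param decomp A converged `stochastic_decomposition` (square TFD).
#' @param alpha Renyi order.
#' @return Named numeric vector `c(shannon = ..., renyi = ...)` of absolute
#'   identity residuals.
#' @export
entropy_identity_check <- function(decomp, alpha = 3) {
  stopifnot(inherits(decomp, "stochastic_decomposition"))
  if (!isTRUE(decomp$converged)) {
    stop("decomposition did not converge; identities hold only in the limit")
  }
  M <- nrow(decomp$omega)
  omega_dist <- decomp$omega / M
  h_omega <- shannon_entropy(omega_dist, normalized = TRUE)
  h_pi <- shannon_entropy(decomp$pi, normalized = TRUE)
  r_shannon <- abs(h_omega - 0.5 * (1 + h_pi))
  ha_omega <- renyi_entropy(omega_dist, alpha)
  ha_pi <- renyi_entropy(decomp$pi, alpha)
  r_renyi <- abs(ha_omega - (log2(M) + ha_pi))
  c(shannon = r_shannon, renyi = r_renyi)
}
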