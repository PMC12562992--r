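#' Shannon entropy of a discrete distribution
#'
#' `H(P) = -sum p * log2(p)` in bits, with the `0 * log2(0) = 0` convention.
#' With `normalized = TRUE` the value is divided by `log2(#cells)` (for a
#' 2-D support, the number of cells is `M * N`), mapping it to `[0, 1]`.
#'
#' @param p Distribution: numeric vector or matrix summing to 1 (or a
#'   [discrete_distribution()]).
#' @param normalized Divide by the maximum entropy `log2(#cells)`?
#' @return Entropy in bits (dimensionless if normalized).
#' @export
shannon_entropy <- function(p, normalized = FALSE) {
  w <- as_prob(p)
  pos <- w > 0
  h <- -sum(w[pos] * log2(w[pos]))
  if (normalized) h <- h / log2(length(w))
  h
}

#' Renyi entropy of order alpha
#'
#' `H_a(P) = log2(sum p^a) / (1 - a)` in bits, `a > 0`, `a != 1`; the
#' Shannon entropy is the `a -> 1` limit (use [shannon_entropy()] for it).
#' Larger orders emphasise the peaks of the distribution.
#'
#' @inheritParams shannon_entropy
#' @param alpha Entropy order (`> 0`, `!= 1`).
#' @return Entropy in bits.
#' @export
renyi_entropy <- function(p, alpha, normalized = FALSE) {
  check_alpha(alpha)
  w <- as_prob(p)
  h <- log2(sum(w[w > 0]^alpha)) / (1 - alpha)
  if (normalized) h <- h / log2(length(w))
  h
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0) {
    stop("alpha must be a single positive number")
  }
  if (alpha == 1) {
    stop("alpha = 1 is the Shannon limit; call shannon_entropy()")
  }
  invisible(alpha)
}

uniform_reference <- function(p) rep(1 / n_cells(p), n_cells(p))

check_support <- function(p, q) {
  if (n_cells(p) != n_cells(q)) {
    stop("distributions must share a support (same number of cells)")
  }
}

#' Euclidean (squared-distance) disequilibrium
#'
#' `D_SQ(P, Q) = sum (p_i - q_i)^2`.  Against the uniform reference this
#' reduces to the identity `sum p^2 - 1/N`.
#'
#' @inheritParams shannon_entropy
#' @param q Reference distribution; `NULL` (default) for uniform on the same
#'   support.
#' @return Non-negative dimensionless value.
#' @export
disequilibrium_sq <- function(p, q = NULL) {
  w <- as_prob(p)
  v <- if (is.null(q)) uniform_reference(w) else as_prob(q)
  check_support(w, v)
  sum((w - v)^2)
}

#' Jensen-Shannon divergence
#'
#' `JSD(P, Q) = H(m) - (H(P) + H(Q)) / 2` with `m = (P + Q) / 2`, using
#' unnormalized Shannon entropies; symmetric, bounded by 1 bit.
#'
#' @inheritParams disequilibrium_sq
#' @return Divergence in bits, in `[0, 1]`.
#' @export
jsd <- function(p, q = NULL) {
  w <- as_prob(p)
  v <- if (is.null(q)) uniform_reference(w) else as_prob(q)
  check_support(w, v)
  m <- (w + v) / 2
  shannon_entropy(m) - (shannon_entropy(w) + shannon_entropy(v)) / 2
}

#' Squared total-variation disequilibrium
#'
#' `D_TV(P, Q) = (1/4) * (sum |p_i - q_i|)^2`, i.e. the square of the
#' total-variation distance `TV = (1/2) sum |p - q|`, scaled to `[0, 1]`
#' (the maximum 1 is attained by disjoint point masses).
#'
#' @inheritParams disequilibrium_sq
#' @return Dimensionless value in `[0, 1]`.
#' @export
disequilibrium_tv <- function(p, q = NULL) {
  w <- as_prob(p)
  v <- if (is.null(q)) uniform_reference(w) else as_prob(q)
  check_support(w, v)
  0.25 * sum(abs(w - v))^2
}

#' Renyi divergence
#'
#' `D_a(P, Q) = log2(sum p^a * q^(1-a)) / (a - 1)`; the Kullback-Leibler
#' divergence is its `a -> 1` limit.  Against a uniform reference on `N`
#' cells it satisfies the identity `D_a(P, U) = log2(N) - H_a(P)`.  If `P`
#' puts mass where `Q` has none and `a > 1`, the divergence is infinite and
#' `Inf` is returned.
#'
#' @inheritParams disequilibrium_sq
#' @param alpha Divergence order (`> 0`, `!= 1`).
#' @param symmetrized Also add `D_a(Q, P)`?
#' @return Divergence in bits (possibly `Inf`).
#' @export
renyi_divergence <- function(p, q = NULL, alpha = 3, symmetrized = FALSE) {
  check_alpha(alpha)
  w <- as_prob(p)
  v <- if (is.null(q)) uniform_reference(w) else as_prob(q)
  check_support(w, v)
  one_way <- function(a, b) {
    if (alpha > 1 && any(a > 0 & b == 0)) return(Inf)
    s <- a > 0 & b > 0
    log2(sum(a[s]^alpha * b[s]^(1 - alpha))) / (alpha - 1)
  }
  d <- one_way(w, v)
  if (symmetrized) d <- d + one_way(v, w)
  d
}

#' Geometric-mean Renyi-Jensen-Shannon divergence
#'
#' The Jensen-Shannon analogue for Renyi entropies of (possibly
#' inconsistent) time-frequency distributions,
#' `J_a(P, Q) = H_a(PQ) - (H_a(P) + H_a(Q)) / 2`,
#' where the combined term uses the element-wise geometric mean:
#' `H_a(PQ) = log2(sum (p_i * q_i)^(a/2)) / (1 - a)`.  The combined array
#' `sqrt(p * q)` need not sum to one, which is exactly the situation the
#' construction is designed for.  For `a > 1` the divergence is guaranteed
#' non-negative (a Cauchy-Schwarz consequence), with equality iff `P = Q`;
#' other orders are allowed but carry no sign guarantee.
#'
#' @inheritParams disequilibrium_sq
#' @param alpha Order (`> 0`, `!= 1`; `> 1` for the guaranteed-sign regime).
#' @return Divergence in bits.
#' @export
renyi_jsd <- function(p, q = NULL, alpha = 3) {
  check_alpha(alpha)
  w <- as_prob(p)
  v <- if (is.null(q)) uniform_reference(w) else as_prob(q)
  check_support(w, v)
  s <- w > 0 & v > 0
  h_pq <- log2(sum((w[s] * v[s])^(alpha / 2))) / (1 - alpha)
  h_pq - (renyi_entropy(w, alpha) + renyi_entropy(v, alpha)) / 2
}

#' Quadratic (second-order) approximation of the Renyi-Jensen-Shannon
#' divergence
#'
#' For a small signed perturbation `delta_rho` (summing to zero) of a base
#' distribution `P`, the divergence `J_a(P, P + delta_rho)` is, to second
#' order,
#' `-(1/4) * sum (dH_a/dp_i) * delta_rho_i^2 / d_i`,
#' with gradient `dH_a/dp_i = (a / (1 - a)) * p_i^(a-1) / (ln(2) * sum p^a)`.
#' The divisor `d_i` is taken from the base distribution
#' (`denominator = "base"`, the formula as stated) or from the perturbed one
#' (`denominator = "perturbed"`); the two agree to leading order and both
#' are provided.
#'
#' @param p Base distribution.
#' @param delta_rho Signed perturbation, same length as `p`, summing to 0;
#'   `p + delta_rho` must be a valid distribution.
#' @param alpha Order (`> 0`, `!= 1`).
#' @param denominator `"perturbed"` or `"base"`.
#' @return Approximate divergence in bits.
#' @export
renyi_jsd_quadratic <- function(p, delta_rho, alpha = 3,
                                denominator = c("perturbed", "base")) {
  denominator <- match.arg(denominator)
  check_alpha(alpha)
  w <- as_prob(p)
  dr <- as.numeric(delta_rho)
  if (length(dr) != length(w)) stop("delta_rho must match p in length")
  if (abs(sum(dr)) > 1e-9) stop("delta_rho must sum to 0")
  v <- w + dr
  if (any(v < -1e-12)) stop("p + delta_rho must be non-negative")
  d <- if (denominator == "base") w else v
  active <- dr != 0
  if (any(active & d <= 0)) {
    stop("zero denominator on the support of delta_rho")
  }
  grad <- (alpha / (1 - alpha)) * w^(alpha - 1) / (log(2) * sum(w^alpha))
  s <- active
  -0.25 * sum(grad[s] * dr[s]^2 / d[s])
}

#' Statistical complexity of a distribution
#'
#' The product `C(P) = H(P) * D(P, Q)` of a normalized entropy and a
#' disequilibrium from the reference `Q` (uniform by default, the spectral
#' signature of white noise).  Complexity vanishes both for fully ordered
#' distributions (point mass, `H = 0`) and for fully uniform ones
#' (`D = 0`), and so picks out structured distributions between the two
#' extremes.  Valid combinations:
#' Shannon entropy with `"sq"`, `"jsd"` or `"tv"`;
#' Renyi entropy with `"sq"`, `"jsd"`, `"tv"` or `"renyi_jsd"` (the latter
#' pairs the order-`a` entropy with the order-`a` divergence).
#' The `"tv"` disequilibrium carries its `1/4` scale; `"jsd"` enters in bits
#' without further scaling (its 1-bit bound keeps the product bounded).
#'
#' @inheritParams disequilibrium_sq
#' @param entropy_kind `"shannon"` or `"renyi"`.
#' @param diseq_kind `"sq"`, `"jsd"`, `"tv"` or `"renyi_jsd"`.
#' @param alpha Renyi order for the Renyi entropy / divergence.
#' @return Dimensionless complexity value.
#' @export
complexity <- function(p, entropy_kind = c("shannon", "renyi"),
                       diseq_kind = c("sq", "jsd", "tv", "renyi_jsd"),
                       alpha = 3, q = NULL) {
  entropy_kind <- match.arg(entropy_kind)
  diseq_kind <- match.arg(diseq_kind)
  if (diseq_kind == "renyi_jsd" && entropy_kind != "renyi") {
    stop("the renyi_jsd disequilibrium pairs only with the renyi entropy; ",
         "valid combinations: shannon x {sq, jsd, tv}, ",
         "renyi x {sq, jsd, tv, renyi_jsd}")
  }
  h <- if (entropy_kind == "shannon") {
    shannon_entropy(p, normalized = TRUE)
  } else {
    renyi_entropy(p, alpha, normalized = TRUE)
  }
  d <- switch(diseq_kind,
    sq = disequilibrium_sq(p, q),
    jsd = jsd(p, q),
    tv = disequilibrium_tv(p, q),
    renyi_jsd = renyi_jsd(p, q, alpha)
  )
  h * d
}
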