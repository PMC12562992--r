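test_that("Shannon and Renyi entropies match closed forms and limits", {
  expect_equal(shannon_entropy(rep(1 / 8, 8)), 3)
  expect_equal(shannon_entropy(rep(1 / 8, 8), normalized = TRUE), 1)
  expect_equal(shannon_entropy(c(1, 0, 0)), 0)
  expect_equal(shannon_entropy(c(1/2, 1/4, 1/4)), 1.5)

  expect_equal(renyi_entropy(rep(1 / 3, 3), 2), log2(3), tolerance = 1e-12)
  expect_equal(renyi_entropy(c(1/4, 1/4, 1/2), 2), 3 - log2(3),
               tolerance = 1e-12)
  expect_error(renyi_entropy(c(0.5, 0.5), 1), "Shannon")

  set.seed(71)
  p <- rand_dist(40)
  expect_equal(renyi_entropy(p, 1 + 1e-6), shannon_entropy(p),
               tolerance = 1e-4)
  expect_equal(renyi_entropy(p, 1 - 1e-6), shannon_entropy(p),
               tolerance = 1e-4)

  # Renyi entropy is non-increasing in the order
  h <- vapply(c(0.5, 0.9, 1.5, 2, 3, 5, 10), function(a) renyi_entropy(p, a),
              numeric(1))
  expect_true(all(diff(h) <= 1e-12))
})

test_that("disequilibria match their algebraic identities and bounds", {
  n <- 16
  u <- rep(1 / n, n)
  expect_equal(disequilibrium_sq(u), 0)
  pm <- c(1, rep(0, n - 1))
  expect_equal(disequilibrium_sq(pm), 1 - 1 / n, tolerance = 1e-12)
  set.seed(72)
  p <- rand_dist(n)
  expect_equal(disequilibrium_sq(p), sum(p^2) - 1 / n, tolerance = 1e-12)

  expect_equal(jsd(p, p), 0)
  expect_equal(jsd(c(1, 0), c(0, 1)), 1)
  q <- rand_dist(n)
  expect_equal(jsd(p, q), jsd(q, p), tolerance = 1e-12)
  expect_gte(jsd(p, q), 0)
  expect_lte(jsd(p, q), 1)

  expect_equal(disequilibrium_tv(p, p), 0)
  expect_equal(disequilibrium_tv(c(1, 0), c(0, 1)), 1)
  expect_gte(disequilibrium_tv(p, q), 0)
  expect_lte(disequilibrium_tv(p, q), 1)
})

test_that("Renyi divergence obeys the uniform-reference identity", {
  set.seed(73)
  p <- rand_dist(50)
  expect_equal(renyi_divergence(p, p, alpha = 3), 0, tolerance = 1e-12)
  # D_a(P, U) = log2(N) - H_a(P)
  expect_equal(renyi_divergence(p, alpha = 3),
               log2(50) - renyi_entropy(p, 3), tolerance = 1e-12)
  # symmetrized divergence against uniform, derived closed form
  for (a in c(0.3, 0.6, 0.9)) {
    pred <- log2(50) / (1 - a) - renyi_entropy(p, a) -
      (a / (1 - a)) * renyi_entropy(p, 1 - a)
    expect_equal(renyi_divergence(p, alpha = a, symmetrized = TRUE), pred,
                 tolerance = 1e-10)
  }
  # absolute continuity failure at alpha > 1 is infinite
  expect_identical(renyi_divergence(c(0.5, 0.5), c(1, 0), alpha = 2), Inf)
})

test_that("geometric-mean Renyi-JSD reproduces the three-cell worked case
           and is non-negative for alpha > 1", {
  P <- rep(1 / 3, 3)
  Q <- c(1/4, 1/4, 1/2)
  expect_equal(renyi_jsd(P, Q, alpha = 2), log(3) / log(2) - 3 / 2,
               tolerance = 1e-12)
  expect_equal(renyi_jsd(P, P, alpha = 2), 0, tolerance = 1e-12)
  set.seed(74)
  for (i in 1:50) {
    p <- rand_dist(12)
    q <- rand_dist(12)
    expect_gte(renyi_jsd(p, q, alpha = 2), 0)
    expect_gte(renyi_jsd(p, q, alpha = 3), 0)
  }
})

test_that("quadratic approximation matches both denominator conventions and
           its error is o(eps^2)", {
  P <- rep(1 / 3, 3)
  dr <- c(-1/12, -1/12, 1/6)
  expect_equal(renyi_jsd_quadratic(P, dr, 2, "perturbed"), 1 / (18 * log(2)),
               tolerance = 1e-12)
  expect_equal(renyi_jsd_quadratic(P, dr, 2, "base"), 1 / (16 * log(2)),
               tolerance = 1e-12)

  # |J - quadratic| / eps^2 vanishes as the perturbation shrinks in the
  # regime of the worked case (order 2, uniform base), where the printed
  # gradient form captures the full second order
  set.seed(75)
  p <- rep(1 / 10, 10)
  d0 <- rand_dist(10) - rand_dist(10)
  ratios <- vapply(c(1e-2, 1e-3, 1e-4), function(eps) {
    dr <- eps * d0
    abs(renyi_jsd(p, p + dr, 2) - renyi_jsd_quadratic(p, dr, 2, "base")) /
      eps^2
  }, numeric(1))
  expect_true(all(diff(ratios) < 0))
  expect_lt(ratios[3], ratios[1] / 50)
})

test_that("complexity multiplies normalized entropy and disequilibrium", {
  u <- rep(1 / 9, 9)
  expect_equal(complexity(u, "shannon", "sq"), 0, tolerance = 1e-12)
  pm <- c(1, rep(0, 8))
  expect_equal(complexity(pm, "shannon", "jsd"), 0)

  p <- c(1/2, 1/4, 1/4)
  expect_equal(complexity(p, "shannon", "sq"),
               (1.5 / log2(3)) * (sum(p^2) - 1 / 3), tolerance = 1e-12)

  expect_error(complexity(p, "shannon", "renyi_jsd"), "valid combinations")
})
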