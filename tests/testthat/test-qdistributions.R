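test_that("q-exponential has the closed form and classical limit", {
  expect_identical(q_exponential(0, 1.3), 1)
  expect_equal(q_exponential(1, 1.5), 1.5^-2)
  expect_equal(q_exponential(2, 1 + 1e-8), exp(-2), tolerance = 1e-6)
  expect_equal(q_exponential(0.7, 1), exp(-0.7))
  expect_error(q_exponential(1, 0.9), class = "superexon_unsupported_regime")
})

test_that("constrained pdfs integrate to one across a parameter grid", {
  for (a in c(-0.5, 0.5, 2))
    for (q in c(1.05, 1.15))
      for (sigma in c(12, 500)) {
        p <- qgamma_params(a, sigma, q)
        expect_equal(integrate(function(l) dqgamma(l, p), 0, Inf,
                               rel.tol = 1e-10)$value, 1, tolerance = 1e-6)
      }
  for (alpha in c(0.5, 1.2, 3))
    for (q in c(1.05, 1.12)) {
      p <- invqgamma_params(alpha, 222, q)
      expect_equal(integrate(function(l) dinvqgamma(l, p), 0, Inf,
                             rel.tol = 1e-10)$value, 1, tolerance = 1e-6)
    }
})

test_that("normalizability violations are validity errors", {
  # 1/(q-1) - a - 1 = -0.1  =>  a = 1/(q-1) - 0.9
  q <- 1.2
  expect_error(qgamma_params(1 / (q - 1) - 0.9, 50, q),
               class = "superexon_validity_error")
  expect_error(invqgamma_params(1 / (q - 1) - 0.9, 50, q),
               class = "superexon_validity_error")
  expect_error(qgamma_params(2, -1, 1.1), class = "superexon_validity_error")
})

test_that("q -> 1 recovers the classical gamma and inverse gamma", {
  l <- seq(0.5, 3000, by = 0.5)
  a <- 2; sigma <- 50
  for (eps in c(1e-3, 1e-5)) {
    p <- qgamma_params(a, sigma, 1 + eps)
    ref <- dgamma(l, shape = a + 1, scale = sigma)
    expect_lt(max(abs(dqgamma(l, p) - ref)), 50 * eps)
  }
  alpha <- 1.2; sigma <- 250
  p <- invqgamma_params(alpha, sigma, 1 + 1e-5)
  # classical limit: standard InvGamma(shape alpha+1, scale sigma)
  ref <- exp((alpha + 1) * log(sigma) - lgamma(alpha + 1) -
               (alpha + 2) * log(l) - sigma / l)
  expect_lt(max(abs(dinvqgamma(l, p) - ref)), 1e-2)
})

test_that("closed-form marginals equal quadrature of the mixture integral", {
  ls <- exp(seq(log(2), log(2e4), length.out = 50))
  for (k in c(0.5, 1.5)) for (mu in c(5, 15)) {
    omega <- 4000
    p <- qgamma_from_mixture(k, mu, omega)
    quad <- mixture_marginal_quadrature(
      ls, list(family = "gamma", k = k),
      list(family = "inverse_gamma", mu = mu, omega = omega))
    expect_lt(max(abs(quad - dqgamma(ls, p)) / dqgamma(ls, p)), 1e-8)
  }
  for (alpha in c(0.6, 1.2)) for (delta in c(6, 18)) {
    omega <- 18
    p <- invqgamma_from_mixture(alpha, delta, omega)
    quad <- mixture_marginal_quadrature(
      ls, list(family = "inverse_gamma", alpha = alpha),
      list(family = "gamma", delta = delta, omega = omega))
    expect_lt(max(abs(quad - dinvqgamma(ls, p)) / dinvqgamma(ls, p)), 1e-8)
  }
})

test_that("mixture and marginal parametrizations invert each other", {
  p <- qgamma_from_mixture(0.5, 15, 4000)
  m <- mixture_from_marginal(p)
  expect_equal(unlist(m), c(k = 0.5, mu = 15, omega = 4000))
  p2 <- invqgamma_from_mixture(1.2, 18, 18)
  m2 <- mixture_from_marginal(p2)
  expect_equal(unlist(m2), c(alpha = 1.2, delta = 18, omega = 18))
})

test_that("a sharply peaked mixing law collapses to the local family", {
  # mixing shape -> infinity at fixed mean: q -> 1 and marginal -> local
  k <- 1.5; mean_xi <- 300
  for (mu in c(10, 100, 1000)) {
    p <- qgamma_from_mixture(k, mu, omega = mean_xi * (mu - 1))
    expect_equal(p$q, 1 + 1 / (k + mu))
  }
  p_big <- qgamma_from_mixture(k, 1e5, omega = mean_xi * (1e5 - 1))
  l <- seq(1, 3000, by = 1)
  expect_lt(max(abs(dqgamma(l, p_big) - dlocal_gamma(l, k, mean_xi))), 1e-4)
})

test_that("tails behave: power-law decay, heavier than classical gamma", {
  p <- qgamma_params(2, 50, 1.15)
  l <- exp(seq(log(1e3), log(1e6), length.out = 40))
  log_ratio <- dqgamma(l, p, log = TRUE) - dgamma(l, shape = 3, scale = 50, log = TRUE)
  expect_true(all(diff(log_ratio) > 0))  # q-Gamma tail dominates gamma
  pig <- invqgamma_params(1.2, 250, 1.1)
  d <- dinvqgamma(l, pig)
  expect_true(all(diff(d) < 0))  # eventually decreasing
  slope <- diff(log(d)) / diff(log(l))
  expect_equal(slope[length(slope)], -(1.2 + 2), tolerance = 0.01)
})

test_that("the exact sampler reproduces the analytic law", {
  p <- qgamma_params(2.99, 12.29, 1.17)
  x <- sample_marginal(p, 1e5, seed = 8)
  expect_identical(sample_marginal(p, 1e5, seed = 8), x)
  expect_error(sample_marginal(p, 0), class = "superexon_validity_error")
  # KS against the quadrature CDF, interpolated on a dense log grid
  grid <- exp(seq(log(min(x)) - 1e-9, log(max(x)) + 1e-9, length.out = 3000))
  cdf <- approxfun(grid, qfamily_cdf(grid, p), yleft = 0, yright = 1)
  ks <- ks.test(x, cdf)
  expect_gt(ks$p.value, 0.01)
})

test_that("LM fitting recovers the entropic index from sampled densities", {
  p <- qgamma_params(2.99, 12.29, 1.17)
  f <- fit_marginal(binned_density(sample_marginal(p, 1e5, seed = 14)), "q_gamma")
  expect_equal(f$params$q, 1.17, tolerance = 0.02 / 1.17)
  pig <- invqgamma_params(0.52, 222.67, 1.10)
  f2 <- fit_marginal(binned_density(sample_marginal(pig, 1e5, seed = 15)),
                     "inv_q_gamma")
  expect_equal(f2$params$q, 1.10, tolerance = 0.02 / 1.10)
  expect_error(fit_marginal(binned_density(c(10, 30, 30, 80)), "q_gamma"),
               class = "superexon_validation_error")
})

test_that("A_free mode fits the normalization as a fourth parameter", {
  p <- qgamma_params(2.99, 12.29, 1.17)
  d <- binned_density(sample_marginal(p, 5e4, seed = 16))
  f <- fit_marginal(d, "q_gamma", mode = "A_free")
  expect_false(f$params$constrained)
  expect_equal(f$params$A, qgamma_norm(f$params$a, f$params$sigma, f$params$q),
               tolerance = 0.25)
})
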