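# parameter sets exercised throughout: the four two-parameter laws used
# in the simulation studies
param_grid <- list(c(1, 1), c(1, 0.5), c(7, 1), c(3, 3))

test_that("density matches the closed form and normalizes", {
  # at x = mu the exponent vanishes, leaving sqrt(lambda / (2 pi mu^3))
  expect_equal(dinvgauss(1, 1, 1), 1 / sqrt(2 * pi))
  expect_equal(dinvgauss(3, 3, 3), sqrt(3 / (2 * pi * 27)))
  for (p in param_grid) {
    total <- integrate(dinvgauss, 0, Inf, mu = p[1], lambda = p[2],
                       rel.tol = 1e-12)$value
    expect_equal(total, 1, tolerance = 1e-9)
  }
  # mean of IG(3,3) by quadrature
  m <- integrate(function(x) x * dinvgauss(x, 3, 3), 0, Inf, rel.tol = 1e-12)$value
  expect_equal(m, 3, tolerance = 1e-8)
  expect_equal(dinvgauss(c(-1, 0), 1, 1), c(0, 0))
  expect_error(dinvgauss(1, -1, 1), "mu")
})

test_that("cdf agrees with quadrature of the density", {
  for (p in param_grid) {
    for (x in c(0.2, 1, 2.5, 8)) {
      ref <- integrate(dinvgauss, 0, x, mu = p[1], lambda = p[2],
                       rel.tol = 1e-13, abs.tol = 1e-14)$value
      expect_equal(pinvgauss(x, p[1], p[2]), ref, tolerance = 1e-10)
    }
  }
  # limits and monotonicity
  expect_equal(pinvgauss(Inf, 1, 1), 1)
  expect_equal(pinvgauss(0, 1, 1), 0)
  xs <- seq(0.01, 20, length.out = 200)
  expect_true(all(diff(pinvgauss(xs, 1, 0.5)) >= 0))
  # log-scale second term: large lambda/mu must not overflow
  expect_true(is.finite(pinvgauss(0.5, 1, 800)))
})

test_that("quantile function inverts the cdf", {
  expect_equal(pinvgauss(qinvgauss(0.3, 7, 1), 7, 1), 0.3, tolerance = 1e-10)
  expect_equal(qinvgauss(pinvgauss(2.5, 3, 3), 3, 3), 2.5, tolerance = 1e-8)
  for (p in param_grid) {
    xs <- seq(qinvgauss(1e-4, p[1], p[2]), qinvgauss(1 - 1e-4, p[1], p[2]),
              length.out = 100)
    expect_equal(qinvgauss(pinvgauss(xs, p[1], p[2]), p[1], p[2]), xs,
                 tolerance = 1e-8)
  }
  # strictly increasing in prob, decreasing toward the support boundary
  q <- qinvgauss(c(1e-6, 1e-4, 0.01, 0.5, 0.99), 1, 1)
  expect_true(all(diff(q) > 0))
  expect_lt(q[1], 0.05)
  expect_error(qinvgauss(0, 1, 1), "strictly inside")
  expect_error(qinvgauss(1, 1, 1), "strictly inside")
})

test_that("closed-form moments match numerical integrals of the density", {
  for (p in param_grid) {
    mom <- ig_moments(p[1], p[2])
    m1 <- integrate(function(x) x * dinvgauss(x, p[1], p[2]), 0, Inf,
                    rel.tol = 1e-12)$value
    cm <- vapply(2:4, function(r)
      integrate(function(x) (x - m1)^r * dinvgauss(x, p[1], p[2]), 0, Inf,
                rel.tol = 1e-12)$value, numeric(1))
    expect_equal(unname(mom), c(m1, cm[1], cm[2] / cm[1]^1.5, cm[3] / cm[1]^2 - 3),
                 tolerance = 1e-8)
  }
  expect_equal(unname(ig_moments(1, 1)), c(1, 1, 3, 15))
  expect_equal(unname(ig_moments(7, 1)), c(7, 343, 3 * sqrt(7), 105))
})

test_that("random variates are reproducible and follow the law", {
  expect_identical(rinvgauss(100, 1, 1, seed = 11), rinvgauss(100, 1, 1, seed = 11))
  x <- rinvgauss(1e5, 1, 1, seed = 42)
  expect_lt(abs(mean(x) - 1), 4 * sqrt(1 / 1e5))
  # one-sample distribution test against the cdf (independent oracle)
  ks <- suppressWarnings(ks.test(x, function(q) pinvgauss(q, 1, 1)))
  expect_gt(ks$p.value, 0.001)
  # sampling property of the mean: Var(xbar) ~ mu^3 / (lambda n)
  n <- 50
  means <- vapply(seq_len(200), function(i)
    mean(rinvgauss(n, 1, 1, seed = 1000 + i)), numeric(1))
  expect_lt(abs(var(means) / (1 / n) - 1), 0.2)
})

test_that("shifted model is an exact translation", {
  expect_equal(dinvgauss(1.5, 1, 1, shift = 0.5), dinvgauss(1, 1, 1))
  expect_equal(dinvgauss(2, 1, 0.5, shift = 0), dinvgauss(2, 1, 0.5))
  expect_equal(dinvgauss(0.4, 1, 1, shift = 0.5), 0)  # below the shift
  tot <- integrate(dinvgauss, 0.5, Inf, mu = 1, lambda = 1, shift = 0.5,
                   rel.tol = 1e-12)$value
  expect_equal(tot, 1, tolerance = 1e-9)
  expect_equal(pinvgauss(2.5, 3, 3, shift = 1), pinvgauss(1.5, 3, 3))
  expect_equal(qinvgauss(0.3, 1, 1, shift = 2), qinvgauss(0.3, 1, 1) + 2)
})

test_that("log-likelihood identities hold and the case-study value reproduces", {
  x <- jug_bridge_runoff()
  expect_equal(round(ig_loglik(x, 0.8032, 1.4397), 4), -14.3916)
  expect_equal(ig_loglik(x, 1.2, 0.7),
               sum(log(dinvgauss(x, 1.2, 0.7))))
  # shifted likelihood with alpha = 0 reduces to the plain one
  expect_equal(ig_loglik(x, 0.8, 1.4, shift = 0), ig_loglik(x, 0.8, 1.4))
  y <- x + 0.5
  expect_equal(ig_loglik(y, 0.8, 1.4, shift = 0.5), ig_loglik(x, 0.8, 1.4))
  # the sum(log(x_i - alpha)) term blows up toward min(x)
  lls <- vapply(c(0.1, 0.15, 0.1699), function(a)
    ig_loglik(x, 0.8, 1.4, shift = a), numeric(1))
  expect_error(ig_loglik(x, 0.8, 1.4, shift = min(x)), "exceed")
  expect_error(ig_loglik(c(1, -1), 1, 1), "positive|exceed")
})

test_that("analytic MLE and UMVUE match their closed forms", {
  x <- jug_bridge_runoff()
  est <- ig_mle(x)
  expect_equal(round(unname(est), 4), c(0.8032, 1.4397))
  expect_error(ig_mle(c(2, 2)), "degenerate")
  # estimates land near the truth on a large sample
  y <- rinvgauss(1e5, 3, 3, seed = 5)
  est2 <- ig_mle(y)
  se_mu <- sqrt(27 / 3 / 1e5)
  se_lam <- 3 * sqrt(2 / 1e5)
  expect_lt(abs(est2["mu"] - 3), 3 * se_mu)
  expect_lt(abs(est2["lambda"] - 3), 3 * se_lam)
  # UMVUE shape relation is exact algebra
  u <- ig_umvue(x)
  expect_equal(unname(u["lambda"] / est["lambda"]), (25 - 3) / 25)
  expect_silent(ig_umvue(c(0.5, 1, 1.5, 2)))   # minimal n = 4
  expect_error(ig_umvue(c(1, 2, 3)), "length >= 4")
})

test_that("the analytic MLE maximizes the log-likelihood", {
  x <- rinvgauss(40, 1, 0.5, seed = 9)
  est <- ig_mle(x)
  ll0 <- ig_loglik(x, est["mu"], est["lambda"])
  set.seed(77)
  for (i in seq_len(1000)) {
    mu <- est["mu"] * exp(runif(1, -1, 1))
    lam <- est["lambda"] * exp(runif(1, -1, 1))
    expect_lte(ig_loglik(x, mu, lam), ll0 + 1e-10)
  }
})
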