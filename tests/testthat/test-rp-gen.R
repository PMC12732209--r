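# independent Riemann-sum oracle for the normalized quantization error:
# sigma^-2 * int min_i (x - b_i)^2 f(x) dx on a fine midpoint grid
mse_oracle <- function(points, mu, lambda, m = 2e5) {
  hi <- qinvgauss(1 - 1e-12, mu, lambda)
  xs <- (seq_len(m) - 0.5) * hi / m
  w <- hi / m
  d2 <- Reduce(pmin, lapply(points, function(b) (xs - b)^2))
  sum(d2 * dinvgauss(xs, mu, lambda)) * w / (mu^3 / lambda)
}

test_that("QMC representative points sit at the midpoint-level quantiles", {
  rp <- rp_qmc(1, 1, 5)
  expect_equal(rp$points, qinvgauss((2 * (1:5) - 1) / 10, 1, 1))
  expect_equal(rp$probs, rep(1 / 5, 5))
  # k = 1 is the median with probability one
  rp1 <- rp_qmc(3, 3, 1)
  expect_equal(rp1$points, qinvgauss(0.5, 3, 3))
  expect_equal(rp1$probs, 1)
  expect_error(rp_qmc(1, 1, 0), "at least 1")
})

test_that("MC representative points are sorted, equal-weight and seeded", {
  rp <- rp_mc(1, 1, 30, seed = 4)
  expect_identical(rp$points, rp_mc(1, 1, 30, seed = 4)$points)
  expect_false(is.unsorted(rp$points, strictly = TRUE))
  expect_equal(rp$probs, rep(1 / 30, 30))
})

test_that("cell probabilities telescope the cdf and match quadrature", {
  expect_equal(cell_probabilities(2.4, 1, 1), 1)
  set.seed(3)
  for (rep in 1:5) {
    pts <- sort(rinvgauss(7, 1, 0.5))
    p <- cell_probabilities(pts, 1, 0.5)
    expect_equal(sum(p), 1, tolerance = 1e-10)
    expect_true(all(p >= 0))
  }
  pts <- c(0.3, 0.8, 1.6, 3.1)
  p <- cell_probabilities(pts, 1, 1)
  edges <- c(0, (pts[-4] + pts[-1]) / 2, qinvgauss(1 - 1e-14, 1, 1))
  pq <- vapply(seq_len(4), function(i)
    integrate(dinvgauss, edges[i], edges[i + 1], mu = 1, lambda = 1,
              rel.tol = 1e-12)$value, numeric(1))
  expect_equal(p, pq, tolerance = 1e-9)
  expect_error(cell_probabilities(c(2, 1), 1, 1), "increasing")
  expect_error(cell_probabilities(c(1, 1), 1, 1), "increasing")
})

test_that("MSE solvers satisfy the centroid fixed point and preserve the mean", {
  # k = 1: the mean minimizes E(X - b)^2
  expect_equal(rp_mse_fh(1, 1, 1)$points, 1, tolerance = 1e-8)
  expect_equal(rp_mse_pkm(3, 3, 1)$points, 3, tolerance = 1e-8)
  for (k in c(2, 5, 17, 30)) {
    fh <- rp_mse_fh(1, 1, k)
    pkm <- rp_mse_pkm(1, 1, k)
    # shared stationarity condition, 4-dp agreement between the solvers
    expect_lt(max(abs(fh$points - pkm$points)), 1e-4)
    for (rp in list(fh, pkm)) {
      expect_equal(sum(rp$points * rp$probs), 1, tolerance = 1e-6)
      # quantization contracts spread
      expect_lte(sum((rp$points - 1)^2 * rp$probs), 1)
    }
  }
  fh33 <- rp_mse_fh(3, 3, 7)
  expect_equal(sum(fh33$points * fh33$probs), 3, tolerance = 1e-6)
})

test_that("the k = 2 principal points match a brute-force grid minimization", {
  fh <- rp_mse_fh(1, 1, 2)
  step <- 0.01
  b1s <- seq(0.55, 0.85, by = step)
  b2s <- seq(2.7, 3.4, by = step)
  vals <- outer(b1s, b2s, Vectorize(function(b1, b2)
    mse_oracle(c(b1, b2), 1, 1, m = 1e4)))
  i <- which(vals == min(vals), arr.ind = TRUE)
  expect_lt(abs(fh$points[1] - b1s[i[1]]), step)
  expect_lt(abs(fh$points[2] - b2s[i[2]]), step)
  expect_lte(mse_oracle(fh$points, 1, 1), min(vals) + 1e-6)
})

test_that("quantization error is 1 at the mean, decreases in k, matches quadrature", {
  expect_equal(mse_value(1, 1, 1), 1, tolerance = 1e-8)
  vals <- vapply(1:10, function(k) mse_value(rp_mse_fh(1, 1, k)$points, 1, 1),
                 numeric(1))
  expect_true(all(diff(vals) < 0))
  pts <- rp_mse_fh(1, 1, 4)$points
  expect_equal(mse_value(pts, 1, 1), mse_oracle(pts, 1, 1), tolerance = 1e-4)
})

test_that("NTLBG quantizer is close to, but no better than, the exact solution", {
  nt <- rp_mse_ntlbg(1, 1, 5)
  expect_equal(sum(nt$probs), 1, tolerance = 1e-10)
  # grid discretization leaves only a small mean bias
  expect_lt(abs(sum(nt$points * nt$probs) - 1), 2e-3)
  fh <- rp_mse_fh(1, 1, 5)
  expect_gte(mse_value(nt$points, 1, 1), mse_value(fh$points, 1, 1) - 1e-12)
  expect_error(rp_mse_ntlbg(1, 1, 5, m_grid = 5), "m_grid")
})

test_that("Cramer-von Mises distance is exact and minimized by the QMC set", {
  rp <- rp_qmc(1, 1, 5)
  # independent fine-grid Riemann oracle on the probability scale
  ts <- (seq_len(2e5) - 0.5) / 2e5
  tb <- pinvgauss(rp$points, 1, 1)
  Fhat <- c(0, cumsum(rp$probs))[findInterval(ts, tb) + 1L]
  oracle <- mean((ts - Fhat)^2)
  expect_equal(cvm_distance(rp, r = 2), oracle, tolerance = 1e-4)
  # for the optimal lattice d_2 = 1/(12 k^2)
  expect_equal(cvm_distance(rp, r = 2), 1 / (12 * 25), tolerance = 1e-10)
  expect_gte(cvm_distance(rp_mc(1, 1, 5, seed = 2), r = 2), 0)
  # d_2 decreases along QMC sets as k grows
  d <- vapply(c(2, 4, 8, 16), function(k) cvm_distance(rp_qmc(1, 1, k)), numeric(1))
  expect_true(all(diff(d) < 0))
  expect_error(cvm_distance(rp, r = 0), "positive")
})
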