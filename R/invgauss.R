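#' The inverse Gaussian (Wald) distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the inverse Gaussian distribution with mean \code{mu} and shape
#' \code{lambda}, optionally translated by a location \code{shift} (the
#' three-parameter model).
#'
#' The density of \eqn{IG(\mu,\lambda)} is
#' \deqn{f(x;\mu,\lambda)=\sqrt{\lambda/(2\pi x^3)}\,
#'   \exp\{-\lambda(x-\mu)^2/(2\mu^2 x)\}, \quad x>0,}
#' with mean \eqn{\mu}, variance \eqn{\mu^3/\lambda}, skewness
#' \eqn{3\sqrt{\mu/\lambda}} and excess kurtosis \eqn{15\mu/\lambda}.
#' The distribution function uses the standard closed form
#' \eqn{\Phi(\sqrt{\lambda/x}(x/\mu-1)) +
#'   e^{2\lambda/\mu}\Phi(-\sqrt{\lambda/x}(x/\mu+1))};
#' the second term is evaluated on the log scale so large
#' \eqn{\lambda/\mu} cannot overflow.  Quantiles are found by monotone
#' bracketed root finding on the cdf to an absolute probability tolerance
#' below 1e-10.  Random variates use the Michael-Schucany-Haas
#' chi-square transform, which is exact.
#'
#' The three-parameter model \eqn{IG(\alpha,\mu,\lambda)} is the same law
#' translated so its support is \eqn{(\alpha,\infty)}; set
#' \code{shift = alpha}.  The density is zero at or below the shift.
#'
#' @param x,q vector of quantiles.
#' @param p vector of probabilities in (0,1).
#' @param n number of variates to draw.
#' @param mu mean parameter, positive.
#' @param lambda shape parameter, positive.
#' @param shift location shift \eqn{\alpha} (default 0, the two-parameter
#'   model).
#' @param log,log.p logical; if TRUE, probabilities/densities are returned
#'   on the log scale.
#' @param lower.tail logical; if TRUE (default), probabilities are
#'   \eqn{P(X \le x)}.
#' @param seed optional integer; when supplied, \code{rinvgauss} draws from
#'   a private RNG stream seeded with it and leaves the global RNG state
#'   untouched, so identical seeds give identical samples.
#'
#' @return \code{dinvgauss} the density, \code{pinvgauss} the distribution
#'   function, \code{qinvgauss} the quantile function, \code{rinvgauss} a
#'   vector of random variates.
#' @examples
#' dinvgauss(1, mu = 1, lambda = 1)        # 1/sqrt(2*pi)
#' pinvgauss(qinvgauss(0.3, 7, 1), 7, 1)   # 0.3
#' mean(rinvgauss(1e4, 3, 3, seed = 1))    # close to 3
#' @name invgauss
NULL

#' @rdname invgauss
#' @export
dinvgauss <- function(x, mu, lambda, shift = 0, log = FALSE) {
  check_ig_params(mu, lambda)
  y <- x - shift
  out <- rep(if (log) -Inf else 0, length(y))
  ok <- is.finite(y) & y > 0
  yy <- y[ok]
  ld <- 0.5 * (log(lambda) - log(2 * pi) - 3 * log(yy)) -
    lambda * (yy - mu)^2 / (2 * mu^2 * yy)
  out[ok] <- if (log) ld else exp(ld)
  out[!is.finite(y)] <- NA_real_
  out
}

#' @rdname invgauss
#' @export
pinvgauss <- function(q, mu, lambda, shift = 0, lower.tail = TRUE, log.p = FALSE) {
  check_ig_params(mu, lambda)
  y <- q - shift
  out <- numeric(length(y))
  ok <- is.finite(y) & y > 0
  yy <- y[ok]
  a <- sqrt(lambda / yy)
  # second term computed in log scale: exp(2*lambda/mu) can overflow alone
  out[ok] <- pnorm(a * (yy / mu - 1)) +
    exp(2 * lambda / mu + pnorm(-a * (yy / mu + 1), log.p = TRUE))
  out[ok] <- pmin(out[ok], 1)
  out[is.finite(y) & y <= 0] <- 0
  out[!is.finite(y) & !is.na(y)] <- ifelse(y[!is.finite(y) & !is.na(y)] > 0, 1, 0)
  out[is.na(y)] <- NA_real_
  if (!lower.tail) out <- 1 - out
  if (log.p) log(out) else out
}

#' @rdname invgauss
#' @export
qinvgauss <- function(p, mu, lambda, shift = 0) {
  check_ig_params(mu, lambda)
  if (any(!is.finite(p) | p <= 0 | p >= 1))
    stop("probabilities must lie strictly inside (0, 1)", call. = FALSE)
  sd <- sqrt(mu^3 / lambda)
  vapply(p, function(pp) {
    lo <- mu * 1e-12
    hi <- mu + 50 * sd
    while (pinvgauss(hi, mu, lambda) < pp) hi <- hi * 2
    while (pinvgauss(lo, mu, lambda) > pp) lo <- lo / 64
    uniroot(function(z) pinvgauss(z, mu, lambda) - pp,
            lower = lo, upper = hi, tol = 1e-13 * max(1, mu))$root
  }, numeric(1)) + shift
}

#' @rdname invgauss
#' @export
rinvgauss <- function(n, mu, lambda, shift = 0, seed = NULL) {
  check_ig_params(mu, lambda)
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("'n' must be a positive integer", call. = FALSE)
  n <- as.integer(n)
  with_seed(seed, {
    y <- rnorm(n)^2
    x <- mu + mu^2 * y / (2 * lambda) -
      mu / (2 * lambda) * sqrt(4 * mu * lambda * y + mu^2 * y^2)
    u <- runif(n)
    ifelse(u <= mu / (mu + x), x, mu^2 / x) + shift
  })
}

# partial expectation E[X * 1(X <= t)] for IG(mu, lambda); closed form,
# the workhorse behind the Lloyd / Fang-He centroid updates.
ig_partial_mean <- function(t, mu, lambda) {
  out <- numeric(length(t))
  ok <- is.finite(t) & t > 0
  tt <- t[ok]
  a <- sqrt(lambda / tt)
  out[ok] <- mu * (pnorm(a * (tt / mu - 1)) -
                     exp(2 * lambda / mu + pnorm(-a * (tt / mu + 1), log.p = TRUE)))
  out[!is.finite(t) & t > 0] <- mu
  out
}

#' Closed-form moments of the inverse Gaussian law
#'
#' @param mu,lambda distribution parameters, positive.
#' @return named vector with components \code{mean}, \code{variance},
#'   \code{skewness} and \code{excess_kurtosis}: \eqn{(\mu,\ \mu^3/\lambda,\
#'   3\sqrt{\mu/\lambda},\ 15\mu/\lambda)}.
#' @examples
#' ig_moments(1, 1)   # 1, 1, 3, 15
#' @export
ig_moments <- function(mu, lambda) {
  check_ig_params(mu, lambda)
  c(mean = mu, variance = mu^3 / lambda,
    skewness = 3 * sqrt(mu / lambda), excess_kurtosis = 15 * mu / lambda)
}

#' Log-likelihood of the inverse Gaussian model
#'
#' Evaluates \eqn{\sum_i \log f(x_i)} for the two-parameter model, or for
#' the shifted three-parameter model when \code{shift} is nonzero.  The
#' shift must lie strictly below the smallest observation.
#'
#' @param x numeric sample.
#' @param mu,lambda distribution parameters, positive.
#' @param shift location shift \eqn{\alpha}; must satisfy
#'   \code{shift < min(x)}.
#' @return the log-likelihood, a single number.
#' @export
ig_loglik <- function(x, mu, lambda, shift = 0) {
  check_ig_params(mu, lambda)
  check_sample(x, positive = FALSE)
  if (any(x <= shift))
    stop("all observations must exceed the location shift", call. = FALSE)
  sum(dinvgauss(x, mu, lambda, shift = shift, log = TRUE))
}

#' Analytic maximum likelihood and UMVU estimators
#'
#' `ig_mle` returns the closed-form MLE of the two-parameter model,
#' \eqn{\hat\mu = \bar X} and
#' \eqn{\hat\lambda = n / \sum_i (1/X_i - 1/\bar X)}.
#' `ig_umvue` replaces the shape estimate by the uniformly minimum-variance
#' unbiased \eqn{\hat\lambda_{UMVUE} = (n-3) / \sum_i (1/X_i - 1/\bar X)},
#' which requires \eqn{n \ge 4}.
#'
#' @param x positive numeric sample (length at least 2 for `ig_mle`,
#'   4 for `ig_umvue`), not constant.
#' @return named vector \code{c(mu, lambda)}.
#' @examples
#' x <- rinvgauss(100, 3, 3, seed = 7)
#' ig_mle(x)
#' @export
ig_mle <- function(x) {
  check_sample(x, positive = TRUE, min_n = 2L)
  mu <- mean(x)
  denom <- sum(1 / x - 1 / mu)
  if (denom <= .Machine$double.eps * length(x) / min(x))
    stop("degenerate sample: shape estimate is undefined for (near-)constant data",
         call. = FALSE)
  c(mu = mu, lambda = length(x) / denom)
}

#' @rdname ig_mle
#' @export
ig_umvue <- function(x) {
  check_sample(x, positive = TRUE, min_n = 4L)
  est <- ig_mle(x)
  n <- length(x)
  c(mu = unname(est["mu"]), lambda = unname(est["lambda"]) * (n - 3) / n)
}
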