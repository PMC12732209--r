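# vectorized two-parameter log-likelihood via sufficient statistics:
# l(mu, lambda) = n/2 log lambda - n/2 log 2pi - 3/2 sum(log x)
#                 - lambda/(2 mu^2) * (Sx - 2 mu n + mu^2 Sinv)
loglik_grid_2p <- function(theta, n, s_x, s_logx, s_inv) {
  mu <- theta[, 1L]; lam <- theta[, 2L]
  n / 2 * log(lam) - n / 2 * log(2 * pi) - 1.5 * s_logx -
    lam / (2 * mu^2) * (s_x - 2 * mu * n + mu^2 * s_inv)
}

#' Maximum likelihood fitting of the inverse Gaussian model
#'
#' Fits the two-parameter \eqn{IG(\mu,\lambda)} or three-parameter
#' (location-shifted) \eqn{IG(\alpha,\mu,\lambda)} model by maximizing the
#' log-likelihood.  The `analytic` method (two-parameter only) uses the
#' closed forms \eqn{\hat\mu = \bar X},
#' \eqn{\hat\lambda = n/\sum(1/X_i - 1/\bar X)}.  The `snto` method runs
#' the sequential number-theoretic optimizer over a data-driven box:
#' \eqn{\mu \in [\bar x/10, 10\bar x]},
#' \eqn{\lambda \in [\hat\lambda_{ML}/10, 10\hat\lambda_{ML}]}, and for
#' the shifted model \eqn{\alpha \in [\min(x) - range(x),\ \min(x) -
#' \epsilon]} with \eqn{\epsilon = 10^{-9} range(x)}, which keeps the
#' unbounded-likelihood boundary \eqn{\alpha \to \min(x)} out of the
#' search.
#'
#' @param x a positive numeric sample, or a [revise_sample()] result
#'   (its revised values are fitted).
#' @param model "two_param" or "three_param".
#' @param method "analytic" (two-parameter only) or "snto".
#' @param snto_control named list overriding [snto_maximize()] settings
#'   (`n_points`, `contraction`, `max_sweeps`, `diameter_tol`) or the
#'   search `box` (list of c(lo, hi) per parameter).
#' @param seed optional seed (only used for a scrambled SNTO net).
#' @return list of class `ig_fit`: `estimate` (named vector `mu`,
#'   `lambda`, and `shift` for the three-parameter model), `loglik`,
#'   `model`, `method`, `n`.
#' @examples
#' x <- rinvgauss(50, 1, 1, seed = 3)
#' ig_fit(x)                               # analytic two-parameter fit
#' ig_fit(x, method = "snto")$estimate     # agrees to ~1e-4
#' @export
ig_fit <- function(x, model = c("two_param", "three_param"),
                   method = c("analytic", "snto"),
                   snto_control = list(), seed = NULL) {
  model <- match.arg(model)
  method <- match.arg(method)
  if (inherits(x, "revised_sample")) x <- x$values
  check_sample(x, positive = model == "two_param", min_n = 2L)
  n <- length(x)
  ctl <- modifyList(list(n_points = 500L, contraction = 0.5,
                         max_sweeps = 100L, diameter_tol = 1e-7, box = NULL),
                    snto_control)
  if (model == "two_param") {
    est0 <- ig_mle(x)
    if (method == "analytic") {
      return(structure(list(estimate = est0,
                            loglik = ig_loglik(x, est0["mu"], est0["lambda"]),
                            model = model, method = method, n = n),
                       class = "ig_fit"))
    }
    s_x <- sum(x); s_logx <- sum(log(x)); s_inv <- sum(1 / x)
    box <- ctl$box
    if (is.null(box))
      box <- list(mu = c(mean(x) / 10, 10 * mean(x)),
                  lambda = c(est0["lambda"] / 10, 10 * est0["lambda"]))
    opt <- snto_maximize(function(th) loglik_grid_2p(th, n, s_x, s_logx, s_inv),
                         lower = c(box[[1]][1], box[[2]][1]),
                         upper = c(box[[1]][2], box[[2]][2]),
                         n_points = ctl$n_points, contraction = ctl$contraction,
                         max_sweeps = ctl$max_sweeps,
                         diameter_tol = ctl$diameter_tol, seed = seed)
    est <- c(mu = opt$par[1], lambda = opt$par[2])
    return(structure(list(estimate = est, loglik = opt$value,
                          model = model, method = method, n = n),
                     class = "ig_fit"))
  }
  # three-parameter model: SNTO only (the likelihood is multimodal in alpha)
  if (method == "analytic")
    stop("the analytic method applies to the two-parameter model only",
         call. = FALSE)
  rng <- max(x) - min(x)
  if (rng <= 0) stop("degenerate sample", call. = FALSE)
  eps <- 1e-9 * rng
  a_hi <- min(x) - eps
  a_lo <- min(x) - rng
  # moment-scale boxes for mu and lambda: anchor the closed-form estimates
  # at several candidate shifts spanning the alpha box (the conditional
  # MLE scale varies strongly with alpha)
  anchors <- a_hi - c(1e-3, 0.1, 0.5, 1) * rng
  lam_anchor <- vapply(anchors, function(a) unname(ig_mle(x - a)["lambda"]),
                       numeric(1))
  box <- ctl$box
  if (is.null(box))
    box <- list(shift = c(a_lo, a_hi),
                mu = c((mean(x) - a_hi) / 10, 10 * (mean(x) - a_lo)),
                lambda = c(min(lam_anchor) / 10, 10 * max(lam_anchor)))
  # the conditional scale of lambda (and mu) varies over orders of
  # magnitude across the alpha box, so the search runs on the log scale
  obj <- function(th) {
    vapply(seq_len(nrow(th)), function(i) {
      a <- th[i, 1L]
      if (a >= min(x)) return(-Inf)
      y <- x - a
      loglik_grid_2p(matrix(exp(th[i, 2:3]), 1L), n, sum(y), sum(log(y)),
                     sum(1 / y))
    }, numeric(1))
  }
  opt <- snto_maximize(obj,
                       lower = c(box[[1]][1], log(box[[2]][1]), log(box[[3]][1])),
                       upper = c(box[[1]][2], log(box[[2]][2]), log(box[[3]][2])),
                       n_points = ctl$n_points, contraction = ctl$contraction,
                       max_sweeps = ctl$max_sweeps,
                       diameter_tol = ctl$diameter_tol, seed = seed)
  est <- c(mu = exp(opt$par[2]), lambda = exp(opt$par[3]), shift = opt$par[1])
  structure(list(estimate = est, loglik = opt$value,
                 model = model, method = method, n = n),
            class = "ig_fit")
}

#' @export
print.ig_fit <- function(x, ...) {
  cat(sprintf("Inverse Gaussian %s fit (%s), n = %d\n",
              sub("_", "-", x$model), x$method, x$n))
  print(round(x$estimate, 6))
  cat(sprintf("log-likelihood: %.4f\n", x$loglik))
  invisible(x)
}

# integration range covering both laws' essential support
accuracy_range <- function(true, est) {
  lo <- min(qinvgauss(1e-10, true["mu"], true["lambda"], shift = true["shift"]),
            qinvgauss(1e-10, est["mu"], est["lambda"], shift = est["shift"]))
  hi <- max(qinvgauss(1 - 1e-10, true["mu"], true["lambda"], shift = true["shift"]),
            qinvgauss(1 - 1e-10, est["mu"], est["lambda"], shift = est["shift"]))
  c(max(lo, min(true["shift"], est["shift"]) + 1e-300), hi)
}

#' Distributional accuracy measures between two inverse Gaussian laws
#'
#' Four measures of the disparity between a true and an estimated law:
#' \describe{
#'   \item{`l2_cdf_distance`}{\eqn{(\int (F_{true}-F_{est})^2 dx)^{1/2}}}
#'   \item{`l2_pdf_distance`}{\eqn{(\int (f_{true}-f_{est})^2 dx)^{1/2}}}
#'   \item{`kl_divergence`}{\eqn{\int f_{true} \ln(f_{true}/f_{est}) dx}
#'     (requires the estimated support to cover the true support:
#'     `est` shift must not exceed `true` shift)}
#'   \item{`abi`}{the absolute bias index, the mean of the per-parameter
#'     relative errors \eqn{|\theta - \hat\theta|/\theta}; for the
#'     three-parameter model all three parameters enter the mean}
#' }
#' All are zero iff the two parameter sets coincide.  Integrals run over
#' the union of the two laws' \eqn{[10^{-10}, 1-10^{-10}]} quantile
#' ranges by adaptive quadrature.
#'
#' @param true,est parameter vectors `c(mu, lambda)` or
#'   `c(mu, lambda, shift)` (also accepts an `ig_fit`'s `estimate`).
#' @return a nonnegative number.
#' @export
l2_cdf_distance <- function(true, est) {
  true <- as_ig_params(true); est <- as_ig_params(est)
  r <- accuracy_range(true, est)
  v <- integrate(function(x)
    (pinvgauss(x, true["mu"], true["lambda"], shift = true["shift"]) -
       pinvgauss(x, est["mu"], est["lambda"], shift = est["shift"]))^2,
    r[1], r[2], rel.tol = 1e-9, subdivisions = 500L)$value
  sqrt(v)
}

#' @rdname l2_cdf_distance
#' @export
l2_pdf_distance <- function(true, est) {
  true <- as_ig_params(true); est <- as_ig_params(est)
  r <- accuracy_range(true, est)
  v <- integrate(function(x)
    (dinvgauss(x, true["mu"], true["lambda"], shift = true["shift"]) -
       dinvgauss(x, est["mu"], est["lambda"], shift = est["shift"]))^2,
    r[1], r[2], rel.tol = 1e-9, subdivisions = 500L)$value
  sqrt(v)
}

#' @rdname l2_cdf_distance
#' @export
kl_divergence <- function(true, est) {
  true <- as_ig_params(true); est <- as_ig_params(est)
  if (est["shift"] > true["shift"])
    stop("support mismatch: estimated support does not cover the true support",
         call. = FALSE)
  lo <- qinvgauss(1e-10, true["mu"], true["lambda"], shift = true["shift"])
  hi <- qinvgauss(1 - 1e-10, true["mu"], true["lambda"], shift = true["shift"])
  integrate(function(x) {
    ft <- dinvgauss(x, true["mu"], true["lambda"], shift = true["shift"])
    fe <- dinvgauss(x, est["mu"], est["lambda"], shift = est["shift"])
    ifelse(ft > 0, ft * (log(ft) - log(fe)), 0)
  }, lo, hi, rel.tol = 1e-9, subdivisions = 500L)$value
}

#' @rdname l2_cdf_distance
#' @export
abi <- function(true, est) {
  true <- as_ig_params(true); est <- as_ig_params(est)
  if (true["mu"] <= 0 || true["lambda"] <= 0)
    stop("true parameters must be positive", call. = FALSE)
  rel <- c(abs(true["mu"] - est["mu"]) / true["mu"],
           abs(true["lambda"] - est["lambda"]) / true["lambda"])
  if (true["shift"] != 0 || est["shift"] != 0) {
    if (true["shift"] == 0)
      stop("relative error of a zero shift is undefined", call. = FALSE)
    rel <- c(rel, abs(true["shift"] - est["shift"]) / abs(true["shift"]))
  }
  mean(rel)
}

#' Kolmogorov-Smirnov goodness of fit for a fitted inverse Gaussian law
#'
#' Compares the empirical cdf of a sample with a fitted
#' \eqn{IG(\mu,\lambda)} (optionally shifted) cdf.  Two statistics are
#' returned: `statistic`, the empirical cdf evaluated at the sample
#' points, \eqn{\max_i |i/n - F(x_{(i)})|}; and `statistic_sup`, the full
#' sup-norm over both step limits,
#' \eqn{\max_i \max(|i/n - F(x_{(i)})|, |(i-1)/n - F(x_{(i)})|)}.
#' The p-value comes from the asymptotic Kolmogorov series (100 terms)
#' evaluated at `statistic_sup`, whose sampling theory the series
#' describes.
#'
#' @param x numeric sample.
#' @param mu,lambda,shift fitted parameters.
#' @return list with `statistic`, `statistic_sup`, `p_value`, `n`.
#' @export
ig_ks_test <- function(x, mu, lambda, shift = 0) {
  check_sample(x, positive = FALSE)
  n <- length(x)
  Fx <- pinvgauss(sort(x), mu, lambda, shift = shift)
  d_at <- max(abs(seq_len(n) / n - Fx))
  d_sup <- max(d_at, max(abs((seq_len(n) - 1) / n - Fx)))
  lam <- sqrt(n) * d_sup
  j <- seq_len(100L)
  p <- min(1, max(0, 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lam^2))))
  list(statistic = d_at, statistic_sup = d_sup, p_value = p, n = n)
}

#' Goodness-of-fit indicators for a fitted inverse Gaussian law
#'
#' Residual-based indicators on the probability scale: with the empirical
#' cdf evaluated at the sample points, \eqn{F_{emp}(x_{(i)}) = i/n}, the
#' residuals \eqn{e_i = F_{emp}(x_{(i)}) - F_{fit}(x_{(i)})} give
#' `bias` = mean(e), `sse` = \eqn{\sum e_i^2} and
#' `r2` = \eqn{1 - sse / \sum (F_{emp} - \bar F_{emp})^2}, together with
#' the Kolmogorov-Smirnov results of [ig_ks_test()] (whose `statistic` is
#' \eqn{\max_i |e_i|}) and the log-likelihood.
#'
#' @inheritParams ig_ks_test
#' @return list with `ks_D`, `ks_p`, `bias`, `sse`, `r2`, `loglik` and
#'   the residual vector `residuals`.
#' @export
fit_indicators <- function(x, mu, lambda, shift = 0) {
  check_sample(x, positive = FALSE, min_n = 2L)
  n <- length(x)
  xs <- sort(x)
  femp <- seq_len(n) / n
  e <- femp - pinvgauss(xs, mu, lambda, shift = shift)
  ks <- ig_ks_test(x, mu, lambda, shift = shift)
  list(ks_D = ks$statistic, ks_p = ks$p_value,
       bias = mean(e), sse = sum(e^2),
       r2 = 1 - sum(e^2) / sum((femp - mean(femp))^2),
       loglik = ig_loglik(x, mu, lambda, shift = shift),
       residuals = e)
}
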