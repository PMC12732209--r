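#' Harrell-Davis quantile estimator
#'
#' The Harrell-Davis estimator of the p-th quantile is the weighted sum of
#' all order statistics \eqn{Q(p) = \sum_i W_{n,i} X_{(i)}}, with beta
#' weights
#' \deqn{W_{n,i} = I_{i/n}(a, b) - I_{(i-1)/n}(a, b),\quad
#'   a = (n+1)p,\ b = (n+1)(1-p),}
#' where \eqn{I_x(a,b)} is the regularized incomplete beta function.  The
#' weights are nonnegative and telescope to one.
#'
#' @param n sample size.
#' @param p probability level in (0,1) (`hd_quantile` accepts a vector).
#' @param x numeric sample.
#' @return `hd_weights`: the weight vector \eqn{W_{n,1..n}};
#'   `hd_quantile`: the estimated quantile(s), always inside
#'   \[min(x), max(x)\].
#' @export
hd_weights <- function(n, p) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("'n' must be a positive integer", call. = FALSE)
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1)
    stop("'p' must lie strictly inside (0, 1)", call. = FALSE)
  n <- as.integer(n)
  a <- (n + 1) * p
  b <- (n + 1) * (1 - p)
  pbeta(seq_len(n) / n, a, b) - pbeta((seq_len(n) - 1) / n, a, b)
}

#' @rdname hd_weights
#' @export
hd_quantile <- function(x, p) {
  check_sample(x, positive = FALSE)
  xs <- sort(x)
  n <- length(x)
  vapply(p, function(pp) sum(hd_weights(n, pp) * xs), numeric(1))
}

#' Sfakianakis-Verginis quantile estimators
#'
#' The three SV estimators weight order statistics by the binomial pmf
#' \eqn{B(i;n,q)}.  With \eqn{X_{(1)} \le \dots \le X_{(n)}} sorted and
#' \eqn{B_i = B(i;n,q)}:
#' \deqn{SV1 = \tfrac{2B_0+B_1}{2} X_{(1)} + \tfrac{B_0}{2}(X_{(2)}-X_{(3)})
#'  + \sum_{i=2}^{n-1} \tfrac{B_i+B_{i-1}}{2} X_{(i)}
#'  + \tfrac{B_n}{2}(X_{(n-1)}-X_{(n-2)}) + \tfrac{2B_n+B_{n-1}}{2} X_{(n)},}
#' \deqn{SV2 = \sum_{i=0}^{n-1} B_i X_{(i+1)} + (2X_{(n)}-X_{(n-1)}) B_n,}
#' \deqn{SV3 = \sum_{i=1}^{n} B_i X_{(i)} + (2X_{(1)}-X_{(2)}) B_0.}
#' The edge terms extrapolate linearly beyond the sample (so SV outputs
#' can leave the sample range, but always stay within
#' \eqn{[2X_{(1)}-X_{(2)},\ 2X_{(n)}-X_{(n-1)}]}).  SV1 requires
#' \eqn{n \ge 3}; SV2 and SV3 require \eqn{n \ge 2}.  At the boundary,
#' \eqn{SV2(0) = X_{(1)}} and \eqn{SV3(1) = X_{(n)}}.
#'
#' @param x numeric sample.
#' @param q probability level in \[0, 1\] (vectors allowed).
#' @param variant one of "sv1", "sv2", "sv3".
#' @return estimated quantile(s).
#' @export
sv_quantile <- function(x, q, variant = c("sv1", "sv2", "sv3")) {
  variant <- match.arg(variant)
  min_n <- if (variant == "sv1") 3L else 2L
  check_sample(x, positive = FALSE, min_n = min_n)
  if (any(q < 0 | q > 1)) stop("'q' must lie in [0, 1]", call. = FALSE)
  xs <- sort(x)
  n <- length(x)
  one <- function(qq) {
    B <- dbinom(0:n, n, qq)     # B[i + 1] = B(i; n, q)
    switch(variant,
      sv1 = (2 * B[1] + B[2]) / 2 * xs[1] + B[1] * (xs[2] - xs[3]) / 2 +
        sum((B[3:n] + B[2:(n - 1)]) / 2 * xs[2:(n - 1)]) +
        B[n + 1] * (xs[n - 1] - xs[n - 2]) / 2 +
        (2 * B[n + 1] + B[n]) / 2 * xs[n],
      sv2 = sum(B[1:n] * xs) + (2 * xs[n] - xs[n - 1]) * B[n + 1],
      sv3 = sum(B[2:(n + 1)] * xs) + (2 * xs[1] - xs[2]) * B[1])
  }
  vapply(q, one, numeric(1))
}

#' Revise a sample through a nonparametric quantile estimator
#'
#' Replaces a raw sample by quantile estimates at the QMC probability
#' lattice \eqn{(2j-1)/(2m)}, \eqn{j = 1,\dots,m} - the same levels that
#' define QMC representative points.  The result is a distribution-matched
#' rearrangement of the sample information, used to stabilize maximum
#' likelihood fitting.  By default m equals the raw sample size.
#'
#' @param x numeric sample.
#' @param estimator one of "hd", "sv1", "sv2", "sv3".
#' @param m number of revision levels (default `length(x)`).
#' @return list of class `revised_sample` with `levels`, `values`,
#'   `estimator` and the raw `source` sample.  Deterministic given x.
#' @export
revise_sample <- function(x, estimator = c("hd", "sv1", "sv2", "sv3"),
                          m = length(x)) {
  estimator <- match.arg(estimator)
  if (!is.numeric(m) || length(m) != 1L || m < 1)
    stop("'m' must be a positive integer", call. = FALSE)
  m <- as.integer(m)
  lev <- (2 * seq_len(m) - 1) / (2 * m)
  vals <- if (estimator == "hd") hd_quantile(x, lev)
          else sv_quantile(x, lev, variant = estimator)
  structure(list(levels = lev, values = vals, estimator = estimator,
                 source = x),
            class = "revised_sample")
}

#' @export
print.revised_sample <- function(x, ...) {
  cat(sprintf("Sample of %d values revised by %s at %d QMC levels\n",
              length(x$source), toupper(x$estimator), length(x$values)))
  print(utils::head(data.frame(level = x$levels, value = x$values), 8L),
        row.names = FALSE)
  if (length(x$values) > 8L) cat("...\n")
  invisible(x)
}
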