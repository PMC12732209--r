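#' Representative point sets
#'
#' An `rp_set` is a finite discrete approximation of an inverse Gaussian
#' law: ordered support points \eqn{b_1 < \dots < b_k} with probabilities
#' \eqn{p_1,\dots,p_k} summing to one, together with the generating
#' parameters and the cell edges \eqn{a_1=0 < a_2 < \dots < a_{k+1}=\infty}
#' (interior edges are the midpoints \eqn{(b_{i-1}+b_i)/2}).
#'
#' @param points strictly increasing vector of positive support points.
#' @param probs probabilities of the points; must be nonnegative and sum
#'   to 1 (within 1e-10).
#' @param mu,lambda parameters of the source distribution.
#' @param method label for the construction ("MC", "QMC", "FH", "PKM",
#'   "NTLBG" or a user tag).
#' @return an object of class `rp_set`: a list with elements `points`,
#'   `probs`, `k`, `method`, `mu`, `lambda`, `cell_edges`.
#' @seealso [rp_qmc()], [rp_mse_fh()], [rp_mse_pkm()], [rp_mse_ntlbg()],
#'   [rp_mc()]
#' @export
rp_set <- function(points, probs, mu, lambda, method = "custom") {
  check_ig_params(mu, lambda)
  if (!is.numeric(points) || length(points) < 1L || any(!is.finite(points)) ||
      any(points <= 0))
    stop("'points' must be finite positive numbers", call. = FALSE)
  if (is.unsorted(points, strictly = TRUE))
    stop("'points' must be strictly increasing", call. = FALSE)
  if (length(probs) != length(points) || any(!is.finite(probs)) || any(probs < 0))
    stop("'probs' must be nonnegative, one per point", call. = FALSE)
  if (abs(sum(probs) - 1) > 1e-10)
    stop("'probs' must sum to 1", call. = FALSE)
  k <- length(points)
  edges <- c(0, if (k > 1) (points[-k] + points[-1]) / 2, Inf)
  structure(list(points = as.numeric(points), probs = as.numeric(probs),
                 k = k, method = method, mu = mu, lambda = lambda,
                 cell_edges = edges),
            class = "rp_set")
}

#' @export
print.rp_set <- function(x, ...) {
  cat(sprintf("%s representative points (k = %d) of IG(mu = %g, lambda = %g)\n",
              x$method, x$k, x$mu, x$lambda))
  df <- data.frame(point = x$points, prob = x$probs)
  print(utils::head(df, 10L), row.names = FALSE)
  if (x$k > 10L) cat(sprintf("... %d more points\n", x$k - 10L))
  invisible(x)
}

#' @export
as.data.frame.rp_set <- function(x, ...) {
  data.frame(index = seq_len(x$k), point = x$points, prob = x$probs)
}

#' Cell probabilities of a point set under an inverse Gaussian law
#'
#' For strictly increasing points \eqn{b_1<\dots<b_k} the midpoint cell
#' edges are \eqn{a_1=0}, \eqn{a_i=(b_{i-1}+b_i)/2}, \eqn{a_{k+1}=\infty},
#' and the probability attached to \eqn{b_i} is
#' \eqn{p_i = F(a_{i+1}) - F(a_i)} under \eqn{IG(\mu,\lambda)}.
#'
#' @param points strictly increasing positive vector.
#' @param mu,lambda source distribution parameters.
#' @return probability vector of the same length, summing to 1.
#' @export
cell_probabilities <- function(points, mu, lambda) {
  check_ig_params(mu, lambda)
  if (any(!is.finite(points)) || any(points <= 0) ||
      is.unsorted(points, strictly = TRUE))
    stop("'points' must be finite, positive and strictly increasing",
         call. = FALSE)
  k <- length(points)
  if (k == 1L) return(1)
  a <- (points[-k] + points[-1]) / 2
  diff(c(0, pinvgauss(a, mu, lambda), 1))
}
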