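#' Monte Carlo representative points
#'
#' Draws k i.i.d. variates from \eqn{IG(\mu,\lambda)}, sorts them, and
#' assigns probability 1/k to each: the support of the empirical
#' distribution of a random sample.
#'
#' @param mu,lambda source distribution parameters.
#' @param k number of points.
#' @param seed optional integer seed (identical seed, identical set).
#' @return an [rp_set] with method "MC".
#' @export
rp_mc <- function(mu, lambda, k, seed = NULL) {
  if (k < 1) stop("'k' must be at least 1", call. = FALSE)
  pts <- sort(rinvgauss(k, mu, lambda, seed = seed))
  if (anyDuplicated(pts)) pts <- pts + seq_along(pts) * 1e-12 * mu  # ties: machine jitter
  rp_set(pts, rep(1 / k, k), mu, lambda, method = "MC")
}

#' Quasi-Monte Carlo representative points
#'
#' Equal-weight quantiles at the levels \eqn{(2j-1)/(2k)},
#' \eqn{j=1,\dots,k}.  This lattice minimizes both the star discrepancy
#' and every Cramer-von Mises distance \eqn{d_r} among all k-point
#' discrete approximations of a continuous law.
#'
#' @inheritParams rp_mc
#' @return an [rp_set] with method "QMC".
#' @export
rp_qmc <- function(mu, lambda, k) {
  if (k < 1) stop("'k' must be at least 1", call. = FALSE)
  lev <- (2 * seq_len(k) - 1) / (2 * k)
  rp_set(qinvgauss(lev, mu, lambda), rep(1 / k, k), mu, lambda, method = "QMC")
}

# one Lloyd update: midpoint edges, then exact conditional means per cell.
# Uses the closed-form partial expectation, so each sweep is O(k).
lloyd_update <- function(b, mu, lambda) {
  k <- length(b)
  if (k == 1L) return(mu)
  a <- (b[-k] + b[-1]) / 2
  Fa <- c(0, pinvgauss(a, mu, lambda), 1)
  Ea <- c(0, ig_partial_mean(a, mu, lambda), mu)
  dF <- diff(Fa)
  if (any(dF <= 0)) return(rep(NA_real_, k))  # collapsed cell
  diff(Ea) / dF
}

fh_residual <- function(b, mu, lambda) b - lloyd_update(b, mu, lambda)

#' Mean-square-error representative points (principal points)
#'
#' MSE representative points minimize the normalized quantization error
#' \deqn{MSE(b) = \sigma^{-2} \int \min_i (x-b_i)^2 f(x)\,dx,}
#' equivalently they satisfy the self-consistency condition
#' \eqn{b_i = E[X \mid a_i < X \le a_{i+1}]} with midpoint cell edges.
#' Three solvers are provided:
#'
#' * `rp_mse_fh()` - a damped Newton iteration on the centroid residual
#'   system (the nonlinear-equation approach), warm-started by Lloyd
#'   sweeps, converging to residuals below `tol`;
#' * `rp_mse_pkm()` - the parametric k-means (Lloyd) fixed-point
#'   iteration, stopping when the largest point shift drops below `tol`;
#' * `rp_mse_ntlbg()` - the LBG/k-means quantizer run on a fine
#'   quasi-Monte Carlo discretization of the law (`m_grid` support points
#'   at levels \eqn{(2i-1)/(2m)}), initialized at the k QMC points; its
#'   small residual biases reflect the grid discretization.
#'
#' All three attach the exact continuous-law cell probabilities of
#' [cell_probabilities()].  Should two points collapse during iteration
#' they are separated by machine-scale jitter and iteration continues.
#'
#' @inheritParams rp_mc
#' @param tol convergence tolerance (residual norm for FH, max point shift
#'   for PKM / NTLBG).
#' @param max_iter iteration cap; exceeding it raises an error carrying
#'   the last residual.
#' @param m_grid size of the QMC discretization grid for NTLBG; must be
#'   much larger than k (default 1e4).
#' @return an [rp_set] with method "FH", "PKM" or "NTLBG".
#' @export
rp_mse_fh <- function(mu, lambda, k, tol = 1e-12, max_iter = 200L) {
  if (k < 1) stop("'k' must be at least 1", call. = FALSE)
  if (k == 1L) return(rp_set(mu, 1, mu, lambda, method = "FH"))
  b <- rp_mse_pkm(mu, lambda, k, tol = 1e-8, max_iter = 1e5L)$points
  r <- fh_residual(b, mu, lambda)
  for (it in seq_len(max_iter)) {
    if (max(abs(r)) < tol) break
    # finite-difference Jacobian of the residual system
    J <- matrix(0, k, k)
    h <- pmax(abs(b), mu) * 1e-7
    for (j in seq_len(k)) {
      bj <- b; bj[j] <- bj[j] + h[j]
      J[, j] <- (fh_residual(bj, mu, lambda) - r) / h[j]
    }
    step <- tryCatch(solve(J, r), error = function(e) NULL)
    accepted <- FALSE
    if (!is.null(step)) {
      damp <- 1
      while (damp >= 1e-6) {
        bn <- b - damp * step
        if (all(bn > 0) && !is.unsorted(bn, strictly = TRUE)) {
          rn <- fh_residual(bn, mu, lambda)
          if (all(is.finite(rn)) && max(abs(rn)) < max(abs(r))) {
            b <- bn; r <- rn; accepted <- TRUE; break
          }
        }
        damp <- damp / 2
      }
    }
    if (!accepted) {  # fall back to a Lloyd sweep
      bn <- lloyd_update(b, mu, lambda)
      if (any(!is.finite(bn))) stop("Fang-He iteration collapsed", call. = FALSE)
      b <- bn
      r <- fh_residual(b, mu, lambda)
    }
  }
  if (max(abs(r)) >= tol)
    stop(sprintf("Fang-He solver did not converge: last residual %.3e", max(abs(r))),
         call. = FALSE)
  rp_set(b, cell_probabilities(b, mu, lambda), mu, lambda, method = "FH")
}

#' @rdname rp_mse_fh
#' @export
rp_mse_pkm <- function(mu, lambda, k, tol = 1e-10, max_iter = 1e5L) {
  if (k < 1) stop("'k' must be at least 1", call. = FALSE)
  if (k == 1L) return(rp_set(mu, 1, mu, lambda, method = "PKM"))
  b <- qinvgauss((2 * seq_len(k) - 1) / (2 * k), mu, lambda)
  shift <- Inf
  for (it in seq_len(max_iter)) {
    bn <- lloyd_update(b, mu, lambda)
    if (any(!is.finite(bn)) || any(diff(bn) < 1e-12 * mu)) {
      bn[which(!is.finite(bn))] <- b[which(!is.finite(bn))]
      bn <- bn + seq_along(bn) * 1e-12 * mu  # separate collapsing points
      bn <- sort(bn)
    }
    shift <- max(abs(bn - b))
    b <- bn
    if (shift < tol) break
  }
  if (shift >= tol)
    stop(sprintf("parametric k-means did not converge: last shift %.3e", shift),
         call. = FALSE)
  rp_set(b, cell_probabilities(b, mu, lambda), mu, lambda, method = "PKM")
}

#' @rdname rp_mse_fh
#' @export
rp_mse_ntlbg <- function(mu, lambda, k, m_grid = 1e4L, tol = 1e-12,
                         max_iter = 1e4L) {
  if (k < 1) stop("'k' must be at least 1", call. = FALSE)
  if (m_grid <= k) stop("'m_grid' must exceed 'k'", call. = FALSE)
  grid <- qinvgauss((2 * seq_len(m_grid) - 1) / (2 * m_grid), mu, lambda)
  b <- qinvgauss((2 * seq_len(k) - 1) / (2 * k), mu, lambda)
  if (k == 1L) {
    b <- mean(grid)
    return(rp_set(b, 1, mu, lambda, method = "NTLBG"))
  }
  for (it in seq_len(max_iter)) {
    a <- (b[-k] + b[-1]) / 2
    idx <- findInterval(grid, a) + 1L
    bn <- vapply(seq_len(k), function(i) mean(grid[idx == i]), numeric(1))
    if (any(!is.finite(bn))) {  # empty cluster: re-seed it next to its neighbour
      bad <- which(!is.finite(bn))
      bn[bad] <- b[bad]
    }
    shift <- max(abs(bn - b))
    b <- bn
    if (shift < tol) break
  }
  rp_set(b, cell_probabilities(b, mu, lambda), mu, lambda, method = "NTLBG")
}

#' Normalized quantization error of a point set
#'
#' Evaluates \eqn{MSE(b) = \sigma^{-2}\sum_i \int_{a_i}^{a_{i+1}}
#' (x-b_i)^2 f(x)\,dx} by per-cell adaptive quadrature, with the upper
#' infinite edge truncated at the \eqn{1-10^{-13}} quantile.
#'
#' @inheritParams cell_probabilities
#' @return a nonnegative number; equals 1 for the single point
#'   \eqn{b=\mu}.
#' @export
mse_value <- function(points, mu, lambda) {
  check_ig_params(mu, lambda)
  if (any(!is.finite(points)) || any(points <= 0) ||
      is.unsorted(points, strictly = TRUE))
    stop("'points' must be finite, positive and strictly increasing",
         call. = FALSE)
  k <- length(points)
  edges <- c(0, if (k > 1) (points[-k] + points[-1]) / 2,
             qinvgauss(1 - 1e-13, mu, lambda))
  total <- 0
  for (i in seq_len(k)) {
    total <- total + integrate(function(x) (x - points[i])^2 * dinvgauss(x, mu, lambda),
                               lower = edges[i], upper = edges[i + 1],
                               rel.tol = 1e-10, abs.tol = 1e-12,
                               subdivisions = 500L)$value
  }
  total / (mu^3 / lambda)
}

#' Cramer-von Mises distance between a law and a point set
#'
#' The distance family \eqn{d_r(F,\hat F) = \int_0^1 |t - \hat
#' F(F^{-1}(t))|^r dt} between the continuous cdf \eqn{F} of the source
#' law and the step cdf \eqn{\hat F} of the representative point set.  The
#' integrand is piecewise \eqn{|t - c_i|^r} between consecutive values of
#' \eqn{F(b_i)}, so the integral is evaluated exactly in closed form.
#' The QMC set minimizes \eqn{d_r} for every \eqn{r > 0}.
#'
#' @param rp an [rp_set].
#' @param r positive exponent (r = 2 is the classical CvM distance).
#' @return a nonnegative number.
#' @export
cvm_distance <- function(rp, r = 2) {
  if (!inherits(rp, "rp_set")) stop("'rp' must be an rp_set", call. = FALSE)
  if (!is.numeric(r) || length(r) != 1L || r <= 0)
    stop("'r' must be a positive number", call. = FALSE)
  tb <- pinvgauss(rp$points, rp$mu, rp$lambda)     # breakpoints in t
  cum <- c(0, cumsum(rp$probs))                    # step heights
  lo <- c(0, tb); hi <- c(tb, 1)
  H <- function(s) sign(s) * abs(s)^(r + 1) / (r + 1)
  sum(H(hi - cum) - H(lo - cum))
}
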