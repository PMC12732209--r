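#' Weighted low-order moments of a representative point set
#'
#' Plug-in moments of the discrete law \eqn{(b_i, p_i)}:
#' \deqn{E(b)=\sum b_i p_i,\quad Var(b)=\sum (b_i-E(b))^2 p_i,}
#' with skewness and excess kurtosis standardized by \eqn{Var(b)}.
#' Comparing these with the closed-form moments of the source law
#' ([ig_moments()]) gives the estimation biases of the construction.
#'
#' @param rp an [rp_set] with at least 2 points (variance-normalized
#'   statistics are undefined for a single point).
#' @return named vector \code{c(mean, variance, skewness,
#'   excess_kurtosis)}.
#' @export
rp_moments <- function(rp) {
  if (!inherits(rp, "rp_set")) stop("'rp' must be an rp_set", call. = FALSE)
  if (rp$k < 2L)
    stop("skewness and kurtosis are undefined for a single-point set",
         call. = FALSE)
  b <- rp$points; p <- rp$probs
  m <- sum(b * p)
  v <- sum((b - m)^2 * p)
  c(mean = m, variance = v,
    skewness = sum((b - m)^3 * p) / v^1.5,
    excess_kurtosis = sum((b - m)^4 * p) / v^2 - 3)
}

check_zones <- function(zones) {
  if (!is.numeric(zones) || length(zones) < 2L || is.unsorted(zones, strictly = TRUE))
    stop("'zones' must be strictly increasing break points", call. = FALSE)
  invisible(TRUE)
}

#' Probability-weighted kernel density estimate from representative points
#'
#' The Gaussian-kernel estimator \eqn{\hat p_h(x) = \sum_i p_i\,
#' k_h(x - b_i)} with a zone-specific bandwidth: the evaluation range is
#' partitioned by the break points `zones`, and the bandwidth
#' `bandwidths[j]` applies to x falling in the j-th zone.  (The zones
#' partition the evaluation axis, not the point set: each evaluation uses
#' all k points, so a single-bandwidth configuration integrates to one.)
#'
#' @param rp an [rp_set].
#' @param x evaluation points; must lie inside `(zones[1],
#'   zones[length(zones)]]`.
#' @param bandwidths positive bandwidths, one per zone.
#' @param zones strictly increasing zone break points (default
#'   `c(0, 1, 15)`: zones (0,1] and (1,15]).
#' @return vector of density values.
#' @export
rp_kde <- function(rp, x, bandwidths, zones = c(0, 1, 15)) {
  if (!inherits(rp, "rp_set")) stop("'rp' must be an rp_set", call. = FALSE)
  check_zones(zones)
  nz <- length(zones) - 1L
  if (length(bandwidths) != nz || any(bandwidths <= 0))
    stop("'bandwidths' must be positive, one per zone", call. = FALSE)
  iz <- findInterval(x, zones, left.open = TRUE)
  if (any(iz < 1L | iz > nz | x > zones[nz + 1L]))
    stop("evaluation points must lie inside the zones", call. = FALSE)
  out <- numeric(length(x))
  for (j in seq_len(nz)) {
    sel <- iz == j
    if (!any(sel)) next
    h <- bandwidths[j]
    out[sel] <- colSums(rp$probs * dnorm(outer(rp$points, x[sel], "-") / h)) / h
  }
  out
}

#' Squared L2 error of the weighted KDE on one zone
#'
#' Computes \eqn{\int_{zone} (\hat p_h(x) - f(x))^2 dx} by composite
#' midpoint quadrature (`n_grid` panels), where \eqn{f} is the source
#' inverse Gaussian density of the point set.
#'
#' @param rp an [rp_set].
#' @param h a single positive bandwidth.
#' @param zone numeric length-2 interval `c(lo, hi)` with `lo < hi`.
#' @param n_grid number of quadrature panels (default 2000).
#' @return the squared L2 distance (take `sqrt` for the distance itself).
#' @export
kde_l2_zone <- function(rp, h, zone, n_grid = 2000L) {
  if (!inherits(rp, "rp_set")) stop("'rp' must be an rp_set", call. = FALSE)
  if (!is.numeric(h) || length(h) != 1L || h <= 0)
    stop("'h' must be a single positive bandwidth", call. = FALSE)
  if (length(zone) != 2L || zone[1] >= zone[2])
    stop("'zone' must be an interval c(lo, hi) with lo < hi", call. = FALSE)
  w <- (zone[2] - zone[1]) / n_grid
  xs <- zone[1] + (seq_len(n_grid) - 0.5) * w
  est <- colSums(rp$probs * dnorm(outer(rp$points, xs, "-") / h)) / h
  sum((est - dinvgauss(xs, rp$mu, rp$lambda))^2) * w
}

#' Per-zone bandwidth selection by L2 distance
#'
#' For each zone, picks the bandwidth from `h_grid` minimizing the
#' squared L2 distance between the weighted KDE and the source density
#' over that zone ([kde_l2_zone()]).
#'
#' @param rp an [rp_set].
#' @param zones strictly increasing break points (default `c(0, 1, 15)`).
#' @param h_grid candidate bandwidths (default: 400 log-spaced values in
#'   \[1e-3, 1\]).
#' @param n_grid quadrature panels per zone.
#' @return a list of class `kde_config`: `zones`, `bandwidths` (the
#'   per-zone minimizers), `l2sq` (the attained squared-L2 values) and
#'   `h_grid`.
#' @export
select_bandwidths <- function(rp, zones = c(0, 1, 15),
                              h_grid = exp(seq(log(1e-3), log(1), length.out = 400L)),
                              n_grid = 2000L) {
  if (!length(h_grid) || any(h_grid <= 0))
    stop("'h_grid' must be a nonempty vector of positive bandwidths",
         call. = FALSE)
  check_zones(zones)
  nz <- length(zones) - 1L
  bw <- obj <- numeric(nz)
  for (j in seq_len(nz)) {
    vals <- vapply(h_grid, function(h)
      kde_l2_zone(rp, h, zone = zones[j + 0:1], n_grid = n_grid), numeric(1))
    i <- which.min(vals)
    bw[j] <- h_grid[i]; obj[j] <- vals[i]
  }
  structure(list(zones = zones, bandwidths = bw, l2sq = obj, h_grid = h_grid),
            class = "kde_config")
}

#' @export
print.kde_config <- function(x, ...) {
  nz <- length(x$zones) - 1L
  cat("Two-zone (or multi-zone) KDE configuration\n")
  for (j in seq_len(nz))
    cat(sprintf("  zone %d (%g, %g]: h = %.4g, L2 = %.6g\n",
                j, x$zones[j], x$zones[j + 1], x$bandwidths[j], sqrt(x$l2sq[j])))
  invisible(x)
}
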