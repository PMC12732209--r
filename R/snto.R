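#' Halton low-discrepancy sequence
#'
#' Deterministic quasi-random points in the unit hypercube (van der Corput
#' radical inverses in the first d prime bases).
#'
#' @param n number of points.
#' @param d dimension (up to 8).
#' @return an n x d matrix of points in (0, 1)^d.
#' @export
halton <- function(n, d) {
  bases <- c(2, 3, 5, 7, 11, 13, 17, 19)
  if (d > length(bases)) stop("dimension too large", call. = FALSE)
  radical_inverse <- function(i, base) {
    out <- numeric(length(i))
    f <- 1 / base
    while (any(i > 0)) {
      out <- out + f * (i %% base)
      i <- i %/% base
      f <- f / base
    }
    out
  }
  vapply(seq_len(d), function(j) radical_inverse(seq_len(n), bases[j]),
         numeric(n))
}

#' Sequential number-theoretic optimization
#'
#' Global maximization over a box by sweeps of low-discrepancy (Halton)
#' points: evaluate the objective on a point set spread over the current
#' box, keep the best point, contract the box around it by the contraction
#' ratio, and repeat until the box diameter falls below `diameter_tol` or
#' `max_sweeps` is reached.  The best point found so far is always
#' retained in the evaluation set, so the running maximum is monotone.
#' The search is deterministic; `seed` randomizes the point set by a
#' uniform torus shift only if `scramble = TRUE`.
#'
#' @param objective the function to maximize.  With `vectorized = TRUE`
#'   (default) it must accept an m x d matrix and return m values; with
#'   `vectorized = FALSE` it takes a length-d vector.
#' @param lower,upper numeric vectors: the search box.
#' @param n_points points per sweep (default 500).
#' @param contraction box shrink ratio per sweep, in (0,1) (default 0.5).
#' @param max_sweeps sweep cap (default 100).
#' @param diameter_tol stop when the widest box side drops below this
#'   (default 1e-7).
#' @param vectorized whether `objective` is matrix-vectorized.
#' @param scramble,seed optional random torus shift of the Halton set.
#' @return list with `par` (argmax found), `value` (objective there,
#'   the maximum over all evaluations), `sweeps`, and `evaluations`.
#' @export
snto_maximize <- function(objective, lower, upper, n_points = 500L,
                          contraction = 0.5, max_sweeps = 100L,
                          diameter_tol = 1e-7, vectorized = TRUE,
                          scramble = FALSE, seed = NULL) {
  d <- length(lower)
  if (length(upper) != d || any(upper <= lower))
    stop("'lower' and 'upper' must define a nonempty box", call. = FALSE)
  if (contraction <= 0 || contraction >= 1)
    stop("'contraction' must lie in (0, 1)", call. = FALSE)
  f <- if (vectorized) objective else
    function(m) apply(m, 1L, objective)
  u <- halton(n_points, d)
  if (scramble) {
    shift <- with_seed(seed, runif(d))
    u <- (u + matrix(shift, n_points, d, byrow = TRUE)) %% 1
  }
  lo <- as.numeric(lower); hi <- as.numeric(upper)
  best_x <- NULL; best_v <- -Inf
  evals <- 0L; sweep <- 0L
  while (sweep < max_sweeps) {
    sweep <- sweep + 1L
    X <- sweep(u, 2L, hi - lo, "*")
    X <- sweep(X, 2L, lo, "+")
    if (!is.null(best_x)) X <- rbind(X, best_x)
    v <- f(X)
    evals <- evals + nrow(X)
    v[!is.finite(v)] <- -Inf
    i <- which.max(v)
    if (!is.finite(v[i]))
      stop("objective is non-finite everywhere on the current box", call. = FALSE)
    if (v[i] > best_v) { best_v <- unname(v[i]); best_x <- unname(X[i, , drop = TRUE]) }
    half <- contraction * (hi - lo) / 2
    lo <- pmax(lower, best_x - half)
    hi <- pmin(upper, best_x + half)
    if (max(hi - lo) < diameter_tol) break
  }
  list(par = best_x, value = best_v, sweeps = sweep, evaluations = evals)
}
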