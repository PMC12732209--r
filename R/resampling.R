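#' Draw a random sample from a representative point set
#'
#' Inverse-cdf sampling from the discrete law \eqn{(b_i, p_i)}: a uniform
#' variate U maps to \eqn{b_1} when \eqn{U < p_1}, to \eqn{b_2} when
#' \eqn{p_1 \le U < p_1 + p_2}, and so on.
#'
#' @param rp an [rp_set].
#' @param n sample size.
#' @param seed optional integer seed; identical seeds give identical
#'   samples and the global RNG state is untouched.
#' @return numeric vector of n draws from the point set.
#' @export
rp_draw <- function(rp, n, seed = NULL) {
  if (!inherits(rp, "rp_set")) stop("'rp' must be an rp_set", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("'n' must be a positive integer", call. = FALSE)
  cum <- cumsum(rp$probs)
  with_seed(seed, {
    u <- runif(as.integer(n))
    rp$points[findInterval(u, cum) + 1L]
  })
}

#' Resample a statistic from a representative point set
#'
#' The resampling scheme: draw a sample of size n from the discrete law of
#' the point set, compute the statistic, repeat `reps` times, and report
#' the mean of the replicate statistics as the point estimate.  One master
#' seed reproduces the whole run.
#'
#' @inheritParams rp_draw
#' @param statistic a function mapping a numeric sample to a single
#'   number.
#' @param reps number of replicates (default 1000).
#' @param true_value optional reference value; when given, the bias of
#'   the point estimate is reported.
#' @param name label for the statistic.
#' @return list of class `rp_resample`: `statistic_name`,
#'   `replicate_values`, `point_estimate` (their mean) and `bias` (or NA).
#' @export
rp_resample <- function(rp, n, statistic, reps = 1000L, seed = NULL,
                        true_value = NULL, name = deparse(substitute(statistic))) {
  if (!inherits(rp, "rp_set")) stop("'rp' must be an rp_set", call. = FALSE)
  if (!is.function(statistic)) stop("'statistic' must be a function", call. = FALSE)
  if (!is.numeric(reps) || reps < 1) stop("'reps' must be >= 1", call. = FALSE)
  reps <- as.integer(reps)
  cum <- cumsum(rp$probs)
  vals <- with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      y <- rp$points[findInterval(runif(n), cum) + 1L]
      v <- tryCatch(statistic(y), error = function(e)
        stop(sprintf("statistic failed on replicate %d: %s", r, conditionMessage(e)),
             call. = FALSE))
      as.numeric(v)
    }, numeric(1))
  })
  est <- mean(vals)
  structure(list(statistic_name = name, replicate_values = vals,
                 point_estimate = est,
                 bias = if (is.null(true_value)) NA_real_ else est - true_value),
            class = "rp_resample")
}

#' @export
print.rp_resample <- function(x, ...) {
  cat(sprintf("Resampled statistic '%s': estimate %.6g over %d replicates",
              x$statistic_name, x$point_estimate, length(x$replicate_values)))
  if (!is.na(x$bias)) cat(sprintf(" (bias %.6g)", x$bias))
  cat("\n")
  invisible(x)
}

# population-style (divide by n) sample moments used in the resampling
# comparisons; mirrors the plug-in form of the weighted RP moments.
sample_moments_pop <- function(y) {
  n <- length(y)
  m <- mean(y)
  v <- sum((y - m)^2) / n
  if (v <= 0)
    stop("degenerate sample: standardized moments are undefined for constant draws",
         call. = FALSE)
  c(mean = m, variance = v,
    skewness = sum((y - m)^3) / n / v^1.5,
    excess_kurtosis = sum((y - m)^4) / n / v^2 - 3)
}
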