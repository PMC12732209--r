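# internal helpers shared across the package

# run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched.  seed = NULL means: use the current RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

check_ig_params <- function(mu, lambda) {
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu <= 0)
    stop("'mu' must be a single positive finite number", call. = FALSE)
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) || lambda <= 0)
    stop("'lambda' must be a single positive finite number", call. = FALSE)
  invisible(TRUE)
}

check_sample <- function(x, positive = TRUE, min_n = 1L) {
  if (!is.numeric(x) || length(x) < min_n || any(!is.finite(x)))
    stop(sprintf("sample must be a finite numeric vector of length >= %d", min_n),
         call. = FALSE)
  if (positive && any(x <= 0))
    stop("all sample values must be positive", call. = FALSE)
  invisible(TRUE)
}

# normalise a parameter argument: accepts c(mu=, lambda=) or
# c(mu=, lambda=, shift=) (unnamed vectors are read positionally).
as_ig_params <- function(p) {
  if (is.list(p)) p <- unlist(p)
  if (!is.numeric(p) || !length(p) %in% c(2L, 3L))
    stop("parameters must be a numeric vector (mu, lambda) or (mu, lambda, shift)",
         call. = FALSE)
  nm <- names(p)
  if (!is.null(nm) && all(c("mu", "lambda") %in% nm)) {
    out <- c(mu = unname(p[["mu"]]), lambda = unname(p[["lambda"]]),
             shift = if ("shift" %in% nm) unname(p[["shift"]]) else 0)
  } else {
    out <- c(mu = p[[1L]], lambda = p[[2L]],
             shift = if (length(p) == 3L) p[[3L]] else 0)
  }
  check_ig_params(out[["mu"]], out[["lambda"]])
  out
}
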