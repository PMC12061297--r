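## Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the R RNG with `seed`, evaluates `expr`, then restores the caller's
#' RNG state so that seeded generators never perturb the global random stream.
#'
#' @param seed integer scalar seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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

#' Sample bimodality coefficient
#'
#' Sarle's bimodality coefficient b = (skewness^2 + 1) / kurtosis, computed
#' from moment estimators (kurtosis is the plain fourth standardized moment,
#' not excess). Values above 0.555 (the uniform-distribution reference) are
#' read as evidence of bimodality; a unimodal Gaussian gives 1/3.
#'
#' @param x numeric vector, length >= 4.
#' @return numeric scalar in (0, 1].
#' @export
#' @examples
#' bimodality_coefficient(rnorm(1000))            # ~ 1/3
#' bimodality_coefficient(c(rnorm(500, -2), rnorm(500, 2))) # > 0.555
bimodality_coefficient <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4L) stop("bimodality_coefficient() needs at least 4 finite values")
  m <- mean(x)
  d <- x - m
  m2 <- mean(d^2)
  if (m2 <= 0) stop("bimodality_coefficient() undefined for constant input")
  skew <- mean(d^3) / m2^1.5
  kurt <- mean(d^4) / m2^2
  (skew^2 + 1) / kurt
}

## stopifnot-style check with a formatted message
check_that <- function(ok, ...) {
  if (!isTRUE(ok)) stop(sprintf(...), call. = FALSE)
  invisible(TRUE)
}

## coerce to integer scalar with validation
as_count <- function(x, name, min = 1L) {
  check_that(is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min,
             "'%s' must be a single number >= %d", name, min)
  as.integer(x)
}
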