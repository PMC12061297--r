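#' Calibration between spectral fluctuation and chromatin packing scaling
#'
#' PWS microscopy encodes the local chromatin packing scaling D in the
#' standard deviation of the reference-normalized backscatter spectrum at each
#' pixel. The exact closed-form mapping depends on a priori optical parameters
#' of the instrument and on the assumed chromatin density autocorrelation
#' function, so this package treats sigma <-> D as a pluggable, strictly
#' increasing calibration on an open D domain (default (1, 3), the physical
#' range of a mass-fractal packing exponent in 3D).
#'
#' Two families are provided:
#' \describe{
#'   \item{linear}{`sigma = b * (D - 1)`; `params = c(b = ...)`, `b > 0`.}
#'   \item{power}{`sigma = a * (D - 1)^g`; `params = c(a = ..., g = ...)`,
#'     both positive.}
#' }
#'
#' @param family `"linear"` or `"power"`.
#' @param params named numeric vector of coefficients (see Details).
#' @param domain length-2 numeric, open interval of valid D values.
#' @return an object of class `calibration_model` with `$forward(d)` and
#'   `$inverse(sigma)` functions, plus `$family`, `$params`, `$domain`.
#' @export
#' @examples
#' cal <- calibration_model("linear", c(b = 0.05))
#' cal$forward(2)            # 0.05
#' cal$inverse(cal$forward(2.34))  # 2.34
calibration_model <- function(family = c("linear", "power"),
                              params = c(b = 0.05),
                              domain = c(1, 3)) {
  family <- match.arg(family)
  check_that(length(domain) == 2L && domain[1] < domain[2],
             "calibration domain must be an increasing length-2 interval")
  if (family == "linear") {
    b <- unname(params[["b"]])
    check_that(is.finite(b) && b > 0, "linear calibration needs b > 0")
    fwd <- function(d) b * (d - domain[1])
    inv <- function(s) domain[1] + s / b
  } else {
    a <- unname(params[["a"]]); g <- unname(params[["g"]])
    check_that(is.finite(a) && a > 0 && is.finite(g) && g > 0,
               "power calibration needs a > 0 and g > 0")
    fwd <- function(d) a * (d - domain[1])^g
    inv <- function(s) domain[1] + (s / a)^(1 / g)
  }
  ## monotonicity + round-trip guard on a domain grid
  grid <- seq(domain[1] + 1e-6, domain[2] - 1e-6, length.out = 101L)
  s <- fwd(grid)
  check_that(all(diff(s) > 0), "calibration must be strictly increasing on its domain")
  check_that(max(abs(inv(s) - grid)) < 1e-9,
             "calibration inverse(forward(D)) must round-trip within 1e-9")
  structure(
    list(family = family, params = params, domain = domain,
         forward = fwd, inverse = inv),
    class = "calibration_model"
  )
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("calibration_model: %s, params (%s), D domain (%g, %g)\n",
              x$family,
              paste(sprintf("%s=%g", names(x$params), x$params), collapse = ", "),
              x$domain[1], x$domain[2]))
  invisible(x)
}
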