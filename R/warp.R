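#' Sinh-arcsinh likelihood warp
#'
#' Two-parameter monotone transform used to Gaussianize skewed and
#' heavy/light-tailed residual distributions in the normative model:
#' `warp(y) = sinh(delta * asinh(y) - eps)`. `eps` controls skew,
#' `delta > 0` controls tail weight; `eps = 0, delta = 1` is the identity.
#' The warp is strictly increasing for any `delta > 0`, so deviations keep
#' their ordering in warped space.
#'
#' @param y Numeric vector, response on the standardized scale.
#' @param eps Skew parameter (dimensionless).
#' @param delta Tail-weight parameter (dimensionless, must be > 0).
#' @return `warp()` and `inverse_warp()` return a numeric vector the length
#'   of `y`; `warp_deriv()` returns the (strictly positive) derivative
#'   d warp / d y.
#' @examples
#' warp(c(-3, 0, 7), eps = 0, delta = 1)     # identity
#' inverse_warp(warp(1.3, 0.5, 1.2), 0.5, 1.2)
#' @export
warp <- function(y, eps, delta) {
  check_warp_params(eps, delta)
  sinh(delta * asinh(y) - eps)
}

#' @rdname warp
#' @export
inverse_warp <- function(y, eps, delta) {
  check_warp_params(eps, delta)
  sinh((asinh(y) + eps) / delta)
}

#' @rdname warp
#' @export
warp_deriv <- function(y, eps, delta) {
  check_warp_params(eps, delta)
  delta * cosh(delta * asinh(y) - eps) / sqrt(1 + y^2)
}

# log of warp_deriv, kept separate for numerical stability of the
# log-Jacobian term in the marginal likelihood
log_warp_deriv <- function(y, eps, delta) {
  u <- delta * asinh(y) - eps
  # log cosh(u) = |u| + log1p(exp(-2|u|)) - log 2, stable for large |u|
  log(delta) + abs(u) + log1p(exp(-2 * abs(u))) - log(2) - 0.5 * log1p(y^2)
}

check_warp_params <- function(eps, delta) {
  if (!is.numeric(eps) || !is.numeric(delta) || length(eps) != 1L ||
      length(delta) != 1L || !is.finite(eps) || !is.finite(delta))
    stop("warp parameters must be finite scalars", call. = FALSE)
  if (delta <= 0)
    stop("warp parameter `delta` must be > 0 (got ", delta, ")", call. = FALSE)
  invisible(TRUE)
}
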