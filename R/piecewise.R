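#' Knot-parameterized piecewise-linear function
#'
#' One-dimensional piecewise-linear function used throughout the package for
#' the control-policy weighting functions (distance-dependent push
#' \code{f_targ}, speed-dependent damping \code{f_vel}), the
#' signal-dependent-noise scaling \code{f_SDN}, and the decoder speed
#' transform. Evaluation interpolates linearly between knots and, by default,
#' clamps to the boundary ordinate outside the knot range (the policy
#' functions saturate, mirroring bounded neural modulation). The decoder
#' speed transform instead extrapolates its last segment; see
#' \code{\link{speed_transform}}.
#'
#' @param knots strictly increasing numeric vector of abscissae (length >= 2).
#' @param values numeric vector of ordinates, same length as \code{knots}.
#' @return an object of class \code{"piecewise_linear"}.
#' @examples
#' f <- piecewise_linear(c(0, 1, 2), c(0, 2, 2))
#' pl_eval(f, c(-1, 0.5, 3))   # 0, 1, 2 (clamped outside the range)
#' @export
piecewise_linear <- function(knots, values) {
  knots <- as.numeric(knots)
  values <- as.numeric(values)
  if (length(knots) < 2L)
    stop("piecewise_linear needs at least 2 knots", call. = FALSE)
  if (length(values) != length(knots))
    stop("'values' must match 'knots' in length", call. = FALSE)
  if (any(!is.finite(knots)) || any(!is.finite(values)))
    stop("knots and values must be finite", call. = FALSE)
  if (any(diff(knots) <= 0))
    stop("knots must be strictly increasing", call. = FALSE)
  structure(list(knots = knots, values = values), class = "piecewise_linear")
}

#' Evaluate a piecewise-linear function
#'
#' @param f a \code{\link{piecewise_linear}} object.
#' @param x numeric vector of evaluation points.
#' @param extrapolate if \code{TRUE}, the first/last segments are extended
#'   linearly beyond the knot range; the default clamps to the boundary
#'   ordinates.
#' @return numeric vector of the same length as \code{x}.
#' @export
pl_eval <- function(f, x, extrapolate = FALSE) {
  stopifnot(inherits(f, "piecewise_linear"))
  if (!extrapolate) {
    stats::approx(f$knots, f$values, xout = x, rule = 2)$y
  } else {
    K <- length(f$knots)
    y <- stats::approx(f$knots, f$values, xout = x, rule = 2)$y
    lo <- x < f$knots[1]
    hi <- x > f$knots[K]
    if (any(lo)) {
      s <- (f$values[2] - f$values[1]) / (f$knots[2] - f$knots[1])
      y[lo] <- f$values[1] + s * (x[lo] - f$knots[1])
    }
    if (any(hi)) {
      s <- (f$values[K] - f$values[K - 1]) / (f$knots[K] - f$knots[K - 1])
      y[hi] <- f$values[K] + s * (x[hi] - f$knots[K])
    }
    y
  }
}

#' @export
print.piecewise_linear <- function(x, ...) {
  cat("piecewise-linear function,", length(x$knots), "knots on [",
      x$knots[1], ",", x$knots[length(x$knots)], "]\n")
  invisible(x)
}

# Hat-function interpolation weights under the clamped convention: row t gives
# the weights w such that f(x_t) = sum_k w_k * values_k. Shared by the policy
# fit, which treats the knot ordinates as linear regression parameters.
pl_weights <- function(knots, x) {
  K <- length(knots)
  W <- matrix(0, length(x), K)
  xi <- pmin(pmax(x, knots[1]), knots[K])
  j <- findInterval(xi, knots, rightmost.closed = TRUE)
  j <- pmin(j, K - 1L)
  w <- (xi - knots[j]) / (knots[j + 1L] - knots[j])
  W[cbind(seq_along(x), j)] <- 1 - w
  W[cbind(seq_along(x), j + 1L)] <- W[cbind(seq_along(x), j + 1L)] + w
  W
}

#' Linear damping function through the origin
#'
#' Convenience constructor for a linear \code{f_vel}: value \code{slope * s}
#' over \code{[0, s_max]} (clamped beyond). The damping slope is typically
#' negative or zero.
#'
#' @param slope damping weight per unit speed.
#' @param s_max upper end of the speed range the line covers.
#' @return a \code{\link{piecewise_linear}} object.
#' @export
linear_damping <- function(slope, s_max = 50) {
  piecewise_linear(c(0, s_max), c(0, slope * s_max))
}
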