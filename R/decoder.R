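#' Static nonlinear speed transform
#'
#' A direction-preserving transform of the decoded control vector: the
#' magnitude is remapped, the direction is untouched. Three variants:
#' \describe{
#'   \item{identity}{output equals input.}
#'   \item{exponent}{\code{s_out = s_in^p}; \code{p > 1} compresses
#'     magnitudes below 1 (quieting the noise floor near rest) and expands
#'     magnitudes above 1.}
#'   \item{piecewise}{free-form piecewise-linear map given by breakpoints
#'     \code{(s_in, s_out)}; linear interpolation between breakpoints and
#'     linear extrapolation of the last segment beyond the final breakpoint,
#'     so large inputs do not hit a discontinuous ceiling.}
#' }
#' The transform operates on the normalized control vector \code{u} before
#' smoothing and gain, so its input magnitude lives on the normalized control
#' scale (full effort is about 1, which maps to terminal speed \code{beta}).
#'
#' @param variant one of \code{"identity"}, \code{"exponent"},
#'   \code{"piecewise"}.
#' @param exponent_p exponent for the exponent variant (> 0).
#' @param breakpoints two-column matrix (s_in, s_out) for the piecewise
#'   variant; s_in strictly increasing, starting at 0; s_out >= 0.
#' @return an object of class \code{"speed_transform"}.
#' @export
speed_transform <- function(variant = c("identity", "exponent", "piecewise"),
                            exponent_p = 1, breakpoints = NULL) {
  variant <- match.arg(variant)
  if (variant == "exponent") {
    if (!is.finite(exponent_p) || exponent_p <= 0)
      stop("exponent_p must be > 0", call. = FALSE)
  }
  if (variant == "piecewise") {
    breakpoints <- as.matrix(breakpoints)
    if (ncol(breakpoints) != 2L || nrow(breakpoints) < 2L)
      stop("breakpoints must be a matrix with >= 2 rows and 2 columns",
           call. = FALSE)
    if (any(diff(breakpoints[, 1]) <= 0))
      stop("breakpoint s_in values must be strictly increasing", call. = FALSE)
    if (abs(breakpoints[1, 1]) > 1e-12)
      stop("first breakpoint must have s_in = 0", call. = FALSE)
    if (any(breakpoints[, 2] < 0))
      stop("breakpoint s_out values must be >= 0", call. = FALSE)
  }
  structure(list(variant = variant, exponent_p = exponent_p,
                 breakpoints = breakpoints),
            class = "speed_transform")
}

# integer code for the C++ engine
transform_code <- function(tr) {
  switch(tr$variant, identity = 0L, exponent = 1L, piecewise = 2L)
}
transform_bk <- function(tr) {
  if (tr$variant == "piecewise") tr$breakpoints else matrix(0, 2, 2) + c(0, 1, 0, 1)
}

#' Apply a speed transform to a control vector
#'
#' Maps the magnitude of \code{u} through the transform while preserving its
#' direction; a zero vector stays zero.
#'
#' @param u numeric control vector (any dimensionality).
#' @param transform a \code{\link{speed_transform}}.
#' @return transformed vector of the same length.
#' @examples
#' apply_speed_transform(c(0.3, 0.4), speed_transform("exponent", 2))
#' @export
apply_speed_transform <- function(u, transform = speed_transform()) {
  stopifnot(inherits(transform, "speed_transform"))
  if (any(!is.finite(u))) stop("u must be finite", call. = FALSE)
  s <- sqrt(sum(u^2))
  if (s < 1e-12 || transform$variant == "identity") return(u)
  s_out <- if (transform$variant == "exponent") {
    s^transform$exponent_p
  } else {
    f <- piecewise_linear(transform$breakpoints[, 1], transform$breakpoints[, 2])
    pl_eval(f, s, extrapolate = TRUE)
  }
  u * (s_out / s)
}

#' Linear velocity decoder parameters
#'
#' Gain, exponential smoothing, time step, dimensionality, and an optional
#' static speed transform. The decoder integrates the per-step control vector
#' \code{u_t} through \code{v_{t+1} = alpha v_t + (1 - alpha) beta T(u_t)}
#' and \code{p_{t+1} = p_t + dt v_{t+1}}. With the decoding matrix normalized,
#' \code{beta} is the cursor's terminal velocity: the asymptotic speed under a
#' sustained unit-magnitude control vector.
#'
#' @param gain_beta terminal-velocity gain, workspace units per second (> 0).
#' @param smoothing_alpha exponential smoothing coefficient in [0, 1); higher
#'   values mean slower, smoother cursor responses.
#' @param dt time step in seconds (> 0).
#' @param dims workspace dimensionality (>= 1).
#' @param transform a \code{\link{speed_transform}} (default identity).
#' @return an object of class \code{"decoder_params"}.
#' @export
decoder_params <- function(gain_beta, smoothing_alpha, dt = 0.02, dims = 2L,
                           transform = speed_transform()) {
  if (!is.finite(gain_beta) || gain_beta < 0)
    stop("gain_beta must be >= 0 and finite", call. = FALSE)
  if (!is.finite(smoothing_alpha) || smoothing_alpha < 0 || smoothing_alpha >= 1)
    stop("smoothing_alpha must lie in [0, 1)", call. = FALSE)
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
  dims <- as.integer(dims)
  if (dims < 1L) stop("dims must be >= 1", call. = FALSE)
  stopifnot(inherits(transform, "speed_transform"))
  structure(list(gain_beta = gain_beta, smoothing_alpha = smoothing_alpha,
                 dt = dt, dims = dims, transform = transform),
            class = "decoder_params")
}

#' @export
print.decoder_params <- function(x, ...) {
  cat(sprintf("decoder: beta = %g u/s, alpha = %g, dt = %g s, dims = %d, transform = %s\n",
              x$gain_beta, x$smoothing_alpha, x$dt, x$dims, x$transform$variant))
  invisible(x)
}

#' One decoder step
#'
#' Advances the cursor state by one time step under control input \code{u}:
#' the transformed input is smoothed into the velocity and the updated
#' velocity is integrated into the position.
#'
#' @param state list with numeric \code{position} and \code{velocity} vectors
#'   of length \code{params$dims}.
#' @param u control vector.
#' @param params a \code{\link{decoder_params}}.
#' @return the updated state (same structure).
#' @export
decoder_step <- function(state, u, params) {
  if (any(!is.finite(u)) || any(!is.finite(state$position)) ||
      any(!is.finite(state$velocity)))
    stop("decoder_step: non-finite state or input", call. = FALSE)
  Tu <- apply_speed_transform(u, params$transform)
  v <- params$smoothing_alpha * state$velocity +
    (1 - params$smoothing_alpha) * params$gain_beta * Tu
  list(position = state$position + params$dt * v, velocity = v)
}

#' State-space form of the decoder dynamics
#'
#' Block matrices (A, B) such that one application of
#' \code{x' = A x + B u} to the stacked state \code{x = c(position, velocity)}
#' reproduces one \code{\link{decoder_step}} exactly (identity transform).
#' The forward model of the simulated user runs these matrices.
#'
#' @param params a \code{\link{decoder_params}}.
#' @return list with matrices \code{A} (2d x 2d) and \code{B} (2d x d).
#' @export
build_state_space <- function(params) {
  d <- params$dims
  a <- params$smoothing_alpha
  b <- params$gain_beta
  dt <- params$dt
  I <- diag(d)
  A <- rbind(cbind(I, dt * a * I), cbind(matrix(0, d, d), a * I))
  B <- rbind(dt * (1 - a) * b * I, (1 - a) * b * I)
  list(A = A, B = B)
}

#' Decoder gain in target distances per second
#'
#' Rescales the terminal-velocity gain into the task-relative unit used when
#' comparing conditions across tasks: target distances per second (TD/s).
#'
#' @param params a \code{\link{decoder_params}}.
#' @param target_distance distance to the target in workspace units (> 0).
#' @return \code{gain_beta / target_distance}.
#' @export
gain_in_td_per_s <- function(params, target_distance) {
  if (!is.finite(target_distance) || target_distance <= 0)
    stop("target_distance must be > 0", call. = FALSE)
  params$gain_beta / target_distance
}
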