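#' Control policy of the simulated user
#'
#' The user's per-step control vector is the sum of a pushing component — a
#' unit vector at the target weighted by \code{f_targ} evaluated at the
#' estimated distance to target — and a damping component — a unit vector
#' along the estimated heading weighted by \code{f_vel} evaluated at the
#' estimated speed. \code{f_vel} is typically negative: it slows the cursor
#' to avoid overshooting.
#'
#' @param f_targ \code{\link{piecewise_linear}} over distance-to-target
#'   (workspace units) -> control magnitude; values must be >= 0.
#' @param f_vel \code{\link{piecewise_linear}} over estimated speed
#'   (units/s) -> signed damping weight (typically <= 0).
#' @return an object of class \code{"control_policy"}.
#' @export
control_policy <- function(f_targ, f_vel) {
  stopifnot(inherits(f_targ, "piecewise_linear"),
            inherits(f_vel, "piecewise_linear"))
  if (any(f_targ$values < 0))
    stop("f_targ values must be >= 0", call. = FALSE)
  structure(list(f_targ = f_targ, f_vel = f_vel), class = "control_policy")
}

#' Autoregressive decoding-noise model
#'
#' Decoding error \code{e_t = Pi_1 e_{t-1} + ... + Pi_p e_{t-p} + eps_t} with
#' \code{eps_t ~ N(0, f_SDN(||c_t||) * innovation_cov)}. The AR matrices
#' shape the frequency content of the noise; the optional signal-dependent
#' scaling \code{sdn_fn} lets the innovation variance grow (or shrink) with
#' the commanded control magnitude.
#'
#' @param n_lags AR order p (>= 0).
#' @param ar_coeffs list of \code{n_lags} (dims x dims) matrices.
#' @param innovation_cov symmetric positive semi-definite (dims x dims)
#'   covariance of the innovations.
#' @param sdn_fn \code{\link{piecewise_linear}} over \code{||c_t||} giving a
#'   nonnegative variance scale, or \code{NULL} for a constant scale of 1.
#' @return an object of class \code{"noise_model"}.
#' @export
noise_model <- function(n_lags = 0L, ar_coeffs = list(),
                        innovation_cov, sdn_fn = NULL) {
  n_lags <- as.integer(n_lags)
  if (n_lags < 0L) stop("n_lags must be >= 0", call. = FALSE)
  innovation_cov <- as.matrix(innovation_cov)
  d <- nrow(innovation_cov)
  if (ncol(innovation_cov) != d ||
      max(abs(innovation_cov - t(innovation_cov))) > 1e-8 * (1 + max(abs(innovation_cov))))
    stop("innovation_cov must be a symmetric square matrix", call. = FALSE)
  ev <- eigen((innovation_cov + t(innovation_cov)) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1))
    stop("innovation_cov must be positive semi-definite", call. = FALSE)
  if (length(ar_coeffs) != n_lags)
    stop("ar_coeffs must contain n_lags matrices", call. = FALSE)
  ar_coeffs <- lapply(ar_coeffs, function(m) {
    m <- as.matrix(m)
    if (!all(dim(m) == d)) stop("AR matrices must be dims x dims", call. = FALSE)
    m
  })
  if (!is.null(sdn_fn)) {
    stopifnot(inherits(sdn_fn, "piecewise_linear"))
    if (any(sdn_fn$values < 0))
      stop("sdn_fn values must be >= 0", call. = FALSE)
  }
  if (n_lags > 0L) {
    sr <- ar_spectral_radius(ar_coeffs, d)
    if (sr >= 1)
      warning(sprintf("AR companion spectral radius %.3f >= 1: noise process is non-stationary", sr))
  }
  structure(list(n_lags = n_lags, ar_coeffs = ar_coeffs,
                 innovation_cov = innovation_cov, sdn_fn = sdn_fn,
                 dims = d),
            class = "noise_model")
}

ar_spectral_radius <- function(ar_coeffs, d) {
  p <- length(ar_coeffs)
  if (p == 0L) return(0)
  C <- matrix(0, d * p, d * p)
  for (i in seq_len(p)) C[1:d, ((i - 1) * d + 1):(i * d)] <- ar_coeffs[[i]]
  if (p > 1L) C[(d + 1):(d * p), 1:(d * (p - 1))] <- diag(d * (p - 1))
  max(Mod(eigen(C, only.values = TRUE)$values))
}

# stacked (d x d*n_lags) AR matrix and innovation chol factor for the engine
noise_engine_args <- function(noise, dims) {
  if (is.null(noise)) {
    return(list(n_lags = 0L, Pi = matrix(0, dims, dims),
                cholL = matrix(0, dims, dims),
                sdnk = c(0, 1), sdnv = c(1, 1), sdn_on = FALSE))
  }
  Pi <- if (noise$n_lags > 0L) do.call(cbind, noise$ar_coeffs) else matrix(0, dims, dims)
  cholL <- if (max(abs(noise$innovation_cov)) == 0) {
    matrix(0, dims, dims)
  } else {
    t(chol(noise$innovation_cov + diag(1e-14, dims)))
  }
  if (is.null(noise$sdn_fn)) {
    list(n_lags = noise$n_lags, Pi = Pi, cholL = cholL,
         sdnk = c(0, 1), sdnv = c(1, 1), sdn_on = FALSE)
  } else {
    list(n_lags = noise$n_lags, Pi = Pi, cholL = cholL,
         sdnk = noise$sdn_fn$knots, sdnv = noise$sdn_fn$values, sdn_on = TRUE)
  }
}

#' Simulated iBCI user
#'
#' Bundles the control policy, the decoding-noise model, and the visual
#' feedback delay \code{tau} (in time steps). At each step the user sees the
#' true cursor state \code{tau} steps ago and runs a forward model of the
#' decoder dynamics — seeded with that delayed state and efference copies of
#' its own recent control vectors — to estimate the current state, on which
#' the control policy acts.
#'
#' @param policy a \code{\link{control_policy}}.
#' @param noise a \code{\link{noise_model}} or \code{NULL} for a noiseless user.
#' @param delay_tau feedback delay in time steps (>= 0).
#' @return an object of class \code{"user_model"}.
#' @export
user_model <- function(policy, noise = NULL, delay_tau = 10L) {
  stopifnot(inherits(policy, "control_policy"))
  delay_tau <- as.integer(delay_tau)
  if (delay_tau < 0L) stop("delay_tau must be >= 0", call. = FALSE)
  if (!is.null(noise)) stopifnot(inherits(noise, "noise_model"))
  structure(list(policy = policy, noise = noise, delay_tau = delay_tau),
            class = "user_model")
}

#' @export
print.user_model <- function(x, ...) {
  cat(sprintf("PLM user: tau = %d steps, AR order = %s, SDN = %s\n",
              x$delay_tau,
              if (is.null(x$noise)) "none" else x$noise$n_lags,
              if (is.null(x$noise) || is.null(x$noise$sdn_fn)) "off" else "on"))
  invisible(x)
}

#' Task specification for target acquisition
#'
#' Target geometry and acquisition rules: a target is acquired by holding the
#' cursor in unbroken contact with it (center within target radius + cursor
#' radius) for \code{dwell_s}; a trial fails when \code{max_trial_s} elapses
#' first, after which the cursor is reset to the target position for the next
#' trial.
#'
#' @param target_generator function \code{(trial_index, start_position)}
#'   returning \code{list(target = numeric, radius = numeric)}; see
#'   \code{\link{center_out_targets}} and \code{\link{random_targets}}.
#' @param cursor_radius cursor radius added to the target radius for contact.
#' @param dwell_s required unbroken-contact duration, seconds.
#' @param max_trial_s maximum movement time, seconds.
#' @param inter_trial_s pause between trials (bookkeeping only), seconds.
#' @param workspace_bounds optional \code{c(lo, hi)} square bound applied to
#'   every coordinate (used by keyboard simulations); \code{NULL} leaves the
#'   workspace unbounded.
#' @return an object of class \code{"task_spec"}.
#' @export
task_spec <- function(target_generator, cursor_radius = 0, dwell_s = 0.5,
                      max_trial_s = 10, inter_trial_s = 0,
                      workspace_bounds = NULL) {
  stopifnot(is.function(target_generator))
  if (dwell_s <= 0 || max_trial_s <= 0 || dwell_s >= max_trial_s)
    stop("need 0 < dwell_s < max_trial_s", call. = FALSE)
  if (cursor_radius < 0) stop("cursor_radius must be >= 0", call. = FALSE)
  structure(list(target_generator = target_generator,
                 cursor_radius = cursor_radius, dwell_s = dwell_s,
                 max_trial_s = max_trial_s, inter_trial_s = inter_trial_s,
                 workspace_bounds = workspace_bounds),
            class = "task_spec")
}

#' Center-out-and-back target generator
#'
#' Targets alternate between one of \code{n_directions} radially spaced outer
#' locations at the given distance from the origin and the center of the
#' workspace, as in a standard center-out-and-back task.
#'
#' @param distance distance of the outer targets from the center.
#' @param radius target radius.
#' @param n_directions number of outer directions (evenly spaced).
#' @return a target-generator function for \code{\link{task_spec}}.
#' @export
center_out_targets <- function(distance, radius, n_directions = 8L) {
  force(distance); force(radius); force(n_directions)
  function(trial_index, start_position) {
    if (trial_index %% 2L == 1L) {
      k <- ((trial_index - 1L) %/% 2L) %% n_directions
      th <- 2 * pi * k / n_directions
      list(target = distance * c(cos(th), sin(th)), radius = radius)
    } else {
      list(target = c(0, 0), radius = radius)
    }
  }
}

#' Uniform random target generator
#'
#' Draws each target uniformly in a square workspace, re-drawing until it
#' does not overlap the cursor's current position; the radius is sampled
#' uniformly from \code{radii}.
#'
#' @param half_width half-width of the square workspace.
#' @param radii candidate target radii.
#' @return a target-generator function for \code{\link{task_spec}}.
#' @export
random_targets <- function(half_width, radii) {
  force(half_width); force(radii)
  function(trial_index, start_position) {
    r <- if (length(radii) == 1L) radii else sample(radii, 1L)
    repeat {
      g <- stats::runif(length(start_position), -half_width, half_width)
      if (sqrt(sum((g - start_position)^2)) > r) break
    }
    list(target = g, radius = r)
  }
}

#' Fixed-list target generator
#'
#' Cycles through a fixed list of \code{(target, radius)} pairs.
#'
#' @param targets matrix with one target position per row.
#' @param radii vector of radii, recycled to \code{nrow(targets)}.
#' @return a target-generator function for \code{\link{task_spec}}.
#' @export
fixed_targets <- function(targets, radii) {
  targets <- as.matrix(targets)
  radii <- rep_len(radii, nrow(targets))
  function(trial_index, start_position) {
    i <- ((trial_index - 1L) %% nrow(targets)) + 1L
    list(target = as.numeric(targets[i, ]), radius = radii[i])
  }
}
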