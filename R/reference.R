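#' Reference synthetic study conditions
#'
#' A canonical ground-truth user, decoder, and task on a target-distance
#' normalized workspace (the outer-target distance is 1 unit, so decoder
#' gains are directly in target distances per second). These are the
#' conditions the package's synthetic experiments run under:
#' \describe{
#'   \item{user}{saturating f_targ (full effort beyond ~20\% of the target
#'     distance), linear velocity damping with slope \code{fvel_slope},
#'     feedback delay \code{tau} steps, AR(1) decoding noise with
#'     coefficient \code{ar_coef} and innovation SD \code{innovation_sd}
#'     per dimension (a signal-independent noise floor unless an
#'     \code{sdn_fn} is supplied).}
#'   \item{decoder}{gain 0.8 TD/s, smoothing 0.9, 20 ms steps.}
#'   \item{task}{center-out-and-back to 8 directions at distance 1, target
#'     radius 0.1, 0.5 s dwell, 10 s timeout.}
#' }
#'
#' @param fvel_slope ground-truth damping slope (per unit speed).
#' @param tau feedback delay in steps.
#' @param ar_coef AR(1) coefficient of the decoding noise (isotropic).
#' @param innovation_sd innovation SD per dimension.
#' @param sdn_fn optional \code{\link{piecewise_linear}} signal-dependent
#'   variance scaling.
#' @param n_lags AR order. Order 1 uses \code{ar_coef}; order 2 uses the
#'   damped-oscillatory pair (0.8, -0.25), which keeps the noise correlation
#'   time short (root modulus 0.5) and the stationary SD comparable to the
#'   AR(1) default — decoding noise is correlated over tenths of a second,
#'   not a slow drift.
#' @return \code{reference_user}: a \code{\link{user_model}};
#'   \code{reference_decoder}: a \code{\link{decoder_params}};
#'   \code{reference_task}: a \code{\link{task_spec}}.
#' @export
reference_user <- function(fvel_slope = -1, tau = 10L, ar_coef = 0.6,
                           innovation_sd = 0.15, sdn_fn = NULL,
                           n_lags = 1L) {
  pol <- control_policy(
    piecewise_linear(c(0, 0.2, 1.2), c(0, 1, 1.05)),
    linear_damping(fvel_slope, 5))
  noise <- if (innovation_sd > 0 || n_lags > 0L) {
    ar <- if (n_lags == 2L) {
      list(0.8 * diag(2), -0.25 * diag(2))
    } else {
      lapply(seq_len(n_lags), function(i) ar_coef / 2^(i - 1) * diag(2))
    }
    noise_model(n_lags, ar, innovation_sd^2 * diag(2), sdn_fn)
  }
  user_model(pol, noise, tau)
}

#' @rdname reference_user
#' @param gain_beta,smoothing_alpha decoder settings (TD/s and unitless).
#' @param transform a \code{\link{speed_transform}}.
#' @export
reference_decoder <- function(gain_beta = 0.8, smoothing_alpha = 0.9,
                              transform = speed_transform()) {
  decoder_params(gain_beta, smoothing_alpha, dt = 0.02, dims = 2L,
                 transform = transform)
}

#' @rdname reference_user
#' @param radius target radius in target-distance units.
#' @param dwell_s,max_trial_s acquisition rules in seconds.
#' @export
reference_task <- function(radius = 0.1, dwell_s = 0.5, max_trial_s = 10) {
  task_spec(center_out_targets(distance = 1, radius = radius),
            cursor_radius = 0, dwell_s = dwell_s, max_trial_s = max_trial_s)
}
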