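#' Adaptation search configuration
#'
#' The user-adaptation model assumes that, faced with new gain/smoothing
#' settings, the user rapidly re-tunes only their velocity damping: f_vel is
#' replaced by a line through the origin whose slope is chosen, by brute
#' force over a grid, to minimize a simulated objective under the new
#' settings. No held-out data is used — only simulation from the fitted
#' model.
#'
#' @param slope_grid candidate damping slopes (default 0 to -3 in steps of
#'   -0.1, 31 values).
#' @param n_sims_per_slope simulated trials per candidate slope.
#' @param objective \code{"movement_time"} (mean movement time; timed-out
#'   trials are scored at the maximum trial duration so that failures are
#'   penalized rather than dropped).
#' @return an object of class \code{"adaptation_config"}.
#' @export
adaptation_config <- function(slope_grid = seq(0, -3, by = -0.1),
                              n_sims_per_slope = 100L,
                              objective = "movement_time") {
  stopifnot(length(slope_grid) >= 1L, all(is.finite(slope_grid)),
            n_sims_per_slope >= 1L)
  structure(list(slope_grid = slope_grid,
                 n_sims_per_slope = as.integer(n_sims_per_slope),
                 objective = objective),
            class = "adaptation_config")
}

# censored mean movement time: timeouts count at max_trial_s
censored_movement_time <- function(session) {
  vapply(session$trials, function(tr) {
    if (tr$outcome == "success") tr$t_acquire else tr$time[length(tr$time)]
  }, numeric(1))
}

#' Re-adapt the user's velocity damping to a decoder/task condition
#'
#' Returns a copy of \code{user} whose f_vel is linear through the origin
#' with the grid slope that minimizes the mean simulated movement time under
#' \code{decoder} and \code{task}. Common random numbers (the same seed for
#' every candidate slope) de-noise the comparison; ties are broken toward
#' the slope closest to zero. f_targ and the noise model are unchanged.
#'
#' @param user a \code{\link{user_model}}.
#' @param decoder a \code{\link{decoder_params}}.
#' @param task a \code{\link{task_spec}}.
#' @param cfg an \code{\link{adaptation_config}}.
#' @param seed integer seed (shared across slopes).
#' @return the adapted \code{\link{user_model}}, with attributes
#'   \code{"slope"} and \code{"objective_curve"}.
#' @export
adapt_damping <- function(user, decoder, task, cfg = adaptation_config(),
                          seed = 1L) {
  s_max <- max(user$policy$f_vel$knots[length(user$policy$f_vel$knots)],
               2 * decoder$gain_beta, 1)
  obj <- vapply(cfg$slope_grid, function(sl) {
    cand <- user
    cand$policy$f_vel <- linear_damping(sl, s_max)
    ses <- simulate_condition(cand, decoder, task, cfg$n_sims_per_slope,
                              seed = seed)
    mean(censored_movement_time(ses))
  }, numeric(1))
  best <- which(obj <= min(obj) + 1e-12)
  best <- best[which.min(abs(cfg$slope_grid[best]))]
  out <- user
  out$policy$f_vel <- linear_damping(cfg$slope_grid[best], s_max)
  attr(out, "slope") <- cfg$slope_grid[best]
  attr(out, "objective_curve") <- data.frame(slope = cfg$slope_grid,
                                             objective = obj)
  out
}
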