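#' Forward-model estimate of the current cursor state
#'
#' The simulated user's internal state estimate: start from the true state
#' \code{tau} steps ago (perfect but delayed visual feedback), then run the
#' decoder dynamics forward using efference copies of the user's own recent
#' control vectors,
#' \code{x_hat_t = A^tau x_{t-tau} + sum_{i=0}^{tau-1} A^i B c_{t-i-1}}.
#' Because the efference copies lack the decoding noise, the estimate differs
#' from the true state whenever noise is present — the user can only
#' counteract noise perturbations \code{tau} steps after they occur.
#'
#' Histories shorter than \code{tau} are padded at the front with their first
#' entry (states) and zero vectors (controls).
#'
#' @param state_history list of states \code{list(position, velocity)},
#'   oldest first, last entry being the current true state.
#' @param control_history list of control vectors, oldest first, last entry
#'   being \code{c_{t-1}}; must be one shorter than \code{state_history}.
#' @param tau feedback delay in steps.
#' @param ss state-space matrices from \code{\link{build_state_space}}.
#' @return list with \code{p_hat} and \code{v_hat}.
#' @export
estimate_internal_state <- function(state_history, control_history, tau, ss) {
  n <- length(state_history)
  stopifnot(n >= 1L, tau >= 0L)
  d <- length(state_history[[1]]$position)
  if (n <= tau) {  # pad with the initial state and zero controls
    pad <- tau - n + 1L
    state_history <- c(rep(state_history[1], pad), state_history)
    control_history <- c(rep(list(numeric(d)), pad), control_history)
    n <- n + pad
  }
  xd <- c(state_history[[n - tau]]$position, state_history[[n - tau]]$velocity)
  Ak <- diag(2 * d)
  acc <- numeric(2 * d)
  nc <- length(control_history)
  for (i in seq_len(tau)) {  # i-th term uses c_{t-i}
    acc <- acc + Ak %*% (ss$B %*% control_history[[nc - i + 1L]])
    Ak <- Ak %*% ss$A
  }
  xhat <- Ak %*% xd + acc   # Ak == A^tau after the loop
  list(p_hat = as.numeric(xhat[1:d]), v_hat = as.numeric(xhat[(d + 1):(2 * d)]))
}

#' Control vector from the piecewise-linear policy
#'
#' \code{c = dir(target - p_hat) f_targ(||target - p_hat||) +
#' dir(v_hat) f_vel(||v_hat||)}. Either term is the zero vector when its
#' governing magnitude is below 1e-9, where the unit vectors are undefined.
#'
#' @param target target position.
#' @param p_hat,v_hat internal estimates of cursor position and velocity.
#' @param policy a \code{\link{control_policy}}.
#' @return the control vector.
#' @export
compute_control <- function(target, p_hat, v_hat, policy) {
  stopifnot(all(is.finite(target)), all(is.finite(p_hat)), all(is.finite(v_hat)))
  d <- length(target)
  cvec <- numeric(d)
  dv <- target - p_hat
  dn <- sqrt(sum(dv^2))
  if (dn >= 1e-9) cvec <- cvec + (dv / dn) * pl_eval(policy$f_targ, dn)
  sn <- sqrt(sum(v_hat^2))
  if (sn >= 1e-9) cvec <- cvec + (v_hat / sn) * pl_eval(policy$f_vel, sn)
  cvec
}

#' Draw one decoding-noise sample
#'
#' \code{e_t = sum_i Pi_i e_{t-i} + eps_t} with
#' \code{eps_t ~ N(0, f_SDN(||c||) innovation_cov)}. Uses R's RNG, so the
#' draw is deterministic under \code{set.seed}.
#'
#' @param noise a \code{\link{noise_model}}.
#' @param e_history list of past noise vectors, oldest first (padded with
#'   zeros if shorter than \code{n_lags}).
#' @param c the commanded control vector at this step (for the
#'   signal-dependent scale).
#' @return the noise vector.
#' @export
sample_noise <- function(noise, e_history, c) {
  d <- noise$dims
  scale <- if (is.null(noise$sdn_fn)) 1 else
    max(pl_eval(noise$sdn_fn, sqrt(sum(c^2))), 0)
  Sig <- scale * noise$innovation_cov
  ev <- eigen((Sig + t(Sig)) / 2, symmetric = TRUE)
  if (min(ev$values) < -1e-10 * max(abs(ev$values), 1))
    stop("scaled innovation covariance is not PSD", call. = FALSE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), d) %*% t(ev$vectors)
  e <- as.numeric(L %*% stats::rnorm(d))
  n <- length(e_history)
  for (i in seq_len(noise$n_lags)) {
    ei <- if (n - i + 1L >= 1L) e_history[[n - i + 1L]] else numeric(d)
    e <- e + as.numeric(noise$ar_coeffs[[i]] %*% ei)
  }
  e
}

#' Simulate one closed-loop target-acquisition trial
#'
#' Runs the full loop at each step: delayed feedback -> forward-model state
#' estimate -> control policy -> AR decoding noise -> decoder output
#' \code{u = c + e} -> decoder dynamics (with any speed transform) ->
#' contact/dwell bookkeeping. Contact means the cursor center is within
#' target radius + cursor radius; success requires unbroken contact for
#' \code{dwell_s}; otherwise the trial times out at \code{max_trial_s}.
#'
#' @param user a \code{\link{user_model}}.
#' @param decoder a \code{\link{decoder_params}}.
#' @param task a \code{\link{task_spec}}.
#' @param start list with \code{position} and \code{velocity}.
#' @param target target position vector.
#' @param radius target radius.
#' @param ar_burnin AR-noise warm-up steps before the trial starts.
#' @return an object of class \code{"trial_record"}: per-step matrices
#'   \code{pos}, \code{vel}, \code{u}, \code{c}, \code{e}, a contact flag
#'   vector, the outcome (\code{"success"} or \code{"timeout"}), and the
#'   event times \code{t_first_contact} and \code{t_acquire} (NA if absent).
#' @export
simulate_trial <- function(user, decoder, task, start, target, radius,
                           ar_burnin = 100L) {
  d <- decoder$dims
  stopifnot(length(target) == d, length(start$position) == d)
  ne <- noise_engine_args(user$noise, d)
  tr <- decoder$transform
  bk <- transform_bk(tr)
  ws <- task$workspace_bounds
  res <- cpp_simulate_trial(
    start$position, start$velocity, target, radius + task$cursor_radius,
    user$policy$f_targ$knots, user$policy$f_targ$values,
    user$policy$f_vel$knots, user$policy$f_vel$values,
    ne$n_lags, ne$Pi, ne$cholL, ne$sdnk, ne$sdnv, ne$sdn_on,
    user$delay_tau, decoder$smoothing_alpha, decoder$gain_beta, decoder$dt,
    transform_code(tr), tr$exponent_p, bk[, 1], bk[, 2],
    max_steps = as.integer(round(task$max_trial_s / decoder$dt)),
    dwell_steps = as.integer(ceiling(task$dwell_s / decoder$dt - 1e-9)),
    burnin = as.integer(ar_burnin),
    mode = 0L, key_origin = 0, key_w = 1, n_side = 1L,
    clamp_ws = !is.null(ws), ws_lo = if (is.null(ws)) 0 else ws[1],
    ws_hi = if (is.null(ws)) 0 else ws[2])
  structure(list(
    time = seq(0, by = decoder$dt, length.out = res$n_steps + 1L),
    pos = res$pos, vel = res$vel, u = res$u, c = res$c, e = res$e,
    contact = as.logical(res$contact),
    target = target, radius = radius,
    effective_radius = radius + task$cursor_radius,
    outcome = if (res$outcome == 1L) "success" else "timeout",
    t_first_contact = res$t_first_contact, t_acquire = res$t_acquire,
    dwell_s = task$dwell_s, dt = decoder$dt,
    start = start$position), class = "trial_record")
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("trial: %s, %d steps, first contact %s s, acquired %s s\n",
              x$outcome, length(x$time) - 1L,
              format(x$t_first_contact), format(x$t_acquire)))
  invisible(x)
}

# deterministic per-trial child seeds: trial k reproducible independent of order
trial_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate a block of independent trials under one condition
#'
#' Generates \code{n_trials} target-acquisition trials with per-trial seeded
#' RNG streams (trial k is reproducible independently of the others) and a
#' 100-step AR-noise burn-in per trial. Each trial starts at rest at the
#' previous trial's target position (the cursor reset rule); trial 1 starts
#' at the workspace origin.
#'
#' @param user a \code{\link{user_model}}.
#' @param decoder a \code{\link{decoder_params}}.
#' @param task a \code{\link{task_spec}}.
#' @param n_trials number of trials (>= 1).
#' @param seed integer seed for the block.
#' @return an object of class \code{"simulated_session"}: list of
#'   \code{\link{simulate_trial}} records plus the condition.
#' @export
simulate_condition <- function(user, decoder, task, n_trials, seed = 1L) {
  stopifnot(n_trials >= 1L)
  seeds <- trial_seeds(seed, n_trials)
  d <- decoder$dims
  start_pos <- numeric(d)
  trials <- vector("list", n_trials)
  for (k in seq_len(n_trials)) {
    set.seed(seeds[k])
    tg <- task$target_generator(k, start_pos)
    trials[[k]] <- simulate_trial(user, decoder, task,
                                  start = list(position = start_pos,
                                               velocity = numeric(d)),
                                  target = tg$target, radius = tg$radius)
    start_pos <- tg$target
  }
  structure(list(trials = trials, user = user, decoder = decoder,
                 task = task, seed = seed), class = "simulated_session")
}

#' @export
print.simulated_session <- function(x, ...) {
  ns <- sum(vapply(x$trials, function(t) t$outcome == "success", logical(1)))
  cat(sprintf("simulated session: %d trials (%d successes), beta = %g, alpha = %g\n",
              length(x$trials), ns, x$decoder$gain_beta, x$decoder$smoothing_alpha))
  invisible(x)
}
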