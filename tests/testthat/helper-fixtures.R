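# shared fixtures: small users/tasks on the normalized (target distance = 1)
# workspace so tests stay fast

# saturating push, no damping, no noise — moves straight at the target
noiseless_user <- function(tau = 0L, fvel_slope = 0) {
  user_model(
    control_policy(piecewise_linear(c(0, 0.05, 1.2), c(0, 1, 1)),
                   linear_damping(fvel_slope, 5)),
    noise = NULL, delay_tau = tau)
}

quick_task <- function(radius = 0.1, dwell_s = 0.3, max_trial_s = 6) {
  task_spec(center_out_targets(distance = 1, radius = radius),
            dwell_s = dwell_s, max_trial_s = max_trial_s)
}

# one long noise-only record: zero policy, zero gain; returns the e series
noise_series <- function(noise, n_steps, seed = 1L, burnin = 100L) {
  pol <- control_policy(piecewise_linear(c(0, 1), c(0, 0)),
                        linear_damping(0))
  u <- user_model(pol, noise, delay_tau = 0L)
  dec <- decoder_params(1e-9, 0, dt = 0.02)
  task <- task_spec(function(k, s) list(target = c(50, 0), radius = 0.1),
                    dwell_s = 0.02, max_trial_s = n_steps * 0.02 + 1)
  set.seed(seed)
  tr <- simulate_trial(u, dec, task, list(position = c(0, 0),
                                          velocity = c(0, 0)),
                       target = c(50, 0), radius = 0.1, ar_burnin = burnin)
  tr$e[seq_len(n_steps), , drop = FALSE]
}

slope_of <- function(pl) {
  K <- length(pl$knots)
  (pl$values[K] - pl$values[1]) / (pl$knots[K] - pl$knots[1])
}
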