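# plmbci

Simulation, fitting, and optimization of closed-loop intracortical
brain-computer interface (iBCI) cursor control, built around a
piecewise-linear feedback-control model (PLM) of the user.

## The problem

A linear velocity iBCI decoder has two settings that dominate online
performance: the output gain β (the cursor's terminal speed under full
effort) and the exponential smoothing α,

    v[t+1] = α v[t] + (1 − α) β T(u[t]),      p[t+1] = p[t] + Δt v[t+1],

with `u` the decoded control vector and `T` an optional static speed
transform. Offline calibration does not choose β and α well, because it
ignores the closed loop of user, decoder, and task. `plmbci` models that
loop explicitly. The simulated user

* sees the cursor state with a feedback delay of τ steps and estimates the
  current state with a forward model of the decoder dynamics plus
  efference copies of its own recent commands;
* emits a control vector `c = dir(target − p̂)·f_targ(‖target − p̂‖) +
  dir(v̂)·f_vel(‖v̂‖)` — a piecewise-linear push toward the target plus
  piecewise-linear (negative) velocity damping;
* is corrupted by decoding noise `e` from a vector AR(p) Gaussian process,
  optionally with signal-dependent variance `f_SDN(‖c‖)`, so that the
  decoder input is `u = c + e`.

The model is fit to a few minutes of closed-loop data from a single
condition (`fit_user_model`), predicts performance under held-out gains,
smoothings, target distances and radii (`predict_conditions`, with a
simulation-based model of how the user re-adapts their damping), and
drives decoder optimization: gain × smoothing performance surfaces
(`sweep_surface`), dwell-time selection for a 36-key keyboard by achieved
bit rate (`optimize_keyboard`), and nonlinear speed transforms — exponent
`s^p` or 14-breakpoint piecewise-linear — that quiet the noise floor near
rest while preserving fast travel (`optimize_speed_transform`). A
calibration benchmark (`recalibration_loop`) shows why this matters:
velocity-Kalman recalibration with intention re-estimation drifts the
effective gain down and smoothing up without ever reaching the
sweep-optimal setting.

## Worked example

Fit a user model to one synthetic closed-loop block and predict two
held-out gain conditions:

```r
library(plmbci)

truth <- reference_user()       # ground truth: damping slope -1, tau = 10,
dec   <- reference_decoder()    # AR(1) noise; trained at beta = 0.8 TD/s,
task  <- reference_task()       # alpha = 0.9, 8-direction center-out task

ses <- simulate_condition(truth, dec, task, n_trials = 100, seed = 11)
fit <- fit_user_model(ses, fit_config(delay_tau = "grid"))
fit
#> PLM fit: tau = 10 steps, AR order = 1, final policy R^2 = 0.793
#> innovation sd per dim: 0.151, 0.149

conds <- list(list(decoder = reference_decoder(0.4, 0.9), task = task),
              list(decoder = reference_decoder(1.6, 0.9), task = task))
pr <- predict_conditions(fit, conds, n_sims = 300, seed = 2)
pr[, c("gain_beta", "movement_time", "translation_time", "dial_in_time")]
#>   gain_beta movement_time translation_time dial_in_time
#> 1       0.4      3.064067        2.5640667 1.480297e-18
#> 2       1.6      1.426800        0.8390667 8.773333e-02
```

The fitter recovers the generator: the feedback delay (10 steps = 200 ms)
is found by a residual-whiteness grid search, the AR order by
cross-validation, and the innovation SD (true value 0.15) to a few
percent. The predictions show the canonical trade-off: at low gain the
cursor is slow to reach the target (long translation time); at high gain
it arrives three times faster but pays with a nonzero dial-in time — time
spent fighting the noise to stay on the target.

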