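---
title: "Modelling closed-loop iBCI cursor control with plmbci"
author: "plmbci authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling closed-loop iBCI cursor control with plmbci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plmbci)
```

## The problem

Intracortical brain-computer interfaces (iBCIs) decode motor-cortex
activity into cursor velocity. Two decoder settings dominate the feel and
performance of such a system: the output **gain** β (how fast the cursor
can go) and the exponential **smoothing** α (how sluggishly it responds).
Standard decoder calibration optimizes offline reconstruction error, which
says nothing about how the *closed loop* of user, decoder, and task will
behave — so in practice these knobs are tuned by online trial and error.

`plmbci` implements a user-specific simulator of that closed loop: a
piecewise-linear feedback-control model (PLM) of the user that can be fit
to a few minutes of closed-loop data from one condition and then used to
*predict* performance under different gains, smoothings, target sizes and
distances — and, by extension, to optimize those settings offline.

## The model

The decoder is a linear velocity decoder with exponential smoothing,

$$v_{t+1} = \alpha v_t + (1-\alpha)\,\beta\, T(u_t), \qquad
  p_{t+1} = p_t + \Delta t\, v_{t+1},$$

where $u_t$ is the normalized decoded control vector, $T$ an optional
static speed transform (identity by default), and β is normalized to be the
cursor's *terminal velocity*: the asymptotic speed under a sustained
unit-magnitude control. In state-space form $x_t = A x_{t-1} + B u_t$ with
$x = (p, v)$; `build_state_space()` constructs $(A, B)$ and one application
equals one `decoder_step()` exactly.

The simulated user decomposes the decoder output into intent plus decoding
error, $u_t = c_t + e_t$:

* **Control policy.** $c_t$ is the sum of a *pushing* term — the unit
  vector at the target weighted by a piecewise-linear function
  $f_{\mathrm{targ}}$ of the estimated distance — and a *damping* term —
  the unit heading vector weighted by $f_{\mathrm{vel}}$ (typically
  negative) of the estimated speed. Both weighting functions clamp outside
  their knot range, mirroring bounded neural modulation.
* **Delayed feedback and forward model.** The user sees the true cursor
  state τ steps late and runs the decoder dynamics forward from it using
  efference copies of its own recent commands:
  $\hat x_t = A^\tau x_{t-\tau} + \sum_{i=0}^{\tau-1} A^i B\, c_{t-i-1}$.
  Because the copies lack the noise, perturbations can only be countered τ
  steps after they occur — the essential cost of feedback delay. When a
  speed transform is active the efference copies are the transformed
  commands, keeping the forward model matched to the true dynamics.
* **Decoding noise.** $e_t$ follows a vector AR(p) process with Gaussian
  innovations, capturing both the magnitude and the temporal correlation of
  decoding error. Optionally the innovation covariance is scaled by a
  piecewise-linear function $f_{\mathrm{SDN}}(\lVert c_t\rVert)$ of the
  commanded magnitude (signal-dependent noise); the default is a constant
  scale, i.e. a signal-independent noise floor.

Target acquisition requires holding the cursor in unbroken contact with
the effective target (target radius + cursor radius) for the dwell time;
exceeding the maximum movement time fails the trial and resets the cursor
to the target position.

## Fitting

`fit_user_model()` follows an alternating scheme. The internal state
estimates are initialized as delayed true states; the knot ordinates of
$f_{\mathrm{targ}}$ and $f_{\mathrm{vel}}$ are then linear parameters
(through hat-function interpolation weights) and are solved by least
squares against the observed $u_t$; the estimates are recomputed by the
forward model using efference copies of the *modeled* control; five
iterations by default. The AR noise model is fit to the residuals by least
squares, with the order chosen by contiguous-block cross-validation
(random folds would leak autocorrelation): the order stops growing when
the one-step-ahead R² gains less than `cv_tolerance` (default 1e-3). The
innovation covariance is the covariance of the AR prediction errors, and
the signal-dependent scale is estimated in 20 bins of
$\lVert c_t\rVert \in [0, 1.5]$, each populated bin's innovation
covariance matched to the full-data covariance by a least-squares scalar;
bins with fewer than 30 samples inherit the nearest populated bin's scale.

**Estimating the feedback delay.** With τ unknown, the package searches a
grid of 0–25 steps. It does *not* pick the τ maximizing the policy-fit R²:
when the decoding noise is positively correlated in time, a too-small τ
lets the damping term (built from an insufficiently delayed state
estimate) absorb *predictable noise*, so raw R² is systematically biased
toward τ = 0. Instead the package picks the τ minimizing the generalized
variance of the AR innovations of the policy residuals: at the true delay
the residuals are exactly the noise process, so their innovations are
smallest. On synthetic ground truth this criterion recovers τ exactly,
with a clean interior minimum.

## Adaptation and prediction

Users re-tune their behavior when the decoder dynamics change. Following
the observation that this adaptation is mostly a change in velocity
damping, `adapt_damping()` replaces $f_{\mathrm{vel}}$ by a line through
the origin whose slope is chosen by brute force on a grid from 0 to −3
(step 0.1 by default), minimizing the mean simulated movement time under
the new condition — using *only* simulation from the fitted model, never
held-out data. Common random numbers are used across the candidate slopes
to de-noise the comparison, and ties break toward the least intervention
(slope closest to 0). Timed-out trials are scored at the maximum trial
time in this objective; excluding them would reward reckless settings.

`predict_conditions()` re-adapts the damping per condition, simulates the
requested number of movements, and summarizes the four performance
metrics — movement time, translation time (onset to first contact),
dial-in time (first contact to acquisition minus the dwell), and path
efficiency — with percentile-bootstrap confidence intervals.
`bootstrap_prediction_ci()` expresses the uncertainty due to limited
training data by resampling training trials with replacement and refitting.

## Optimization tools

* `sweep_surface()` / `select_params()`: metric surfaces over a gain ×
  smoothing grid and argmin/argmax selection (ties toward lower gain, then
  higher smoothing).
* `optimize_keyboard()`: for each dwell time of a 36-key square-layout
  keyboard, a full gain/smoothing sweep maximizing the achieved bit rate
  $\log_2(N-1)\max(S_c-S_w,0)/T$; dwelling on a wrong key counts as a
  failure. The damping adaptation for keyboard conditions runs on a radial
  proxy task (typical inter-key distance, inscribed key radius, same
  dwell).
* `optimize_speed_transform()`: either an exhaustive joint grid over
  (β, α, p) for the exponent transform $s_{\mathrm{out}} =
  s_{\mathrm{in}}^p$, or a derivative-free coordinate pattern search over
  the ordinates of a 14-breakpoint piecewise-linear transform, run from 24
  restarts whose solutions are averaged pointwise and then projected to a
  monotone function by isotonic regression (averaging can break
  monotonicity). Every objective evaluation uses common random numbers.

**Where the transform lives.** The speed transform operates on the
normalized control vector *before* smoothing and gain, so its input
magnitude is on the normalized control scale where full effort is ~1 (the
magnitude that maps to terminal speed β). The piecewise breakpoints
therefore span 0–1.25 in normalized units — the same span as 0–1.25 β
expressed in speed units. Placing the transform before the smoothing
dynamics is a modelling choice (the alternative, after smoothing, is not
distinguished by the data the model is fit to); it makes the noise-floor
mechanism explicit: with an exponent p > 1 the transform squashes the
mostly-noise magnitudes near rest while preserving full-effort commands.

## Calibration benchmark

`recalibration_loop()` reproduces the motivating failure of standard
calibration with a *simple* simulated neural user (not the PLM): 50
features linearly tuned to the position error with uniformly distributed
preferred directions, $f_t = E(g_t - p_t) + \varepsilon_t$. A steady-state
velocity Kalman filter is calibrated on open-loop data, then repeatedly
recalibrated on closed-loop blocks with intention re-estimation (decoded
velocities rotated toward the target and zeroed on it). The steady-state
filter $v_t = M v_{t-1} + K f_t$ is re-expressed in gain/smoothing form:
$\alpha_{\mathrm{eff}} = \mathrm{tr}(M)/d$ (the isotropic part of the
smoothing matrix; with uniformly distributed preferred directions $M$ is
near-isotropic, and the reparameterization is exact when it is), and
$\beta_{\mathrm{eff}}$ is the terminal speed
$\lVert (I - M)^{-1} K f \rVert$ averaged over a *fixed* reference feature
set — the open-loop block. The fixed reference matters: measuring against
each round's own features confounds the filter's DC gain with the shifted
closed-loop error distribution (slower cursors spend more time far from
the target, where features are larger), which masks the gain drift.

With the default feature noise (SD 30, putting the decoded
signal-to-noise near 1) the benchmark exhibits the documented pathology:
over five recalibration rounds the effective gain falls strictly and the
smoothing rises strictly, no round attains the movement time of the best
(β, α) found by exhaustive sweep with the same user, and the sweep-optimal
gain for a small-radius task is well below that for a large-radius task.
With the position-error intention mode the recalibration target is
round-invariant, so the drift does not compound: the decoder moves away
from the open-loop settings after one round and then stays put. The
benchmark intentionally keeps the simple linear encoding; real users
saturate and adapt, which this module does not model.

## Synthetic study conditions

All development and testing inputs come from the built-in generator
(`make_synthetic_session()`, `simulate_condition()`), with defaults fixed
once in `reference_user()` / `reference_decoder()` / `reference_task()`:

* a workspace normalized to the outer-target distance (1 unit), so gains
  are in target distances per second (TD/s); 20 ms time steps;
* ground-truth user: saturating $f_{\mathrm{targ}}$ (full effort beyond
  20 % of the target distance), linear damping slope −1, feedback delay
  10 steps (200 ms), AR(1) noise with coefficient 0.6 and innovation SD
  0.15 per dimension (a signal-independent floor of stationary SD ≈ 0.19
  on the unit-effort scale). The AR(2) variant used in the recovery
  replicates is the damped-oscillatory pair (0.8, −0.25): root modulus
  0.5, so the noise stays correlated over tenths of a second rather than
  drifting — a near-unit-root AR(2) would masquerade as intent and is not
  a realistic model of decoding error;
* training decoder β = 0.8 TD/s, α = 0.9; center-out-and-back task with 8
  outer targets, radius 0.1, dwell 0.5 s, timeout 10 s.

These produce movement times of 1.5–4 s and near-ceiling success — the
operating regime of practiced closed-loop cursor use. Two variants define
harder regimes: a *noise-floor* user (AR coefficient 0.8, innovation SD
0.3; stationary SD ≈ 0.5) for the precision task (effective radius =
distance/8, dwell 4 s, timeout 12 s) on which the speed transform is
optimized, and a *control* user with the same AR structure but
signal-dependent scaling $f_{\mathrm{SDN}}(\lVert c\rVert) = \lVert
c\rVert$, whose noise vanishes at rest — for that user the exponent search
should find nothing to fix (p within one grid step of 1).

In the held-out-condition transfer experiment the ground-truth user
generating the "observed" data re-adapts its damping per condition by the
same simulation-based search the prediction uses: the generator emulates
an adapting human, which is precisely the behavior the adaptation module
models.

What the generator does **not** emulate: non-stationary neural signals
(within-session drift), learning beyond damping re-tuning, saturating or
history-dependent neural encoding, and non-Gaussian noise. Passing the
synthetic recovery and transfer checks therefore shows the estimator and
simulator are correct and internally consistent — not that the model
captures every property of real closed-loop data.

## Numerical choices and degenerate inputs

* Unit vectors in the control policy are undefined at zero; pushing and
  damping terms are zeroed when their governing magnitudes are below
  1e-9.
* Histories before a trial's start are padded with the initial state and
  zero controls; AR noise is warmed up with a 100-step burn-in per trial
  (at unit variance scale — no command exists before the trial), so
  trials start near stationarity.
* Each trial is seeded from a per-trial child seed derived by counter from
  the block seed, so trial k is reproducible in isolation; each trial
  starts at rest at the previous target's position.
* A success requires an unbroken-contact run of `ceil(dwell/dt)` steps
  *after* the touching sample, so an uninterrupted acquisition has
  dial-in time exactly 0.
* Path efficiency is `min(1, straight-line distance / path length)`: a
  trial acquired before the cursor has traveled the full start-to-center
  distance counts as perfectly straight rather than exceeding 1.
* Rank-deficient policy regressions (knots with no supporting samples) tie
  the unidentifiable knot to its nearest identifiable neighbor, with a
  warning.
* Degenerate calibration inputs (zero residual covariance, singular
  feature covariance) are ridge-regularized with a warning; the Riccati
  innovation covariance always carries a 1e-12 relative jitter so the
  noiseless limit stays solvable.

## Problem sizes used by the shipped checks

The package's tests and the acceptance script run everything at sizes a
single CPU handles comfortably: 100-trial (≈ 4–5 min) training sessions;
10 recovery replicates; 250 simulated movements per predicted condition;
6-point gain and 4-point smoothing sweeps at 250 trials per cell; a 7 × 5
keyboard grid at 60 selections per cell over 6 dwell times; 96-trial
calibration blocks with an 8 × 5 reference sweep at 24 trials per cell;
and a 5 × 3 × 6 joint (β, α, p) transform grid at 80–120 movements per
evaluation with a 500-trial head-to-head. The damping-adaptation grids in
these sweeps use steps of 0.2–0.25 over the same [−3, 0] range. Larger
settings (the defaults of `sweep_spec()` and `transform_search_spec()`
mirror the full protocol: 250 movements per cell, 400-pair surfaces, 24
pattern-search restarts at 200 movements per evaluation) scale linearly.

## Known limitations

* The fitter assumes the training block used a linear decoder (identity
  transform); fitting data collected *with* a nonlinear transform would
  require inverting it in the forward model.
* `alpha_eff` of a calibrated Kalman decoder is the isotropic part of the
  smoothing matrix; strongly anisotropic tuning would make the scalar
  reparameterization lossy (the exact matrices are returned alongside).
* The adaptation model re-tunes only the damping slope, as a linear
  function; pushing behavior and noise statistics are assumed stable
  across conditions.
* Dimensionality is generic in the decoder and simulator (d ≥ 1), but the
  calibration benchmark and the shipped experiments are two-dimensional.
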