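#' Simulated linearly tuned neural user
#'
#' A population of \code{n_features} features linearly tuned to the cursor's
#' position error, \code{f_t = E (g_t - p_t) + eps_t}, with preferred
#' directions drawn uniformly on the circle and i.i.d. Gaussian feature
#' noise. This simple feedback-policy user (not the piecewise-linear model)
#' drives the calibration benchmark.
#'
#' @param n_features number of neural features.
#' @param noise_sd per-feature Gaussian noise SD; the default puts the
#'   decoder in the noise-dominated regime (decoded signal-to-noise near 1)
#'   where gain and smoothing genuinely trade off.
#' @param modulation_depth scaling of each feature's tuning vector (scalar
#'   or length \code{n_features}).
#' @param dims workspace dimensionality (2 for the benchmark).
#' @param seed seed for drawing the preferred directions.
#' @return an object of class \code{"simulated_neural_user"} with tuning
#'   matrix \code{E} (n_features x dims).
#' @export
simulated_neural_user <- function(n_features = 50L, noise_sd = 30,
                                  modulation_depth = 1, dims = 2L,
                                  seed = 1L) {
  stopifnot(dims == 2L)
  set.seed(seed)
  th <- stats::runif(n_features, 0, 2 * pi)
  E <- rep_len(modulation_depth, n_features) * cbind(cos(th), sin(th))
  structure(list(n_features = as.integer(n_features), E = E,
                 noise_sd = noise_sd, dims = dims),
            class = "simulated_neural_user")
}

#' Generate one feature vector
#'
#' @param user a \code{\link{simulated_neural_user}}.
#' @param g target position.
#' @param p cursor position.
#' @return numeric feature vector of length \code{n_features}.
#' @export
generate_features <- function(user, g, p) {
  as.numeric(user$E %*% (g - p)) +
    stats::rnorm(user$n_features, sd = user$noise_sd)
}

#' Calibrate a steady-state velocity Kalman filter
#'
#' Fits the observation model \code{f ~ H v + q} by least squares, takes a
#' first-order random-walk velocity prior with process covariance estimated
#' from the intended-velocity increments, iterates the Riccati recursion to
#' the steady-state Kalman gain \code{K}, and re-expresses the steady-state
#' filter \code{v_t = M v_{t-1} + K f_t} (with \code{M = (I - K H) a}) in
#' the gain/smoothing decoder form: \code{alpha_eff = tr(M)/dims} (the
#' isotropic part of the smoothing matrix), \code{D = K / ((1 - alpha_eff)
#' beta_eff)}, and \code{beta_eff} the terminal speed: the asymptotic speed
#' \code{||(I - M)^{-1} K f||} the filter would reach if an input were
#' sustained forever, averaged over reference feature vectors. By
#' construction a sustained input with \code{||D f|| = 1} asymptotes at
#' speed \code{beta_eff}.
#'
#' @param features matrix of feature vectors, one row per step.
#' @param intended_velocities matrix of intended velocities, same rows.
#' @param prior_a velocity-prior decay (1 = random walk).
#' @param ridge ridge added to the feature regression when near-singular.
#' @param reference_features optional matrix of feature vectors against
#'   which the terminal speed is measured; defaults to the calibration
#'   features. Passing one fixed reference set makes \code{beta_eff}
#'   comparable across decoders calibrated on different blocks (the input
#'   effort scale is held constant).
#' @return an object of class \code{"calibrated_decoder"}: \code{D},
#'   \code{alpha_eff}, \code{beta_eff}, plus the exact filter matrices
#'   \code{M}, \code{K}, \code{H}.
#' @export
calibrate_velocity_kf <- function(features, intended_velocities,
                                  prior_a = 1, ridge = 0,
                                  reference_features = NULL) {
  F_ <- as.matrix(features)
  V <- as.matrix(intended_velocities)
  stopifnot(nrow(F_) == nrow(V), nrow(F_) >= 30L)
  d <- ncol(V)
  G <- crossprod(V)
  if (ridge > 0 || kappa(G) > 1e10) {
    if (ridge == 0) {
      warning("near-singular intended-velocity covariance; ridge-regularizing")
      ridge <- 1e-8 * mean(diag(G))
    }
    G <- G + diag(ridge, d)
  }
  H <- t(solve(G, crossprod(V, F_)))            # n_features x d
  resid <- F_ - V %*% t(H)
  R <- stats::cov(resid)
  if (kappa(R) > 1e12) {
    warning("singular feature-noise covariance; ridge-regularizing")
    R <- R + diag(1e-6 * mean(diag(R)), ncol(R))
  }
  dV <- diff(V)
  W <- stats::cov(dV)
  if (max(abs(W)) == 0) W <- diag(1e-8, d)
  P <- W
  for (i in 1:500) {
    Pm <- prior_a^2 * P + W
    S <- H %*% Pm %*% t(H) + R
    S <- S + diag(1e-12 * mean(diag(S)), nrow(S))  # keeps S invertible when R ~ 0
    K <- Pm %*% t(H) %*% solve(S)
    Pn <- (diag(d) - K %*% H) %*% Pm
    if (max(abs(Pn - P)) < 1e-12 * max(abs(Pn), 1e-30)) {
      P <- Pn
      break
    }
    P <- Pn
  }
  M <- prior_a * (diag(d) - K %*% H)
  alpha_eff <- min(max(sum(diag(M)) / d, 0), 0.999)
  # terminal velocity: asymptotic speed if each reference input were
  # sustained forever, averaged over the reference samples
  if (is.null(reference_features)) {
    Fr <- F_[sqrt(rowSums(V^2)) > 1e-9, , drop = FALSE]
  } else {
    Fr <- as.matrix(reference_features)
  }
  vinf <- Fr %*% t(K) %*% t(solve(diag(d) - M))
  beta_eff <- mean(sqrt(rowSums(vinf^2)))
  D <- K / ((1 - alpha_eff) * beta_eff)
  structure(list(D = D, alpha_eff = alpha_eff, beta_eff = beta_eff,
                 M = M, K = K, H = H),
            class = "calibrated_decoder")
}

#' @export
print.calibrated_decoder <- function(x, ...) {
  cat(sprintf("calibrated decoder: alpha_eff = %.4f, beta_eff = %.4g\n",
              x$alpha_eff, x$beta_eff))
  invisible(x)
}

#' Re-estimate intended velocities from closed-loop data
#'
#' \code{rotate_to_target}: each decoded velocity keeps its magnitude but
#' its direction is replaced by the unit vector from the cursor to the
#' target; samples with the cursor on top of the target (center within the
#' effective radius) are zeroed. \code{position_error}: returns the encoded
#' control signal \code{g - p} directly.
#'
#' @param decoded_velocities matrix of decoded velocities, one row per step.
#' @param cursor_positions matrix of cursor positions.
#' @param targets matrix of target positions.
#' @param mode \code{"rotate_to_target"} or \code{"position_error"}.
#' @param effective_radius radius of the zeroing region.
#' @return matrix of intended velocities.
#' @export
refit_intention <- function(decoded_velocities, cursor_positions, targets,
                            mode = c("rotate_to_target", "position_error"),
                            effective_radius = 0) {
  mode <- match.arg(mode)
  V <- as.matrix(decoded_velocities)
  P <- as.matrix(cursor_positions)
  G <- as.matrix(targets)
  err <- G - P
  if (mode == "position_error") return(err)
  dn <- sqrt(rowSums(err^2))
  mag <- sqrt(rowSums(V^2))
  dir <- err / pmax(dn, 1e-12)
  out <- dir * mag
  out[dn <= effective_radius, ] <- 0
  out
}

# closed-loop block of the simple feedback user under a calibrated decoder;
# returns the logged series and per-trial movement times
neural_closed_loop_block <- function(nuser, dec, task, n_trials, seed,
                                     use_exact_filter = FALSE) {
  dt <- dec$dt
  max_steps <- round(task$max_trial_s / dt)
  dwell_steps <- ceiling(task$dwell_s / dt - 1e-9)
  set.seed(seed)
  p <- c(0, 0)
  v <- c(0, 0)
  Fs <- Ps <- Gs <- Vs <- NULL
  mts <- numeric(n_trials)
  succ <- logical(n_trials)
  for (k in seq_len(n_trials)) {
    tg <- task$target_generator(k, p)
    g <- tg$target
    r_eff <- tg$radius + task$cursor_radius
    v <- c(0, 0)
    run <- 0L
    prev_in <- sqrt(sum((p - g)^2)) <= r_eff
    t_acq <- NA_real_
    Fb <- matrix(NA_real_, max_steps, nuser$n_features)
    Pb <- Vb <- matrix(NA_real_, max_steps, 2)
    n <- 0L
    for (t in seq_len(max_steps)) {
      f <- generate_features(nuser, g, p)
      v <- if (use_exact_filter) as.numeric(dec$M %*% v + dec$K %*% f) else
        dec$alpha_eff * v +
          (1 - dec$alpha_eff) * dec$beta_eff * as.numeric(dec$D %*% f)
      Pb[t, ] <- p        # state the decode acted from
      Fb[t, ] <- f
      Vb[t, ] <- v
      p <- p + dt * v
      n <- t
      inn <- sqrt(sum((p - g)^2)) <= r_eff
      if (inn) {
        run <- if (prev_in) run + 1L else 0L
        if (run >= dwell_steps) {
          t_acq <- t * dt
          break
        }
      } else run <- 0L
      prev_in <- inn
    }
    succ[k] <- !is.na(t_acq)
    mts[k] <- if (succ[k]) t_acq else task$max_trial_s
    Fs <- rbind(Fs, Fb[seq_len(n), , drop = FALSE])
    Ps <- rbind(Ps, Pb[seq_len(n), , drop = FALSE])
    Vs <- rbind(Vs, Vb[seq_len(n), , drop = FALSE])
    Gs <- rbind(Gs, matrix(g, n, 2, byrow = TRUE))
    p <- g  # reset to the target position
  }
  list(features = Fs, positions = Ps, velocities = Vs, targets = Gs,
       movement_times = mts, success = succ)
}

#' Closed-loop recalibration benchmark
#'
#' Reproduces the calibration-drift experiment: round 0 calibrates a
#' velocity Kalman filter on open-loop data (a scripted cursor replay with
#' the intended velocity taken as the position error); each later round
#' runs a closed-loop block with the previous decoder, re-estimates
#' intention (\code{\link{refit_intention}}), and recalibrates. The
#' effective gain and smoothing of each round's decoder and the block's
#' mean movement time are recorded, exposing how recalibration drifts the
#' decoder dynamics (gain down, smoothing up) without converging to the
#' sweep-optimal setting.
#'
#' @param nuser a \code{\link{simulated_neural_user}}.
#' @param task a \code{\link{task_spec}}.
#' @param n_rounds number of recalibration rounds (>= 1).
#' @param seed integer seed.
#' @param n_trials_per_block trials per closed-loop block.
#' @param intention_mode passed to \code{\link{refit_intention}}.
#' @param dt decoder time step.
#' @return data.frame with one row per round (0 = open-loop calibration):
#'   \code{alpha_eff}, \code{beta_eff}, \code{mean_movement_time},
#'   \code{success_rate}; decoders in \code{attr(, "decoders")}.
#' @export
recalibration_loop <- function(nuser, task, n_rounds = 5L, seed = 1L,
                               n_trials_per_block = 48L,
                               intention_mode = "rotate_to_target",
                               dt = 0.02) {
  # open-loop: scripted straight movements to center-out targets at a
  # comfortable speed, user imagining along
  set.seed(seed)
  p <- c(0, 0)
  Fs <- Vs <- NULL
  r_eff0 <- task$target_generator(1L, p)$radius + task$cursor_radius
  for (k in seq_len(n_trials_per_block)) {
    g <- task$target_generator(k, p)$target
    dist <- sqrt(sum((g - p)^2))
    if (dist < 1e-9) next
    n <- max(round(1 / dt), 2L)          # 1 s scripted reach
    for (t in seq_len(n)) {
      f <- generate_features(nuser, g, p)
      Fs <- rbind(Fs, f)
      Vs <- rbind(Vs, g - p)             # intended velocity = position error
      p <- p + (g - p) / (n - t + 1)
    }
    p <- g
  }
  dec <- calibrate_velocity_kf(Fs, Vs)
  dec$dt <- dt
  rounds <- list()
  decoders <- list(dec)
  for (r in 0:n_rounds) {
    blk <- neural_closed_loop_block(nuser, dec, task, n_trials_per_block,
                                    seed = seed + 100L * (r + 1L))
    rounds[[r + 1L]] <- data.frame(
      round = r, alpha_eff = dec$alpha_eff, beta_eff = dec$beta_eff,
      mean_movement_time = mean(blk$movement_times),
      success_rate = mean(blk$success))
    if (r < n_rounds) {
      vint <- refit_intention(blk$velocities, blk$positions, blk$targets,
                              mode = intention_mode,
                              effective_radius = r_eff0)
      dec <- calibrate_velocity_kf(blk$features, vint,
                                   reference_features = Fs)
      dec$dt <- dt
      decoders[[r + 2L]] <- dec
    }
  }
  out <- do.call(rbind, rounds)
  attr(out, "decoders") <- decoders
  out
}

#' Gain/smoothing sweep for the simulated neural user
#'
#' Movement-time surface over (beta, alpha) multiplicative settings applied
#' to a fixed decoding matrix direction, simulated with the simple
#' feedback-policy neural user. Used as the sweep-optimal reference the
#' recalibration rounds are compared against.
#'
#' @param nuser a \code{\link{simulated_neural_user}}.
#' @param base_decoder a \code{\link{calibrate_velocity_kf}} result whose
#'   \code{D} sets the fixed dimensionality-reduction direction.
#' @param task a \code{\link{task_spec}}.
#' @param gain_grid,smoothing_grid candidate beta and alpha values.
#' @param n_trials trials per cell.
#' @param seed integer seed.
#' @param dt decoder time step.
#' @return data.frame (beta, alpha, mean_movement_time, success_rate); the
#'   optimum row in \code{attr(, "optimum")}.
#' @export
neural_user_sweep <- function(nuser, base_decoder, task, gain_grid,
                              smoothing_grid, n_trials = 32L, seed = 1L,
                              dt = 0.02) {
  rows <- list()
  k <- 0L
  for (b in gain_grid) for (a in smoothing_grid) {
    k <- k + 1L
    dec <- list(D = base_decoder$D, alpha_eff = a, beta_eff = b, dt = dt)
    blk <- neural_closed_loop_block(nuser, dec, task, n_trials,
                                    seed = seed + k)
    rows[[k]] <- data.frame(beta = b, alpha = a,
                            mean_movement_time = mean(blk$movement_times),
                            success_rate = mean(blk$success))
  }
  out <- do.call(rbind, rows)
  attr(out, "optimum") <- out[which.min(out$mean_movement_time), ]
  out
}
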