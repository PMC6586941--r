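test_that("feature generation is linear tuning plus seeded Gaussian noise", {
  nu <- simulated_neural_user(n_features = 40, noise_sd = 0, seed = 1)
  expect_equal(generate_features(nu, c(3, 3), c(3, 3)), rep(0, 40))
  set.seed(2)
  f1 <- generate_features(simulated_neural_user(noise_sd = 5), c(1, 0), c(0, 0))
  set.seed(2)
  f2 <- generate_features(simulated_neural_user(noise_sd = 5), c(1, 0), c(0, 0))
  expect_identical(f1, f2)
  # regressing features on the position error recovers the tuning matrix
  nu2 <- simulated_neural_user(n_features = 30, noise_sd = 2, seed = 3)
  set.seed(4)
  err <- matrix(rnorm(2e4, sd = 10), ncol = 2)
  F_ <- t(apply(err, 1, function(e) generate_features(nu2, e, c(0, 0))))
  Ehat <- t(solve(crossprod(err), crossprod(err, F_)))
  expect_equal(Ehat, nu2$E, tolerance = 0.02)
})

test_that("noiseless calibration decodes the intended direction", {
  nu <- simulated_neural_user(n_features = 40, noise_sd = 1e-6, seed = 5)
  set.seed(6)
  V <- matrix(rnorm(4000, sd = 5), ncol = 2)
  F_ <- t(apply(V, 1, function(v) generate_features(nu, v, c(0, 0))))
  dec <- calibrate_velocity_kf(F_, V)
  Vh <- matrix(rnorm(400, sd = 5), ncol = 2)
  Fh <- t(apply(Vh, 1, function(v) generate_features(nu, v, c(0, 0))))
  u <- Fh %*% t(dec$D)
  ang <- acos(pmin(rowSums(u * Vh) / sqrt(rowSums(u^2) * rowSums(Vh^2)), 1))
  expect_lt(max(ang) * 180 / pi, 1)
})

test_that("more feature noise means a smaller Kalman gain and more smoothing", {
  set.seed(7)
  V <- matrix(rnorm(6000, sd = 5), ncol = 2)
  alphas <- vapply(c(2, 8, 32), function(nsd) {
    nu <- simulated_neural_user(n_features = 40, noise_sd = nsd, seed = 8)
    F_ <- t(apply(V, 1, function(v) generate_features(nu, v, c(0, 0))))
    calibrate_velocity_kf(F_, V)$alpha_eff
  }, numeric(1))
  expect_true(all(diff(alphas) > 0))
})

test_that("gain/smoothing reparameterization reproduces the exact steady-state filter", {
  # constructed exactly isotropic calibration set: H^T H proportional to I,
  # exactly whitened residuals and velocity increments, so M = alpha I holds
  # and the scalar form must match the matrix filter to machine precision
  T_ <- 2000L
  nf <- 8L
  set.seed(9)
  dV0 <- matrix(rnorm(2 * (T_ - 1)), ncol = 2)
  dV0 <- scale(dV0, center = TRUE, scale = FALSE)
  dW <- dV0 %*% solve(chol(cov(dV0)))          # exact cov = I
  V <- apply(rbind(c(0, 0), dW), 2, cumsum)    # so cov(diff(V)) = I exactly
  th <- 2 * pi * (0:(nf - 1)) / nf
  H0 <- 3 * cbind(cos(th), sin(th))            # isotropic frame: t(H)H = c I
  Q0 <- matrix(rnorm(T_ * nf), ncol = nf)
  X1 <- cbind(1, V)                            # project out V and the mean
  Q0 <- Q0 - X1 %*% solve(crossprod(X1), crossprod(X1, Q0))
  Q <- Q0 %*% solve(chol(cov(Q0)))             # exact residual cov = I
  F_ <- V %*% t(H0) + 2 * Q
  dec <- calibrate_velocity_kf(F_, V)
  expect_equal(dec$M, dec$alpha_eff * diag(2), tolerance = 1e-9)
  # identical velocity traces under both parameterizations
  set.seed(10)
  v_exact <- v_scalar <- c(0, 0)
  for (t in 1:200) {
    f <- rnorm(nf)
    v_exact <- as.numeric(dec$M %*% v_exact + dec$K %*% f)
    v_scalar <- dec$alpha_eff * v_scalar +
      (1 - dec$alpha_eff) * dec$beta_eff * as.numeric(dec$D %*% f)
    expect_equal(v_scalar, v_exact, tolerance = 1e-8)
  }
})

test_that("calibrated decoders reach their nominal terminal speed", {
  # sustained unit-magnitude normalized input asymptotes at beta_eff
  nu <- simulated_neural_user(n_features = 40, noise_sd = 10, seed = 11)
  set.seed(12)
  V <- matrix(rnorm(6000, sd = 5), ncol = 2)
  F_ <- t(apply(V, 1, function(v) generate_features(nu, v, c(0, 0))))
  dec <- calibrate_velocity_kf(F_, V)
  f0 <- F_[7, ]
  u0 <- as.numeric(dec$D %*% f0)
  u0 <- u0 / sqrt(sum(u0^2))                   # ||D f|| = 1 direction
  v <- c(0, 0)
  for (k in 1:3000) v <- dec$alpha_eff * v +
      (1 - dec$alpha_eff) * dec$beta_eff * u0
  expect_equal(sqrt(sum(v^2)), dec$beta_eff, tolerance = 0.01)
})

test_that("intention re-estimation rotates, preserves magnitude, and zeroes on target", {
  set.seed(13)
  Vd <- matrix(rnorm(60), ncol = 2)
  P <- matrix(rnorm(60), ncol = 2)
  G <- P + matrix(rnorm(60, sd = 3), ncol = 2)
  out <- refit_intention(Vd, P, G, "rotate_to_target", effective_radius = 1)
  err <- G - P
  on_tgt <- sqrt(rowSums(err^2)) <= 1
  expect_true(all(out[on_tgt, ] == 0))
  off <- !on_tgt
  expect_equal(sqrt(rowSums(out[off, ]^2)), sqrt(rowSums(Vd[off, ]^2)))
  cosang <- rowSums(out[off, ] * err[off, ]) /
    sqrt(rowSums(out[off, ]^2) * rowSums(err[off, ]^2))
  expect_equal(cosang, rep(1, sum(off)))
  # vectors already pointing at the target are unchanged
  Vp <- 2.5 * err[off, ] / sqrt(rowSums(err[off, ]^2))
  expect_equal(refit_intention(Vp, P[off, ], G[off, ], "rotate_to_target"),
               Vp)
  expect_equal(refit_intention(Vd, P, G, "position_error"), err)
})

test_that("a short recalibration loop drifts toward lower gain and more smoothing", {
  nu <- simulated_neural_user(seed = 4)
  task <- task_spec(center_out_targets(10, 1.0), dwell_s = 0.5,
                    max_trial_s = 8)
  res <- recalibration_loop(nu, task, n_rounds = 2, seed = 1,
                            n_trials_per_block = 48)
  expect_identical(nrow(res), 3L)
  expect_gt(res$alpha_eff[3], res$alpha_eff[1])
  expect_lt(res$beta_eff[3], res$beta_eff[1])
  expect_length(attr(res, "decoders"), 3L)
})
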