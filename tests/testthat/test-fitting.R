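test_that("zero-noise, zero-delay policy fit recovers the generator exactly", {
  ftk <- c(0, 0.2, 1.2)
  ftv <- c(0, 1, 1.05)
  truth <- user_model(control_policy(piecewise_linear(ftk, ftv),
                                     linear_damping(-1, 5)),
                      noise = NULL, delay_tau = 0L)
  ses <- simulate_condition(truth, reference_decoder(), reference_task(),
                            30, seed = 1)
  cfg <- fit_config(f_targ_knots = ftk, f_vel_knots = c(0, 5),
                    delay_tau = 0L)
  pf <- fit_control_policy(ses, 0L, reference_decoder(), cfg)
  expect_equal(pf$policy$f_targ$values, ftv, tolerance = 1e-8)
  expect_equal(slope_of(pf$policy$f_vel), -1, tolerance = 1e-8)
  expect_gt(tail(pf$r2, 1), 1 - 1e-12)
})

test_that("noisy synthetic session: policy, delay, and noise recovered within tolerance", {
  truth <- reference_user()           # slope -1, tau 10, AR(1) 0.6, sd 0.15
  ses <- simulate_condition(truth, reference_decoder(), reference_task(),
                            100, seed = 11)
  fit <- fit_user_model(ses, fit_config(delay_tau = "grid"))
  expect_lte(abs(fit$tau - 10), 3)
  expect_lt(abs(slope_of(fit$user$policy$f_vel) - (-1)), 0.2)
  expect_lt(max(abs(diag(fit$user$noise$innovation_cov) / 0.15^2 - 1)), 0.15)
  expect_lte(abs(fit$n_lags - 1), 1)
  # f_targ knot values close to the generator over its support
  xs <- seq(0.1, 1.1, by = 0.2)
  rmse <- sqrt(mean((pl_eval(fit$user$policy$f_targ, xs) -
                       pl_eval(truth$policy$f_targ, xs))^2))
  expect_lt(rmse, 0.1 * max(truth$policy$f_targ$values))
})

test_that("iterative fit does not degrade its training objective", {
  truth <- reference_user()
  ses <- simulate_condition(truth, reference_decoder(), reference_task(),
                            60, seed = 21)
  pf <- fit_control_policy(ses, 10L, reference_decoder(), fit_config())
  expect_true(all(diff(pf$sse) <= 1e-6 * pf$sse[1]))
  expect_true(all(diff(pf$r2) >= -1e-8))
  expect_true(all(is.finite(pf$r2)))
})

test_that("AR order selection: white noise picks 0, AR(2) picks a small order", {
  set.seed(31)
  E <- matrix(rnorm(2e4, sd = 0.2), ncol = 2)
  nm <- fit_noise_model(E, NULL, fit_config(fit_sdn = FALSE))
  expect_identical(nm$n_lags, 0L)
  expect_lt(max(abs(diag(nm$innovation_cov) / 0.04 - 1)), 0.10)

  # stationary AR(2) generator with known one-step predictability
  p1 <- 0.5; p2 <- 0.2; sig <- 0.1
  E2 <- matrix(0, 1e4, 2)
  for (t in 3:1e4) E2[t, ] <- p1 * E2[t - 1, ] + p2 * E2[t - 2, ] +
      rnorm(2, sd = sig)
  nm2 <- fit_noise_model(E2, NULL, fit_config(fit_sdn = FALSE))
  expect_true(nm2$n_lags %in% 1:3)
  # theoretical R^2 = 1 - sigma^2 / var(e), var from Yule-Walker
  rho1 <- p1 / (1 - p2)
  ve <- sig^2 / (1 - p1 * rho1 - p2 * (p1 * rho1 + p2))
  cv <- attr(nm2, "cv_curve")
  expect_lt(abs(cv$cv_r2[cv$order == 2] - (1 - sig^2 / ve)), 0.05)
})

test_that("signal-independent noise yields a flat fitted SDN scale", {
  set.seed(41)
  E <- matrix(rnorm(2e4, sd = 0.2), ncol = 2)
  cmag <- cbind(runif(1e4, 0, 1.4), 0)
  nm <- fit_noise_model(E, cmag, fit_config())
  sc <- attr(nm, "sdn_scales")
  expect_true(all(sc >= 0.8 & sc <= 1.2))
})

test_that("noiseless session fits an essentially zero innovation covariance", {
  truth <- user_model(
    control_policy(piecewise_linear(c(0, 0.3, 1.2), c(0, 1, 1)),
                   linear_damping(-0.5, 5)),
    noise = NULL, delay_tau = 5L)
  ses <- simulate_condition(truth, reference_decoder(), reference_task(),
                            40, seed = 3)
  fit <- suppressWarnings(
    fit_user_model(ses, fit_config(delay_tau = 5L,
                                   f_targ_knots = c(0, 0.3, 1.2),
                                   f_vel_knots = c(0, 5))))
  expect_lt(max(abs(fit$user$noise$innovation_cov)), 1e-10)
})

test_that("in-sample predictions match the training session", {
  truth <- reference_user()
  dec <- reference_decoder()
  task <- reference_task()
  ses <- simulate_condition(truth, dec, task, 100, seed = 55)
  fit <- fit_user_model(ses, fit_config())   # fixed tau = 10 (true value)
  pr <- predict_conditions(fit, list(list(decoder = dec, task = task)),
                           n_sims = 300, seed = 7, adapt = FALSE,
                           n_boot = 200)
  sm_obs <- summarize_condition(ses, n_boot = 200, seed = 7)
  sm_prd <- attr(pr, "summaries")[[1]]
  for (metric in c("movement_time", "translation_time", "path_efficiency")) {
    o <- sm_obs[sm_obs$metric == metric, ]
    p <- sm_prd[sm_prd$metric == metric, ]
    half <- (o$ci_hi - o$ci_lo) / 2 + (p$ci_hi - p$ci_lo) / 2
    expect_lt(abs(o$mean - p$mean), 2 * max(half, 0.02))
  }
})

test_that("bootstrap prediction intervals collapse for deterministic data", {
  truth <- noiseless_user(tau = 0L, fvel_slope = -0.3)
  dec <- reference_decoder()
  task <- reference_task()
  ses <- simulate_condition(truth, dec, task, 16, seed = 9)
  cfg <- fit_config(delay_tau = 0L, max_lags = 2L,
                    f_targ_knots = c(0, 0.05, 1.2), f_vel_knots = c(0, 5),
                    fit_sdn = FALSE)
  ci <- suppressWarnings(bootstrap_prediction_ci(
    ses, cfg, list(list(decoder = dec, task = task)),
    n_boot = 8L, seed = 2, n_sims = 20L, adapt = FALSE))
  mt <- ci[ci$metric == "movement_time", ]
  expect_lt(mt$ci_hi - mt$ci_lo, 1e-6)
})
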