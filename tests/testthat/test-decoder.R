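test_that("one decoder step follows the smoothing equation", {
  # alpha = 0: velocity jumps straight to beta * u
  dp <- decoder_params(2, 0, dt = 0.02)
  st <- decoder_step(list(position = c(0, 0), velocity = c(0, 0)),
                     c(1, 0), dp)
  expect_equal(st$velocity, c(2, 0))
  expect_equal(st$position, c(0.04, 0))
  # alpha -> 1 freezes the decoder (construct the limit explicitly)
  dp1 <- decoder_params(2, 1 - 1e-12, dt = 0.02)
  st1 <- decoder_step(list(position = c(1, 1), velocity = c(3, -1)),
                      c(100, 100), dp1)
  expect_equal(st1$velocity, c(3, -1), tolerance = 1e-9)
  expect_error(decoder_step(list(position = c(0, 0), velocity = c(0, 0)),
                            c(NA, 0), dp), "non-finite")
})

test_that("constant input converges geometrically to the terminal velocity", {
  # closed form: v_k = beta (1 - alpha^k) for unit input from rest
  dp <- decoder_params(2, 0.9, dt = 0.02)
  st <- list(position = c(0, 0), velocity = c(0, 0))
  for (k in 1:40) {
    st <- decoder_step(st, c(1, 0), dp)
    expect_equal(st$velocity[1], 2 * (1 - 0.9^k), tolerance = 1e-12)
  }
  # terminal-velocity property at several smoothing levels
  for (a in c(0, 0.5, 0.9, 0.97)) {
    dp <- decoder_params(1.5, a, dt = 0.02)
    st <- list(position = c(0, 0), velocity = c(0, 0))
    n <- ceiling(10 / (1 - a))
    for (k in seq_len(n)) st <- decoder_step(st, c(0.6, 0.8), dp)
    expect_lt(abs(sqrt(sum(st$velocity^2)) - 1.5), 0.01 * 1.5)
  }
})

test_that("state-space form reproduces stepping to machine precision", {
  set.seed(11)
  for (rep in 1:10) {
    dp <- decoder_params(runif(1, 0.5, 20), runif(1, 0, 0.99),
                         dt = runif(1, 0.01, 0.05))
    ss <- build_state_space(dp)
    st <- list(position = rnorm(2), velocity = rnorm(2))
    x <- c(st$position, st$velocity)
    for (k in 1:50) {
      u <- rnorm(2)
      st <- decoder_step(st, u, dp)
      x <- as.numeric(ss$A %*% x + ss$B %*% u)
    }
    expect_equal(x, c(st$position, st$velocity), tolerance = 1e-12)
  }
  # construction cases
  ss0 <- build_state_space(decoder_params(1, 0, dt = 0.02))
  expect_equal(ss0$A[3:4, 3:4], matrix(0, 2, 2))
  ss95 <- build_state_space(decoder_params(1, 0.95, dt = 0.02))
  expect_equal(ss95$A[3:4, 3:4], 0.95 * diag(2))
})

test_that("speed transforms remap magnitude and preserve direction", {
  expect_equal(apply_speed_transform(c(0.3, -0.7),
                                     speed_transform("exponent", 1)),
               c(0.3, -0.7))
  # p = 2 on magnitude 0.5
  u2 <- apply_speed_transform(c(0.3, 0.4), speed_transform("exponent", 2))
  expect_equal(sqrt(sum(u2^2)), 0.25)
  expect_equal(u2 / 0.25, c(0.6, 0.8))
  # piecewise {(0,0),(1,2)}: magnitude 0.5 -> 1.0, and extrapolation
  tr <- speed_transform("piecewise", breakpoints = rbind(c(0, 0), c(1, 2)))
  expect_equal(sqrt(sum(apply_speed_transform(c(0.3, 0.4), tr)^2)), 1.0)
  expect_equal(sqrt(sum(apply_speed_transform(c(3, 4), tr)^2)), 10) # slope 2
  # direction preservation, contraction/expansion of the exponent variant
  set.seed(3)
  for (rep in 1:25) {
    u <- rnorm(2) * 10^runif(1, -2, 0.5)
    for (trv in list(speed_transform("exponent", 1.7), tr)) {
      out <- apply_speed_transform(u, trv)
      cosang <- sum(u * out) / sqrt(sum(u^2) * sum(out^2))
      expect_equal(cosang, 1, tolerance = 1e-9)
    }
    s <- sqrt(sum(u^2))
    sp <- sqrt(sum(apply_speed_transform(u, speed_transform("exponent", 1.7))^2))
    if (s < 1) expect_lt(sp, s) else if (s > 1) expect_gt(sp, s)
  }
  expect_equal(apply_speed_transform(c(0, 0), speed_transform("exponent", 2)),
               c(0, 0))
  expect_error(speed_transform("piecewise",
                               breakpoints = rbind(c(0, 0), c(0, 1))),
               "strictly increasing")
  expect_error(speed_transform("piecewise",
                               breakpoints = rbind(c(0.5, 0), c(1, 1))),
               "s_in = 0")
})

test_that("gain converts to target distances per second", {
  expect_equal(gain_in_td_per_s(decoder_params(14, 0.9), 14), 1)
  expect_equal(gain_in_td_per_s(decoder_params(4.9 * 3, 0.9), 3), 4.9)
  expect_equal(gain_in_td_per_s(decoder_params(0.5, 0.9), 2), 0.25)
  expect_error(gain_in_td_per_s(decoder_params(1, 0.9), 0), "> 0")
})

test_that("decoder parameter validation rejects out-of-range settings", {
  expect_error(decoder_params(1, 1), "0, 1")
  expect_error(decoder_params(-1, 0.5), "gain_beta")
  expect_error(decoder_params(1, 0.5, dt = 0), "dt")
  expect_error(decoder_params(1, 0.5, dims = 0), "dims")
})
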