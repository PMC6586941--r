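make_session <- function(n_trials = 10, seed = 1) {
  simulate_condition(reference_user(), reference_decoder(), reference_task(),
                     n_trials, seed = seed)
}

test_that("write followed by read restores the session field-by-field", {
  ses <- make_session()
  df <- as_session_frame(ses)
  path <- file.path(tempdir(), "ses.tsv")
  write_session(df, path)
  back <- read_session(path)
  for (col in names(df)) {
    if (is.numeric(df[[col]])) {
      expect_equal(back[[col]], df[[col]], tolerance = 1e-12)
    } else {
      expect_equal(back[[col]], df[[col]])
    }
  }
  cfg <- attr(back, "config")
  expect_equal(cfg$blocks[[1]]$decoder$gain_beta, 0.8)
  expect_equal(cfg$blocks[[1]]$decoder$smoothing_alpha, 0.9)
  unlink(c(path, plmbci:::sidecar_path(path)))
})

test_that("schema validation names the offending row or column", {
  df <- as_session_frame(make_session(4))
  path <- file.path(tempdir(), "bad.tsv")
  # duplicated timestamp within a trial
  bad <- df
  bad$time_s[5] <- bad$time_s[4]
  write_session(structure(bad, config = attr(df, "config"),
                          class = class(df)), path)
  expect_error(read_session(path), "strictly increasing.*row 5")
  # negative radius
  bad <- df
  bad$target_radius[3] <- -1
  write_session(structure(bad, config = attr(df, "config"),
                          class = class(df)), path)
  expect_error(read_session(path), "negative target_radius at row 3")
  # missing required column
  bad <- df
  bad$u_x <- NULL
  write_session(structure(bad, config = attr(df, "config"),
                          class = class(df)), path)
  expect_error(read_session(path), "u_x")
  # non-finite value
  bad <- df
  bad$cursor_y[7] <- NaN
  write_session(structure(bad, config = attr(df, "config"),
                          class = class(df)), path)
  expect_error(read_session(path), "non-finite.*cursor_y")
  unlink(c(path, plmbci:::sidecar_path(path)))
})

test_that("missing velocities are rebuilt by finite differences of position", {
  df <- as_session_frame(make_session(6))
  path <- file.path(tempdir(), "novel.tsv")
  nov <- df
  nov$vel_x <- NULL
  nov$vel_y <- NULL
  write_session(structure(nov, config = attr(df, "config"),
                          class = class(df)), path)
  expect_message(back <- read_session(path), "finite differences")
  # v_t = (p_t - p_{t-1}) / dt matches the stored velocities exactly
  # (position integrates the updated velocity), except the per-trial first
  # sample which is at rest
  expect_equal(back$vel_x, df$vel_x, tolerance = 1e-6)
  expect_equal(back$vel_y, df$vel_y, tolerance = 1e-6)
  unlink(c(path, plmbci:::sidecar_path(path)))
})

test_that("synthetic session files have the requested duration and embed ground truth", {
  gt <- reference_user()
  ses <- make_synthetic_session(gt, reference_decoder(), reference_task(),
                                duration_s = 30, seed = 2)
  expect_identical(nrow(ses), 1500L)
  cfg <- attr(ses, "config")
  expect_equal(cfg$ground_truth$delay_tau, 10L)
  back <- deserialize_user_model(cfg$ground_truth)
  expect_equal(back$policy$f_targ$values, gt$policy$f_targ$values)
  expect_equal(back$noise$innovation_cov, gt$noise$innovation_cov,
               ignore_attr = TRUE)
  ses2 <- make_synthetic_session(gt, reference_decoder(), reference_task(),
                                 duration_s = 30, seed = 3)
  expect_false(identical(ses$u_x, ses2$u_x))
  expect_identical(names(ses), names(ses2))
})

test_that("a session read from disk can be fitted like a simulated one", {
  gt <- reference_user()
  ses <- make_synthetic_session(gt, reference_decoder(), reference_task(),
                                duration_s = 60, seed = 4)
  path <- file.path(tempdir(), "fitme.tsv")
  write_session(ses, path)
  back <- read_session(path)
  fit <- fit_user_model(back, fit_config())    # fixed tau = 10
  expect_lt(abs(slope_of(fit$user$policy$f_vel) - (-1)), 0.35)
  expect_lt(max(abs(diag(fit$user$noise$innovation_cov) / 0.15^2 - 1)), 0.3)
  unlink(c(path, plmbci:::sidecar_path(path)))
})

test_that("the command-line interface chains fixture -> fit -> predict", {
  td <- tempdir()
  fx <- file.path(td, "fix.tsv")
  md <- file.path(td, "model.yaml")
  pr <- file.path(td, "pred.tsv")
  expect_identical(plmbci_cli(c("make-fixture", "--out", fx, "--seed", "3",
                                "--duration", "40", "--log-level", "quiet")),
                   0L)
  expect_true(file.exists(fx))
  expect_identical(suppressMessages(
    plmbci_cli(c("fit", "--session", fx, "--out", md, "--tau", "10",
                 "--log-level", "quiet"))), 0L)
  expect_true(file.exists(md))
  # refitting with the same seed is byte-identical
  md2 <- file.path(td, "model2.yaml")
  suppressMessages(plmbci_cli(c("fit", "--session", fx, "--out", md2,
                                "--tau", "10", "--log-level", "quiet")))
  expect_identical(readLines(md), readLines(md2))
  expect_identical(suppressMessages(
    plmbci_cli(c("predict", "--model", md, "--out", pr, "--n-sims", "30",
                 "--no-adapt", "--log-level", "quiet"))), 0L)
  tab <- read.delim(pr)
  expect_identical(nrow(tab), 3L)
  expect_true(all(is.finite(tab$movement_time)))
  # unknown subcommands and missing options fail with a nonzero status
  expect_identical(suppressMessages(plmbci_cli(c("frobnicate"))), 1L)
  expect_identical(suppressMessages(plmbci_cli(c("fit"))), 1L)
  unlink(c(fx, md, md2, pr, plmbci:::sidecar_path(fx)))
})
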