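#' Gain/smoothing sweep specification
#'
#' @param gain_grid candidate terminal-velocity gains (> 0).
#' @param smoothing_grid candidate smoothing coefficients in [0, 1).
#' @param n_trials_per_cell simulated trials per (gain, smoothing) cell.
#' @param objective default metric optimized by \code{\link{select_params}}.
#' @param seed integer seed.
#' @param adapt re-adapt the user's damping in each cell.
#' @param adapt_cfg an \code{\link{adaptation_config}}.
#' @return an object of class \code{"sweep_spec"}.
#' @export
sweep_spec <- function(gain_grid, smoothing_grid, n_trials_per_cell = 250L,
                       objective = "movement_time", seed = 1L, adapt = TRUE,
                       adapt_cfg = adaptation_config(n_sims_per_slope = 50L)) {
  stopifnot(length(gain_grid) >= 1L, all(gain_grid > 0),
            length(smoothing_grid) >= 1L,
            all(smoothing_grid >= 0 & smoothing_grid < 1))
  structure(list(gain_grid = gain_grid, smoothing_grid = smoothing_grid,
                 n_trials_per_cell = as.integer(n_trials_per_cell),
                 objective = objective, seed = seed, adapt = adapt,
                 adapt_cfg = adapt_cfg), class = "sweep_spec")
}

# per-cell metric means; movement_time is censored (timeouts at max_trial_s)
# so that the optimization objective penalizes failures
cell_metrics <- function(ses) {
  m <- session_metrics(ses)
  cmt <- censored_movement_time(ses)
  data.frame(metric = c("movement_time", "movement_time_success",
                        "translation_time", "dial_in_time",
                        "path_efficiency", "success_rate"),
             mean = c(mean(cmt), mean(m$movement_time, na.rm = TRUE),
                      mean(m$translation_time, na.rm = TRUE),
                      mean(m$dial_in_time, na.rm = TRUE),
                      mean(m$path_efficiency, na.rm = TRUE),
                      mean(m$success)),
             se = c(stats::sd(cmt) / sqrt(length(cmt)),
                    stats::sd(m$movement_time, na.rm = TRUE) /
                      sqrt(max(sum(!is.na(m$movement_time)), 1)),
                    stats::sd(m$translation_time, na.rm = TRUE) /
                      sqrt(max(sum(!is.na(m$translation_time)), 1)),
                    stats::sd(m$dial_in_time, na.rm = TRUE) /
                      sqrt(max(sum(!is.na(m$dial_in_time)), 1)),
                    stats::sd(m$path_efficiency, na.rm = TRUE) /
                      sqrt(max(sum(!is.na(m$path_efficiency)), 1)),
                    stats::sd(m$success) / sqrt(length(m$success))))
}

#' Gain x smoothing performance surfaces
#'
#' Simulates the user under every (gain, smoothing) pair of the grid —
#' re-adapting the velocity damping per cell when \code{spec$adapt} — and
#' records the mean and standard error of each performance metric.
#' \code{movement_time} on the surface is the censored mean (timed-out
#' trials scored at the maximum trial time); \code{movement_time_success}
#' is the mean over successful trials only.
#'
#' @param user a \code{\link{user_model}}.
#' @param task a \code{\link{task_spec}}.
#' @param spec a \code{\link{sweep_spec}}.
#' @param dt,dims decoder time step and dimensionality.
#' @return long-format data.frame (class \code{"performance_surface"}) with
#'   columns gain_beta, smoothing_alpha, metric, mean, se.
#' @export
sweep_surface <- function(user, task, spec, dt = 0.02, dims = 2L) {
  rows <- list()
  k <- 0L
  for (b in spec$gain_grid) for (a in spec$smoothing_grid) {
    k <- k + 1L
    dec <- decoder_params(b, a, dt = dt, dims = dims)
    u_c <- if (spec$adapt)
      adapt_damping(user, dec, task, spec$adapt_cfg, seed = spec$seed) else user
    ses <- simulate_condition(u_c, dec, task, spec$n_trials_per_cell,
                              seed = spec$seed + k)
    cm <- cell_metrics(ses)
    cm$gain_beta <- b
    cm$smoothing_alpha <- a
    rows[[k]] <- cm
  }
  out <- do.call(rbind, rows)[, c("gain_beta", "smoothing_alpha", "metric",
                                  "mean", "se")]
  class(out) <- c("performance_surface", "data.frame")
  out
}

#' Select the optimal (gain, smoothing) pair from a surface
#'
#' Argmin of the objective (argmax when \code{maximize}); ties are broken
#' toward lower gain, then higher smoothing.
#'
#' @param surface a \code{\link{sweep_surface}} result.
#' @param objective metric name present in the surface.
#' @param maximize optimize upward (e.g. for bit rate or success rate).
#' @return list with \code{gain_beta}, \code{smoothing_alpha},
#'   \code{value}.
#' @export
select_params <- function(surface, objective = "movement_time",
                          maximize = FALSE) {
  s <- surface[surface$metric == objective, ]
  if (nrow(s) == 0L) stop("objective not present in surface", call. = FALSE)
  v <- if (maximize) -s$mean else s$mean
  ord <- order(v, s$gain_beta, -s$smoothing_alpha)
  best <- s[ord[1], ]
  list(gain_beta = best$gain_beta, smoothing_alpha = best$smoothing_alpha,
       value = best$mean)
}

#' Grid-keyboard specification
#'
#' A square layout of \code{n_keys} keys tiling the workspace without
#' overlap. A key is selected by holding the cursor inside it, unbroken, for
#' the dwell time; dwelling on a wrong key is a failure.
#'
#' @param n_keys number of keys (a perfect square; default 36, 6 x 6).
#' @param key_size side length of each key, workspace units.
#' @param dwell_grid candidate dwell times in seconds (100 ms steps by
#'   default, 0.3 to 3 s).
#' @param max_trial_s maximum time per selection.
#' @return an object of class \code{"keyboard_spec"}.
#' @export
keyboard_spec <- function(n_keys = 36L, key_size = 0.5,
                          dwell_grid = seq(0.3, 3, by = 0.1),
                          max_trial_s = 10) {
  n_side <- as.integer(round(sqrt(n_keys)))
  if (n_side * n_side != n_keys)
    stop("n_keys must be a perfect square", call. = FALSE)
  structure(list(n_keys = as.integer(n_keys), n_side = n_side,
                 key_size = key_size, dwell_grid = dwell_grid,
                 max_trial_s = max_trial_s), class = "keyboard_spec")
}

key_center <- function(kb, i, j) c((i - 0.5) * kb$key_size,
                                   (j - 0.5) * kb$key_size)

#' Simulate a block of keyboard selections
#'
#' Each trial drives the cursor toward a uniformly random key (different
#' from the current one), starting at the previous target key's center. The
#' cursor position is clamped to the keyboard area. Dwelling on any key for
#' the dwell time selects it.
#'
#' @param user a \code{\link{user_model}}.
#' @param decoder a \code{\link{decoder_params}} (dims must be 2).
#' @param kb a \code{\link{keyboard_spec}}.
#' @param dwell_s dwell time for this block.
#' @param n_trials number of selections to simulate.
#' @param seed integer seed.
#' @return data.frame with per-trial outcome (\code{"correct"},
#'   \code{"wrong"}, \code{"timeout"}) and duration; summary statistics in
#'   attributes \code{n_correct}, \code{n_wrong}, \code{elapsed_s},
#'   \code{bit_rate}.
#' @export
simulate_keyboard <- function(user, decoder, kb, dwell_s, n_trials,
                              seed = 1L) {
  stopifnot(decoder$dims == 2L, dwell_s < kb$max_trial_s)
  ne <- noise_engine_args(user$noise, 2L)
  tr <- decoder$transform
  bk <- transform_bk(tr)
  seeds <- trial_seeds(seed, n_trials)
  cur <- c(ceiling(kb$n_side / 2), ceiling(kb$n_side / 2))  # start mid-grid
  out <- data.frame(outcome = character(n_trials),
                    duration = numeric(n_trials))
  for (k in seq_len(n_trials)) {
    set.seed(seeds[k])
    repeat {
      tgt <- c(sample.int(kb$n_side, 1L), sample.int(kb$n_side, 1L))
      if (any(tgt != cur)) break
    }
    res <- cpp_simulate_trial(
      key_center(kb, cur[1], cur[2]), c(0, 0),
      key_center(kb, tgt[1], tgt[2]), kb$key_size / 2,
      user$policy$f_targ$knots, user$policy$f_targ$values,
      user$policy$f_vel$knots, user$policy$f_vel$values,
      ne$n_lags, ne$Pi, ne$cholL, ne$sdnk, ne$sdnv, ne$sdn_on,
      user$delay_tau, decoder$smoothing_alpha, decoder$gain_beta, decoder$dt,
      transform_code(tr), tr$exponent_p, bk[, 1], bk[, 2],
      max_steps = as.integer(round(kb$max_trial_s / decoder$dt)),
      dwell_steps = as.integer(ceiling(dwell_s / decoder$dt - 1e-9)),
      burnin = 100L, mode = 1L, key_origin = 0, key_w = kb$key_size,
      n_side = kb$n_side, clamp_ws = TRUE, ws_lo = 0,
      ws_hi = kb$n_side * kb$key_size)
    out$outcome[k] <- c("timeout", "wrong", "correct")[res$outcome + 1L]
    out$duration[k] <- if (is.na(res$t_acquire)) kb$max_trial_s else res$t_acquire
    cur <- tgt
  }
  attr(out, "n_correct") <- sum(out$outcome == "correct")
  attr(out, "n_wrong") <- sum(out$outcome == "wrong")
  attr(out, "elapsed_s") <- sum(out$duration)
  attr(out, "bit_rate") <- achieved_bit_rate(kb$n_keys,
                                             attr(out, "n_correct"),
                                             attr(out, "n_wrong"),
                                             attr(out, "elapsed_s"))
  out
}

# proxy radial task used when adapting the damping for keyboard conditions:
# typical inter-key distance, inscribed key radius, same dwell
keyboard_proxy_task <- function(kb, dwell_s) {
  dist <- kb$key_size * kb$n_side / 2
  task_spec(center_out_targets(dist, kb$key_size / 2),
            dwell_s = dwell_s, max_trial_s = kb$max_trial_s)
}

#' Dwell-time and decoder optimization for a grid keyboard
#'
#' For each dwell time in the keyboard's grid, sweeps (gain, smoothing)
#' pairs and records the pair maximizing the achieved bit rate, together
#' with the bit rate, mean selection time, and success rate at that
#' optimum.
#'
#' @param user a \code{\link{user_model}}.
#' @param kb a \code{\link{keyboard_spec}}.
#' @param gain_grid,smoothing_grid decoder grids (defaults: 30 x 30).
#' @param n_trials_per_cell selections simulated per grid cell.
#' @param seed integer seed.
#' @param dt decoder time step.
#' @param adapt re-adapt damping per dwell time (on a radial proxy task).
#' @param adapt_cfg an \code{\link{adaptation_config}}.
#' @return data.frame with one row per dwell time: optimal gain/smoothing,
#'   bit rate, mean acquire time, success rate.
#' @export
optimize_keyboard <- function(user, kb,
                              gain_grid = NULL, smoothing_grid = NULL,
                              n_trials_per_cell = 100L, seed = 1L, dt = 0.02,
                              adapt = TRUE,
                              adapt_cfg = adaptation_config(n_sims_per_slope = 50L)) {
  if (is.null(gain_grid))
    gain_grid <- exp(seq(log(0.5), log(8), length.out = 30L)) *
      kb$key_size * kb$n_side / 6
  if (is.null(smoothing_grid))
    smoothing_grid <- seq(0.5, 0.985, length.out = 30L)
  rows <- list()
  for (di in seq_along(kb$dwell_grid)) {
    dw <- kb$dwell_grid[di]
    u_d <- user
    best <- NULL
    a_mid <- smoothing_grid[ceiling(length(smoothing_grid) / 2)]
    for (b in gain_grid) {
      dec0 <- decoder_params(b, a_mid, dt = dt, dims = 2L)
      if (adapt)
        u_d <- adapt_damping(user, dec0, keyboard_proxy_task(kb, dw),
                             adapt_cfg, seed = seed + di)
      for (a in smoothing_grid) {
        dec <- decoder_params(b, a, dt = dt, dims = 2L)
        sim <- simulate_keyboard(u_d, dec, kb, dw, n_trials_per_cell,
                                 seed = seed + 1000L * di)
        br <- attr(sim, "bit_rate")
        cand <- list(gain_beta = b, smoothing_alpha = a, bit_rate = br,
                     mean_acquire_s = mean(sim$duration),
                     success_rate = mean(sim$outcome == "correct"))
        if (is.null(best) || br > best$bit_rate) best <- cand
      }
    }
    rows[[di]] <- data.frame(dwell_s = dw, gain_beta = best$gain_beta,
                             smoothing_alpha = best$smoothing_alpha,
                             bit_rate = best$bit_rate,
                             mean_acquire_s = best$mean_acquire_s,
                             success_rate = best$success_rate)
  }
  do.call(rbind, rows)
}

#' Speed-transform search specification
#'
#' @param variant \code{"piecewise"} (pattern search over breakpoint
#'   ordinates) or \code{"exponent"} (joint exhaustive grid over gain,
#'   smoothing, and the exponent).
#' @param n_breakpoints breakpoints of the piecewise transform, evenly
#'   spaced from 0 to \code{bp_span} on the normalized control scale.
#' @param bp_span upper end of the breakpoint span (1.25 x the full-effort
#'   magnitude of 1).
#' @param n_restarts independent pattern searches whose results are
#'   averaged pointwise.
#' @param sims_per_eval simulated movements per objective evaluation.
#' @param exponent_grid candidate exponents for the exponent variant.
#' @param gain_grid,smoothing_grid decoder grids for the exponent variant's
#'   joint search (default: around the base decoder).
#' @param step0,min_step,max_iter pattern-search step schedule.
#' @param seed integer seed.
#' @return an object of class \code{"transform_search_spec"}.
#' @export
transform_search_spec <- function(variant = c("piecewise", "exponent"),
                                  n_breakpoints = 14L, bp_span = 1.25,
                                  n_restarts = 24L, sims_per_eval = 200L,
                                  exponent_grid = seq(0.5, 3, by = 0.25),
                                  gain_grid = NULL, smoothing_grid = NULL,
                                  step0 = 0.25, min_step = 0.02,
                                  max_iter = 60L, seed = 1L) {
  variant <- match.arg(variant)
  structure(list(variant = variant, n_breakpoints = as.integer(n_breakpoints),
                 bp_span = bp_span, n_restarts = as.integer(n_restarts),
                 sims_per_eval = as.integer(sims_per_eval),
                 exponent_grid = exponent_grid, gain_grid = gain_grid,
                 smoothing_grid = smoothing_grid, step0 = step0,
                 min_step = min_step, max_iter = as.integer(max_iter),
                 seed = seed), class = "transform_search_spec")
}

# censored mean movement time of n simulated trials under a fixed seed
transform_objective <- function(user, decoder, task, n_sims, seed) {
  ses <- simulate_condition(user, decoder, task, n_sims, seed = seed)
  mean(censored_movement_time(ses))
}

# derivative-free coordinate pattern search with shrinking step; only
# accepts moves that improve the common-random-number objective estimate
pattern_search <- function(f, x0, step0, min_step, max_iter, lower = 0) {
  x <- x0
  fx <- f(x)
  step <- step0
  it <- 0L
  while (step >= min_step && it < max_iter) {
    it <- it + 1L
    improved <- FALSE
    for (j in seq_along(x)) {
      for (s in c(step, -step)) {
        xc <- x
        xc[j] <- max(xc[j] + s, lower)
        if (xc[j] == x[j]) next
        fc <- f(xc)
        if (fc < fx - 1e-12) {
          x <- xc
          fx <- fc
          improved <- TRUE
        }
      }
    }
    if (!improved) step <- step / 2
  }
  list(x = x, value = fx)
}

#' Optimize a nonlinear speed transform by simulation
#'
#' Piecewise variant: a derivative-free coordinate pattern search over the
#' ordinates of a piecewise-linear transform (breakpoints evenly spaced on
#' the normalized control scale; the ordinate at 0 is pinned to 0), run
#' from \code{n_restarts} starts and averaged pointwise; the average is
#' projected to a monotone non-decreasing function (isotonic regression)
#' since averaging can break monotonicity. The objective of every
#' evaluation is the censored mean movement time of
#' \code{sims_per_eval} simulated movements with common random numbers.
#' The base decoder should already carry the sweep-optimal linear gain and
#' smoothing.
#'
#' Exponent variant: exhaustive joint grid search over (gain, smoothing,
#' exponent) minimizing the same objective.
#'
#' @param user a \code{\link{user_model}}.
#' @param decoder base \code{\link{decoder_params}}.
#' @param task a \code{\link{task_spec}}.
#' @param spec a \code{\link{transform_search_spec}}.
#' @param adapt re-adapt the damping for each decoder setting evaluated.
#' @param adapt_cfg an \code{\link{adaptation_config}}.
#' @return for \code{"piecewise"}: the optimized
#'   \code{\link{speed_transform}} with search diagnostics in attributes;
#'   for \code{"exponent"}: list with \code{decoder} (optimal gain,
#'   smoothing, and exponent transform), \code{exponent_p}, and the search
#'   \code{grid} of objective values.
#' @export
optimize_speed_transform <- function(user, decoder, task, spec,
                                     adapt = TRUE,
                                     adapt_cfg = adaptation_config(n_sims_per_slope = 50L)) {
  if (spec$variant == "exponent") {
    gg <- spec$gain_grid
    if (is.null(gg)) gg <- decoder$gain_beta * c(0.5, 0.75, 1, 1.5, 2)
    sg <- spec$smoothing_grid
    if (is.null(sg)) sg <- unique(pmin(pmax(
      decoder$smoothing_alpha + c(-0.1, -0.05, 0, 0.04, 0.08), 0), 0.99))
    grid <- expand.grid(gain_beta = gg, smoothing_alpha = sg,
                        exponent_p = spec$exponent_grid)
    grid$objective <- NA_real_
    for (r in seq_len(nrow(grid))) {
      tr <- if (abs(grid$exponent_p[r] - 1) < 1e-12) speed_transform() else
        speed_transform("exponent", grid$exponent_p[r])
      dec <- decoder_params(grid$gain_beta[r], grid$smoothing_alpha[r],
                            dt = decoder$dt, dims = decoder$dims,
                            transform = tr)
      u_r <- if (adapt) adapt_damping(user, dec, task, adapt_cfg,
                                      seed = spec$seed) else user
      grid$objective[r] <- transform_objective(u_r, dec, task,
                                               spec$sims_per_eval,
                                               seed = spec$seed + 1L)
    }
    best <- grid[order(grid$objective, grid$gain_beta,
                       -grid$smoothing_alpha), ][1, ]
    tr <- if (abs(best$exponent_p - 1) < 1e-12) speed_transform() else
      speed_transform("exponent", best$exponent_p)
    list(decoder = decoder_params(best$gain_beta, best$smoothing_alpha,
                                  dt = decoder$dt, dims = decoder$dims,
                                  transform = tr),
         exponent_p = best$exponent_p, objective = best$objective,
         grid = grid)
  } else {
    bp_in <- seq(0, spec$bp_span, length.out = spec$n_breakpoints)
    u_s <- if (adapt) adapt_damping(user, decoder, task, adapt_cfg,
                                    seed = spec$seed) else user
    obj_for <- function(ord, seed) {
      tr <- speed_transform("piecewise", breakpoints = cbind(bp_in, c(0, ord)))
      dec <- decoder_params(decoder$gain_beta, decoder$smoothing_alpha,
                            dt = decoder$dt, dims = decoder$dims,
                            transform = tr)
      transform_objective(u_s, dec, task, spec$sims_per_eval, seed = seed)
    }
    sols <- matrix(NA_real_, spec$n_restarts, spec$n_breakpoints - 1L)
    vals <- numeric(spec$n_restarts)
    for (r in seq_len(spec$n_restarts)) {
      seed_r <- spec$seed + 101L * r
      set.seed(seed_r)
      x0 <- bp_in[-1] * stats::runif(1, 0.7, 1.3)  # jittered identity start
      ps <- pattern_search(function(x) obj_for(x, seed_r), x0,
                           spec$step0, spec$min_step, spec$max_iter)
      sols[r, ] <- ps$x
      vals[r] <- ps$value
    }
    avg <- colMeans(sols)
    iso <- stats::isoreg(bp_in, c(0, avg))$yf   # monotone projection
    iso <- pmax(iso, 0)
    iso[1] <- 0
    out <- speed_transform("piecewise", breakpoints = cbind(bp_in, iso))
    attr(out, "restart_values") <- vals
    attr(out, "restart_solutions") <- sols
    out
  }
}
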