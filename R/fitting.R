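#' Model-fitting configuration
#'
#' Constants of the user-model fit: the number of policy/estimate
#' alternations, knot placement for the policy functions, AR lag-selection
#' settings, and signal-dependent-noise binning.
#'
#' @param n_policy_iterations alternations of policy regression and
#'   internal-estimate recomputation (default 5).
#' @param f_targ_knots abscissae for f_targ, or \code{NULL} for 8 knots
#'   evenly spaced from 0 to the maximum observed target distance.
#' @param f_vel_knots abscissae for f_vel, or \code{NULL} for 6 knots evenly
#'   spaced from 0 to the 95th percentile of observed speed.
#' @param max_lags largest AR order considered.
#' @param cv_folds contiguous-block cross-validation folds for lag selection.
#' @param cv_tolerance minimum one-step-ahead R-squared improvement for
#'   accepting another lag.
#' @param sdn_bins number of \code{||c||} bins for the signal-dependent
#'   noise fit.
#' @param sdn_range range of \code{||c||} covered by the bins.
#' @param sdn_min_samples minimum samples for a bin to be estimated; sparser
#'   bins inherit the nearest populated bin's scale.
#' @param fit_sdn estimate the signal-dependent scaling (default TRUE).
#' @param delay_tau feedback delay in steps, or \code{"grid"} to search
#'   0..25 for the delay maximizing the final policy-fit R-squared.
#' @return an object of class \code{"fit_config"}.
#' @export
fit_config <- function(n_policy_iterations = 5L, f_targ_knots = NULL,
                       f_vel_knots = NULL, max_lags = 10L, cv_folds = 5L,
                       cv_tolerance = 1e-3, sdn_bins = 20L,
                       sdn_range = c(0, 1.5), sdn_min_samples = 30L,
                       fit_sdn = TRUE, delay_tau = 10L) {
  stopifnot(n_policy_iterations >= 1L, max_lags >= 0L, cv_folds >= 2L)
  structure(list(n_policy_iterations = as.integer(n_policy_iterations),
                 f_targ_knots = f_targ_knots, f_vel_knots = f_vel_knots,
                 max_lags = as.integer(max_lags),
                 cv_folds = as.integer(cv_folds),
                 cv_tolerance = cv_tolerance, sdn_bins = as.integer(sdn_bins),
                 sdn_range = sdn_range,
                 sdn_min_samples = as.integer(sdn_min_samples),
                 fit_sdn = fit_sdn, delay_tau = delay_tau),
            class = "fit_config")
}

# Canonical per-sample arrays for fitting. Sample t carries the state x_t the
# decoder output u_t acted from; the final state of each trial is dropped.
as_fit_data <- function(session, ...) UseMethod("as_fit_data")

#' @export
as_fit_data.simulated_session <- function(session, ...) {
  pos <- vel <- u <- targ <- NULL
  trial_start <- integer(0)
  off <- 0L
  for (tr in session$trials) {
    n <- nrow(tr$u)
    pos <- rbind(pos, tr$pos[seq_len(n), , drop = FALSE])
    vel <- rbind(vel, tr$vel[seq_len(n), , drop = FALSE])
    u <- rbind(u, tr$u)
    targ <- rbind(targ, matrix(tr$target, n, length(tr$target), byrow = TRUE))
    trial_start <- c(trial_start, rep(off, n))
    off <- off + n
  }
  list(pos = pos, vel = vel, u = u, targ = targ,
       trial_start = trial_start, dt = session$decoder$dt,
       d = ncol(pos), decoder = session$decoder, task = session$task)
}

#' @export
as_fit_data.list <- function(session, ...) {
  stopifnot(all(c("pos", "vel", "u", "targ", "trial_start", "dt") %in%
                  names(session)))
  session$d <- ncol(session$pos)
  session
}

resample_trials <- function(session, idx) UseMethod("resample_trials")

#' @export
resample_trials.simulated_session <- function(session, idx) {
  out <- session
  out$trials <- session$trials[idx]
  out
}

# policy regression for one set of internal estimates; returns knot values
policy_regression <- function(u, targ, est_p, est_v, ft_knots, fv_knots) {
  d <- ncol(u)
  dvec <- targ - est_p
  dn <- sqrt(rowSums(dvec^2))
  dirT <- dvec / pmax(dn, 1e-9)
  dirT[dn < 1e-9, ] <- 0
  sn <- sqrt(rowSums(est_v^2))
  dirV <- est_v / pmax(sn, 1e-9)
  dirV[sn < 1e-9, ] <- 0
  WT <- pl_weights(ft_knots, dn)
  WV <- pl_weights(fv_knots, sn)
  KT <- length(ft_knots)
  X <- do.call(rbind, lapply(seq_len(d), function(i)
    cbind(dirT[, i] * WT, dirV[, i] * WV)))
  y <- as.numeric(u)
  cn <- sqrt(colSums(X^2))
  keep <- cn > 1e-7 * sqrt(nrow(X))
  theta <- numeric(ncol(X))
  if (!all(keep)) {
    warning("some policy knots have no supporting samples; tying to nearest identifiable neighbor")
    fit <- stats::lm.fit(X[, keep, drop = FALSE], y)
    theta[keep] <- fit$coefficients
    for (j in which(!keep)) {  # nearest kept knot within the same function
      grp <- if (j <= KT) seq_len(KT) else KT + seq_len(ncol(X) - KT)
      cand <- intersect(grp, which(keep))
      if (length(cand)) theta[j] <- theta[cand[which.min(abs(cand - j))]]
    }
  } else {
    theta <- stats::lm.fit(X, y)$coefficients
  }
  theta[is.na(theta)] <- 0
  fitted <- as.numeric(X %*% theta)
  list(ft_values = pmax(theta[seq_len(KT)], 0),
       fv_values = theta[(KT + 1):ncol(X)],
       sse = sum((y - fitted)^2),
       r2 = 1 - sum((y - fitted)^2) / sum((y - mean(y))^2))
}

#' Fit the piecewise-linear control policy
#'
#' Iterative fit of f_targ and f_vel together with the user's internal state
#' estimates: (1) initialize the estimates to delayed true cursor states;
#' (2) solve the knot ordinates by linear least squares (via interpolation
#' weights, the ordinates are linear parameters) minimizing the error
#' between the modeled control vector and the observed decoder output; (3)
#' recompute the estimates by running the forward model from delayed true
#' states with efference copies of the modeled control; repeat (2)-(3) for
#' \code{n_policy_iterations}.
#'
#' @param session a \code{\link{simulate_condition}} session, a session read
#'   with \code{\link{read_session}}, or a prepared fit-data list.
#' @param tau assumed feedback delay in steps.
#' @param decoder training-block \code{\link{decoder_params}} (taken from
#'   the session if omitted).
#' @param cfg a \code{\link{fit_config}}.
#' @return list with the fitted \code{policy}, the modeled control series
#'   \code{c_hat}, internal estimates \code{p_hat}/\code{v_hat},
#'   per-iteration \code{r2} and \code{sse}, and the knots used.
#' @export
fit_control_policy <- function(session, tau, decoder = NULL,
                               cfg = fit_config()) {
  fd <- as_fit_data(session)
  if (is.null(decoder)) decoder <- fd$decoder
  stopifnot(!is.null(decoder))
  d <- fd$d
  TT <- nrow(fd$u)
  dn_obs <- sqrt(rowSums((fd$targ - fd$pos)^2))
  ft_knots <- cfg$f_targ_knots
  if (is.null(ft_knots)) ft_knots <- seq(0, max(dn_obs), length.out = 8L)
  fv_knots <- cfg$f_vel_knots
  if (is.null(fv_knots)) {
    smax <- stats::quantile(sqrt(rowSums(fd$vel^2)), 0.95, names = FALSE)
    fv_knots <- seq(0, max(smax, 1e-3), length.out = 6L)
  }
  # step 1: delayed true states, clamped at each trial's first sample
  idx <- pmax(seq_len(TT) - tau, fd$trial_start + 1L)
  est_p <- fd$pos[idx, , drop = FALSE]
  est_v <- fd$vel[idx, , drop = FALSE]
  r2 <- sse <- numeric(cfg$n_policy_iterations)
  fw <- NULL
  for (it in seq_len(cfg$n_policy_iterations)) {
    reg <- policy_regression(fd$u, fd$targ, est_p, est_v, ft_knots, fv_knots)
    r2[it] <- reg$r2
    sse[it] <- reg$sse
    fw <- cpp_policy_forward(fd$pos, fd$vel, fd$targ, fd$trial_start,
                             tau, decoder$smoothing_alpha, decoder$gain_beta,
                             decoder$dt, ft_knots, reg$ft_values,
                             fv_knots, reg$fv_values)
    est_p <- fw$p_hat
    est_v <- fw$v_hat
  }
  policy <- control_policy(piecewise_linear(ft_knots, reg$ft_values),
                           piecewise_linear(fv_knots, reg$fv_values))
  list(policy = policy, c_hat = fw$c_hat, p_hat = fw$p_hat, v_hat = fw$v_hat,
       r2 = r2, sse = sse, ft_knots = ft_knots, fv_knots = fv_knots)
}

var_design <- function(E, q) {
  TT <- nrow(E)
  d <- ncol(E)
  Y <- E[(q + 1):TT, , drop = FALSE]
  if (q == 0L) return(list(X = NULL, Y = Y))
  X <- do.call(cbind, lapply(seq_len(q), function(i)
    E[(q + 1 - i):(TT - i), , drop = FALSE]))
  list(X = X, Y = Y)
}

# one-step-ahead R^2 (averaged over dimensions) under contiguous-block CV
cv_predictive_r2 <- function(E, q, folds) {
  dz <- var_design(E, q)
  n <- nrow(dz$Y)
  fold_id <- cut(seq_len(n), folds, labels = FALSE)
  r2s <- numeric(folds)
  for (f in seq_len(folds)) {
    test <- fold_id == f
    if (q == 0L) {
      pred <- matrix(0, sum(test), ncol(E))
    } else {
      B <- stats::lm.fit(dz$X[!test, , drop = FALSE],
                         dz$Y[!test, , drop = FALSE])$coefficients
      B[is.na(B)] <- 0
      pred <- dz$X[test, , drop = FALSE] %*% B
    }
    err <- dz$Y[test, , drop = FALSE] - pred
    sst <- colSums(sweep(dz$Y[test, , drop = FALSE], 2,
                         colMeans(dz$Y[!test, , drop = FALSE]))^2)
    r2s[f] <- mean(1 - colSums(err^2) / pmax(sst, 1e-12))
  }
  mean(r2s)
}

#' Fit the autoregressive decoding-noise model
#'
#' Fits AR coefficient matrices by least squares for orders 0 to
#' \code{max_lags}, selecting the smallest order after which the
#' cross-validated one-step-ahead R-squared stops improving by
#' \code{cv_tolerance}. The innovation covariance is the covariance of the
#' AR prediction errors. The signal-dependent scaling f_SDN is estimated by
#' binning \code{||c_t||}, computing each populated bin's innovation
#' covariance, and least-squares-matching it to the full-data covariance by
#' a scalar (sparse bins inherit the nearest populated bin's scale).
#'
#' @param residuals matrix of decoding errors \code{e_t = u_t - c_t}, one
#'   row per step.
#' @param c_series matrix of modeled control vectors (same rows); used only
#'   for the signal-dependent fit.
#' @param cfg a \code{\link{fit_config}}.
#' @return a \code{\link{noise_model}} with attributes \code{"cv_curve"}
#'   (data.frame order/cv_r2) and \code{"sdn_scales"}.
#' @export
fit_noise_model <- function(residuals, c_series = NULL, cfg = fit_config()) {
  E <- as.matrix(residuals)
  TT <- nrow(E)
  d <- ncol(E)
  stopifnot(TT >= cfg$max_lags + 100L)
  cv <- vapply(0:cfg$max_lags, function(q) cv_predictive_r2(E, q, cfg$cv_folds),
               numeric(1))
  q <- 0L
  while (q < cfg$max_lags && cv[q + 2L] > cv[q + 1L] + cfg$cv_tolerance)
    q <- q + 1L
  dz <- var_design(E, q)
  if (q == 0L) {
    innov <- dz$Y
    ar <- list()
  } else {
    B <- stats::lm.fit(dz$X, dz$Y)$coefficients
    B[is.na(B)] <- 0
    innov <- dz$Y - dz$X %*% B
    ar <- lapply(seq_len(q), function(i)
      t(B[((i - 1) * d + 1):(i * d), , drop = FALSE]))
  }
  Sigma <- stats::cov(innov)
  sdn_fn <- NULL
  scales <- NULL
  if (cfg$fit_sdn && !is.null(c_series)) {
    cmag <- sqrt(rowSums(as.matrix(c_series)^2))[(q + 1):TT]
    edges <- seq(cfg$sdn_range[1], cfg$sdn_range[2],
                 length.out = cfg$sdn_bins + 1L)
    centers <- (edges[-1] + edges[-length(edges)]) / 2
    bin <- pmin(pmax(findInterval(cmag, edges, rightmost.closed = TRUE), 1L),
                cfg$sdn_bins)
    cnt <- tabulate(bin, cfg$sdn_bins)
    pop <- which(cnt >= cfg$sdn_min_samples)
    if (length(pop) < 2L) {
      warning("fewer than 2 populated SDN bins; using a constant noise scale")
    } else {
      denom <- sum(Sigma * Sigma)
      scales <- rep(NA_real_, cfg$sdn_bins)
      for (b in pop) {
        Sb <- stats::cov(innov[bin == b, , drop = FALSE])
        scales[b] <- max(sum(Sb * Sigma) / denom, 0)
      }
      for (b in which(is.na(scales)))  # inherit nearest populated bin
        scales[b] <- scales[pop[which.min(abs(pop - b))]]
      sdn_fn <- piecewise_linear(centers, scales)
    }
  }
  out <- noise_model(n_lags = q, ar_coeffs = ar, innovation_cov = Sigma,
                     sdn_fn = sdn_fn)
  attr(out, "cv_curve") <- data.frame(order = 0:cfg$max_lags, cv_r2 = cv)
  attr(out, "sdn_scales") <- scales
  out
}

#' Fit the full user model from one block of closed-loop data
#'
#' Resolves the feedback delay (fixed, or a grid search over 0..25 steps
#' maximizing the final policy-fit R-squared), runs the iterative
#' control-policy fit, and fits the AR noise model to the residuals
#' \code{e_t = u_t - c_t}.
#'
#' @param session training session (see \code{\link{fit_control_policy}}).
#' @param cfg a \code{\link{fit_config}}.
#' @param decoder training-block \code{\link{decoder_params}} (from the
#'   session if omitted).
#' @return an object of class \code{"fit_report"}: the fitted \code{user}
#'   (\code{\link{user_model}}), \code{tau}, per-iteration policy
#'   \code{r2}/\code{sse}, the AR \code{cv_curve} and selected
#'   \code{n_lags}, residual diagnostics, and the training condition.
#' @export
fit_user_model <- function(session, cfg = fit_config(), decoder = NULL) {
  fd <- as_fit_data(session)
  if (is.null(decoder)) decoder <- fd$decoder
  stopifnot(!is.null(decoder))
  tau_grid <- NULL
  if (identical(cfg$delay_tau, "grid")) {
    # Residual-whiteness criterion: at the true delay the residuals are the
    # pure AR decoding noise, so the generalized variance of their AR
    # innovations is minimized. (Maximizing raw policy-fit R^2 instead is
    # biased toward tau = 0: with positively correlated noise, the damping
    # term built from the undelayed state absorbs predictable noise.)
    taus <- 0:25
    crit <- r2s <- numeric(length(taus))
    for (i in seq_along(taus)) {
      pf_i <- fit_control_policy(fd, taus[i], decoder, cfg)
      r2s[i] <- utils::tail(pf_i$r2, 1)
      E <- fd$u - pf_i$c_hat
      dz <- var_design(E, min(3L, cfg$max_lags))
      innov <- if (is.null(dz$X)) dz$Y else {
        B <- stats::lm.fit(dz$X, dz$Y)$coefficients
        B[is.na(B)] <- 0
        dz$Y - dz$X %*% B
      }
      crit[i] <- det(stats::cov(innov))
    }
    tau_grid <- data.frame(tau = taus, r2 = r2s, innovation_gv = crit)
    if (diff(range(crit)) < 0.01 * min(crit)) {
      warning("tau criterion nearly flat across grid; using smallest tau")
      tau <- taus[1]
    } else tau <- taus[which.min(crit)]
  } else tau <- as.integer(cfg$delay_tau)
  pf <- fit_control_policy(fd, tau, decoder, cfg)
  resid <- fd$u - pf$c_hat
  noise <- fit_noise_model(resid, pf$c_hat, cfg)
  user <- user_model(pf$policy, noise, tau)
  structure(list(user = user, tau = tau, r2 = pf$r2, sse = pf$sse,
                 n_lags = noise$n_lags, cv_curve = attr(noise, "cv_curve"),
                 sdn_scales = attr(noise, "sdn_scales"),
                 innovation_cov = noise$innovation_cov,
                 residual_sd = apply(resid, 2, stats::sd),
                 tau_grid = tau_grid,
                 decoder = decoder, task = fd$task),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("PLM fit: tau = %d steps, AR order = %d, final policy R^2 = %.3f\n",
              x$tau, x$n_lags, utils::tail(x$r2, 1)))
  cat("innovation sd per dim:", paste(signif(sqrt(diag(x$innovation_cov)), 3),
                                      collapse = ", "), "\n")
  invisible(x)
}

#' Predict performance under held-out decoder/task conditions
#'
#' For each condition, the fitted user's velocity damping is first
#' re-adapted to the condition by simulation (\code{\link{adapt_damping}};
#' disable with \code{adapt = FALSE}), \code{n_sims} trials are simulated,
#' and the trial metrics are summarized with percentile-bootstrap confidence
#' intervals.
#'
#' @param fitted a \code{\link{fit_user_model}} report or a
#'   \code{\link{user_model}}.
#' @param conditions list of \code{list(decoder =, task =)} pairs.
#' @param n_sims simulated trials per condition.
#' @param seed integer seed.
#' @param adapt re-adapt f_vel per condition (default TRUE).
#' @param adapt_cfg an \code{\link{adaptation_config}}.
#' @param n_boot bootstrap resamples for the per-condition CIs.
#' @return data.frame (class \code{"condition_predictions"}) with one row
#'   per condition: the condition's gain/smoothing, metric means, and
#'   success rate; full summaries in \code{attr(, "summaries")}.
#' @export
predict_conditions <- function(fitted, conditions, n_sims = 1000L, seed = 1L,
                               adapt = TRUE,
                               adapt_cfg = adaptation_config(),
                               n_boot = 500L) {
  user <- if (inherits(fitted, "fit_report")) fitted$user else fitted
  stopifnot(inherits(user, "user_model"))
  summaries <- vector("list", length(conditions))
  rows <- vector("list", length(conditions))
  for (i in seq_along(conditions)) {
    cond <- conditions[[i]]
    u_i <- if (adapt)
      adapt_damping(user, cond$decoder, cond$task, adapt_cfg,
                    seed = seed + 7919L * i) else user
    ses <- simulate_condition(u_i, cond$decoder, cond$task, n_sims,
                              seed = seed + i)
    sm <- summarize_condition(ses, n_boot = n_boot, seed = seed + i)
    summaries[[i]] <- sm
    mt <- function(name) sm$mean[sm$metric == name]
    rows[[i]] <- data.frame(
      condition = i, gain_beta = cond$decoder$gain_beta,
      smoothing_alpha = cond$decoder$smoothing_alpha,
      movement_time = mt("movement_time"),
      translation_time = mt("translation_time"),
      dial_in_time = mt("dial_in_time"),
      path_efficiency = mt("path_efficiency"),
      success_rate = mt("success_rate"),
      adapted_slope = if (adapt) attr(u_i, "slope") else NA_real_)
  }
  out <- do.call(rbind, rows)
  attr(out, "summaries") <- summaries
  class(out) <- c("condition_predictions", "data.frame")
  out
}

#' Bootstrap confidence intervals for held-out-condition predictions
#'
#' Resamples the training trials with replacement, refits the full user
#' model on each resample, re-predicts every condition, and returns 2.5/97.5
#' percentile intervals per condition and metric. The intervals express the
#' prediction uncertainty due to limited training data.
#'
#' @param session training session (must contain per-trial records, e.g. a
#'   \code{\link{simulate_condition}} result or a read session).
#' @param cfg a \code{\link{fit_config}}.
#' @param conditions list of \code{list(decoder =, task =)} pairs.
#' @param n_boot bootstrap replicates (>= 100 recommended).
#' @param seed integer seed.
#' @param n_sims simulated trials per condition inside each replicate.
#' @param adapt re-adapt f_vel per condition.
#' @param adapt_cfg an \code{\link{adaptation_config}}.
#' @return data.frame with condition, metric, ci_lo, ci_hi.
#' @export
bootstrap_prediction_ci <- function(session, cfg = fit_config(), conditions,
                                    n_boot = 100L, seed = 1L, n_sims = 200L,
                                    adapt = TRUE,
                                    adapt_cfg = adaptation_config(n_sims_per_slope = 50L)) {
  n_tr <- length(session$trials)
  stopifnot(n_tr >= 2L)
  set.seed(seed)
  metrics <- c("movement_time", "translation_time", "dial_in_time",
               "path_efficiency", "success_rate")
  acc <- array(NA_real_, c(n_boot, length(conditions), length(metrics)))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n_tr, n_tr, replace = TRUE)
    fit_b <- fit_user_model(resample_trials(session, idx), cfg)
    pr <- predict_conditions(fit_b, conditions, n_sims = n_sims,
                             seed = seed + 31L * b, adapt = adapt,
                             adapt_cfg = adapt_cfg, n_boot = 2L)
    for (m in seq_along(metrics)) acc[b, , m] <- pr[[metrics[m]]]
  }
  out <- expand.grid(condition = seq_along(conditions), metric = metrics,
                     stringsAsFactors = FALSE)
  out$ci_lo <- out$ci_hi <- NA_real_
  for (r in seq_len(nrow(out))) {
    v <- acc[, out$condition[r], match(out$metric[r], metrics)]
    q <- stats::quantile(v, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    out$ci_lo[r] <- q[1]
    out$ci_hi[r] <- q[2]
  }
  out
}
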