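#' Trial-level performance metrics
#'
#' Computes, for a completed trial: total movement time (target onset to
#' acquisition), translation time (onset to first cursor-target contact),
#' dial-in time (first contact to acquisition, minus the obligatory dwell
#' time — the cost of stopping and staying on the target), path efficiency
#' (straight-line start-to-target distance divided by the distance the
#' cursor actually traveled, capped at 1), success, and the Fitts index of
#' difficulty of the movement. For failed (timeout) trials the time metrics
#' are \code{NA}; such trials enter success rates but are excluded from time
#' and path means.
#'
#' On every successful trial the decomposition
#' \code{movement_time = translation_time + dial_in_time + dwell_s} holds
#' exactly in step units.
#'
#' @param trial a \code{\link{simulate_trial}} record.
#' @param task the \code{\link{task_spec}} the trial was run under (supplies
#'   the dwell time; defaults to the value stored in the record).
#' @return a one-row data.frame of class \code{"trial_metrics"}.
#' @export
trial_metrics <- function(trial, task = NULL) {
  dwell <- if (is.null(task)) trial$dwell_s else task$dwell_s
  success <- identical(trial$outcome, "success")
  seg <- diff(trial$pos)
  L <- sum(sqrt(rowSums(seg^2)))
  D <- sqrt(sum((trial$target - trial$start)^2))
  pe <- if (L <= 0) {
    warning("trial with zero path length: path efficiency undefined")
    NA_real_
  } else min(1, D / L)
  mt <- if (success) trial$t_acquire else NA_real_
  tt <- if (is.na(trial$t_first_contact)) NA_real_ else trial$t_first_contact
  di <- if (success && !is.na(tt)) mt - tt - dwell else NA_real_
  out <- data.frame(
    movement_time = mt, translation_time = tt, dial_in_time = di,
    path_efficiency = pe, success = success,
    index_of_difficulty = if (D > 0 && trial$effective_radius > 0)
      index_of_difficulty(D, trial$effective_radius) else NA_real_)
  class(out) <- c("trial_metrics", "data.frame")
  out
}

#' Fitts index of difficulty
#'
#' Shannon formulation with target width taken as twice the effective
#' radius: \code{ID = log2(distance / (2 effective_radius) + 1)} bits.
#'
#' @param distance start-to-target distance (> 0).
#' @param effective_radius target radius + cursor radius (> 0).
#' @return index of difficulty in bits.
#' @export
index_of_difficulty <- function(distance, effective_radius) {
  if (any(distance <= 0) || any(effective_radius <= 0))
    stop("distance and effective_radius must be > 0", call. = FALSE)
  log2(distance / (2 * effective_radius) + 1)
}

#' Achieved bit rate
#'
#' Conservative lower bound on communication throughput for an N-choice
#' selection interface:
#' \code{B = log2(N - 1) max(S_c - S_w, 0) / T} bits/s, where \code{S_c} and
#' \code{S_w} are the numbers of correct and wrong selections and \code{T}
#' the elapsed time.
#'
#' @param n_targets number of selectable targets N (>= 2).
#' @param n_correct correct selections.
#' @param n_wrong wrong selections.
#' @param elapsed_s elapsed time in seconds (> 0).
#' @return bits per second.
#' @export
achieved_bit_rate <- function(n_targets, n_correct, n_wrong, elapsed_s) {
  if (n_targets < 2) stop("n_targets must be >= 2", call. = FALSE)
  if (elapsed_s <= 0) stop("elapsed_s must be > 0", call. = FALSE)
  log2(n_targets - 1) * max(n_correct - n_wrong, 0) / elapsed_s
}

#' Metrics for every trial in a session
#'
#' @param session a \code{\link{simulate_condition}} result or a plain list
#'   of trial records.
#' @return data.frame with one row per trial.
#' @export
session_metrics <- function(session) {
  trials <- if (inherits(session, "simulated_session")) session$trials else session
  do.call(rbind, lapply(trials, trial_metrics))
}

#' Condition-level summary with bootstrap confidence intervals
#'
#' Mean, standard error, and percentile-bootstrap 95\% confidence interval
#' for each trial-level metric, plus the success rate. Trials are resampled
#' with replacement; failed trials are excluded from the time and path means
#' but counted in the success rate.
#'
#' @param trials a list of trial records, a \code{simulated_session}, or a
#'   data.frame of trial metrics.
#' @param n_boot number of bootstrap resamples.
#' @param seed RNG seed for the resampling.
#' @return an object of class \code{"condition_summary"}: data.frame with
#'   columns metric, mean, se, ci_lo, ci_hi plus attributes \code{n_trials}
#'   and \code{success_rate}.
#' @export
summarize_condition <- function(trials, n_boot = 1000L, seed = 1L) {
  m <- if (is.data.frame(trials)) trials else session_metrics(trials)
  stopifnot(nrow(m) >= 1L)
  metrics <- c("movement_time", "translation_time", "dial_in_time",
               "path_efficiency")
  set.seed(seed)
  idx <- matrix(sample.int(nrow(m), nrow(m) * n_boot, replace = TRUE),
                nrow = n_boot)
  out <- lapply(metrics, function(mm) {
    x <- m[[mm]]
    mu <- mean(x, na.rm = TRUE)
    bs <- apply(idx, 1L, function(i) mean(x[i], na.rm = TRUE))
    ci <- stats::quantile(bs, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    data.frame(metric = mm, mean = mu, se = stats::sd(bs, na.rm = TRUE),
               ci_lo = min(ci[1], mu), ci_hi = max(ci[2], mu))
  })
  out <- do.call(rbind, out)
  sr <- mean(m$success)
  bs_sr <- apply(idx, 1L, function(i) mean(m$success[i]))
  out <- rbind(out, data.frame(metric = "success_rate", mean = sr,
                               se = stats::sd(bs_sr),
                               ci_lo = min(stats::quantile(bs_sr, 0.025), sr),
                               ci_hi = max(stats::quantile(bs_sr, 0.975), sr)))
  attr(out, "n_trials") <- nrow(m)
  attr(out, "success_rate") <- sr
  class(out) <- c("condition_summary", "data.frame")
  out
}

#' Prediction-vs-observation evaluation statistics
#'
#' Fraction of variance accounted for,
#' \code{FVAF = 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)}; mean
#' absolute error; and an ordinary least-squares regression of the
#' predictions on the observations with a two-sided test on the slope. FVAF
#' is at most 1 and can be negative when predictions are worse than the
#' observed mean.
#'
#' @param observed numeric vector of observed condition means.
#' @param predicted numeric vector of predicted condition means (same
#'   length, >= 3).
#' @return list with \code{fvaf}, \code{mae}, \code{slope},
#'   \code{intercept}, \code{slope_p}.
#' @export
evaluate_predictions <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 3L)
  sst <- sum((observed - mean(observed))^2)
  if (sst <= 0)
    stop("observed values have zero variance: FVAF undefined", call. = FALSE)
  fit <- stats::lm(predicted ~ observed)
  cf <- summary(fit)$coefficients
  list(fvaf = 1 - sum((observed - predicted)^2) / sst,
       mae = mean(abs(observed - predicted)),
       slope = unname(cf[2, 1]), intercept = unname(cf[1, 1]),
       slope_p = unname(cf[2, 4]))
}
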