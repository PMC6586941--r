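dim_suffix <- function(d) {
  if (d <= 3L) c("x", "y", "z")[seq_len(d)] else paste0("d", seq_len(d))
}

session_columns <- function(d) {
  sfx <- dim_suffix(d)
  c("time_s", "block_id", "trial_id",
    paste0("target_", sfx), "target_radius",
    paste0("cursor_", sfx), paste0("vel_", sfx), paste0("u_", sfx))
}

#' Convert a simulated session to the tabular session format
#'
#' One row per time step: sample t carries the cursor state the decoder
#' output \code{u_t} acted from (each trial's final state is implied by the
#' following step and is not stored).
#'
#' @param session a \code{\link{simulate_condition}} result.
#' @param block_id block identifier for all rows.
#' @return a \code{"bci_session"} data.frame with the session configuration
#'   (per-block decoder and task settings) in \code{attr(, "config")}.
#' @export
as_session_frame <- function(session, block_id = 1L) {
  fd <- as_fit_data(session)
  d <- fd$d
  sfx <- dim_suffix(d)
  radius <- unlist(lapply(session$trials, function(tr)
    rep(tr$radius, nrow(tr$u))))
  trial_id <- unlist(lapply(seq_along(session$trials), function(k)
    rep(k, nrow(session$trials[[k]]$u))))
  dt <- fd$dt
  tt <- stats::ave(seq_along(trial_id), trial_id, FUN = seq_along)
  df <- data.frame(time_s = (tt - 1L) * dt, block_id = block_id,
                   trial_id = trial_id)
  for (i in seq_len(d)) df[[paste0("target_", sfx[i])]] <- fd$targ[, i]
  df$target_radius <- radius
  for (i in seq_len(d)) df[[paste0("cursor_", sfx[i])]] <- fd$pos[, i]
  for (i in seq_len(d)) df[[paste0("vel_", sfx[i])]] <- fd$vel[, i]
  for (i in seq_len(d)) df[[paste0("u_", sfx[i])]] <- fd$u[, i]
  cfg <- list(dims = d,
              blocks = list(list(block_id = block_id,
                                 decoder = serialize_decoder(session$decoder),
                                 task = serialize_task(session$task))))
  structure(df, config = cfg, class = c("bci_session", "data.frame"))
}

serialize_decoder <- function(dec) {
  out <- list(gain_beta = dec$gain_beta, smoothing_alpha = dec$smoothing_alpha,
              dt = dec$dt, dims = dec$dims,
              transform = list(variant = dec$transform$variant))
  if (dec$transform$variant == "exponent")
    out$transform$exponent_p <- dec$transform$exponent_p
  if (dec$transform$variant == "piecewise")
    out$transform$breakpoints <- apply(dec$transform$breakpoints, 1, as.list)
  out
}

deserialize_decoder <- function(x) {
  tr <- switch(x$transform$variant,
               identity = speed_transform(),
               exponent = speed_transform("exponent", x$transform$exponent_p),
               piecewise = speed_transform("piecewise", breakpoints =
                 do.call(rbind, lapply(x$transform$breakpoints, unlist))))
  decoder_params(x$gain_beta, x$smoothing_alpha, x$dt, x$dims, tr)
}

serialize_task <- function(task) {
  list(cursor_radius = task$cursor_radius, dwell_s = task$dwell_s,
       max_trial_s = task$max_trial_s, inter_trial_s = task$inter_trial_s)
}

#' Serialize / restore a user model
#'
#' Structured-list (YAML-ready) representation of a
#' \code{\link{user_model}}; \code{deserialize_user_model} inverts it.
#'
#' @param user a \code{\link{user_model}}.
#' @return a plain list.
#' @export
serialize_user_model <- function(user) {
  out <- list(delay_tau = user$delay_tau,
              f_targ = list(knots = user$policy$f_targ$knots,
                            values = user$policy$f_targ$values),
              f_vel = list(knots = user$policy$f_vel$knots,
                           values = user$policy$f_vel$values))
  if (!is.null(user$noise)) {
    n <- user$noise
    out$noise <- list(n_lags = n$n_lags,
                      ar_coeffs = lapply(n$ar_coeffs, function(m)
                        as.list(as.data.frame(m))),
                      innovation_cov = as.list(as.data.frame(n$innovation_cov)))
    if (!is.null(n$sdn_fn))
      out$noise$sdn = list(knots = n$sdn_fn$knots, values = n$sdn_fn$values)
  }
  out
}

#' @rdname serialize_user_model
#' @param x a list produced by \code{serialize_user_model} (e.g. read back
#'   from YAML).
#' @export
deserialize_user_model <- function(x) {
  pol <- control_policy(
    piecewise_linear(unlist(x$f_targ$knots), unlist(x$f_targ$values)),
    piecewise_linear(unlist(x$f_vel$knots), unlist(x$f_vel$values)))
  noise <- NULL
  if (!is.null(x$noise)) {
    Sig <- do.call(cbind, lapply(x$noise$innovation_cov, unlist))
    ar <- lapply(x$noise$ar_coeffs, function(m)
      do.call(cbind, lapply(m, unlist)))
    sdn <- if (!is.null(x$noise$sdn))
      piecewise_linear(unlist(x$noise$sdn$knots), unlist(x$noise$sdn$values))
    noise <- noise_model(x$noise$n_lags, ar, Sig, sdn)
  }
  user_model(pol, noise, x$delay_tau)
}

sidecar_path <- function(path) paste0(sub("\\.[^./]*$", "", path), ".yaml")

#' Write a session to delimited text plus a YAML sidecar
#'
#' The table is tab-separated with a header, numbers at 12 significant
#' digits; the sidecar (same path with a .yaml extension) carries the
#' per-block decoder and task settings and, for synthetic sessions, the
#' ground-truth user model.
#'
#' @param session a \code{"bci_session"} frame (see
#'   \code{\link{as_session_frame}}) or a \code{\link{simulate_condition}}
#'   result.
#' @param path output file path for the table.
#' @return \code{path}, invisibly.
#' @export
write_session <- function(session, path) {
  if (inherits(session, "simulated_session"))
    session <- as_session_frame(session)
  stopifnot(inherits(session, "bci_session"))
  cfg <- attr(session, "config")
  df <- as.data.frame(session)
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  for (j in which(num)) out[[j]] <- formatC(df[[j]], digits = 12,
                                            format = "g")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  yaml::write_yaml(cfg, sidecar_path(path), precision = 12)
  invisible(path)
}

#' Read and validate a session file
#'
#' Reads the tab-separated session table and its YAML sidecar, checking the
#' schema: required columns, strictly increasing time within each trial,
#' constant time step within each block, finite values, nonnegative radii,
#' and dimensionality consistent with the sidecar. A missing velocity
#' column triple is reconstructed by finite differences of the cursor
#' position (with a notice); stored velocities are used as-is when present.
#'
#' @param path session table path.
#' @return a \code{"bci_session"} data.frame with \code{attr(, "config")}.
#' @export
read_session <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  scp <- sidecar_path(path)
  cfg <- if (file.exists(scp)) yaml::read_yaml(scp) else NULL
  d <- if (!is.null(cfg$dims)) as.integer(cfg$dims) else
    sum(grepl("^cursor_", names(df)))
  sfx <- dim_suffix(d)
  need <- setdiff(session_columns(d), paste0("vel_", sfx))
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("session file missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  ccols <- paste0("cursor_", sfx)
  if (!all(paste0("vel_", sfx) %in% names(df))) {
    message("velocity columns absent; reconstructing by finite differences")
    for (i in seq_len(d)) df[[paste0("vel_", sfx[i])]] <- 0
    for (tid in unique(df$trial_id)) {
      rows <- which(df$trial_id == tid)
      if (length(rows) < 2L) next
      dtv <- diff(df$time_s[rows])
      for (i in seq_len(d)) {
        p <- df[[ccols[i]]][rows]
        df[[paste0("vel_", sfx[i])]][rows] <- c(0, diff(p) / dtv)
      }
    }
  }
  numcols <- setdiff(session_columns(d), c("block_id", "trial_id"))
  for (cc in numcols) if (any(!is.finite(df[[cc]])))
    stop(sprintf("non-finite value in column '%s' (first at row %d)",
                 cc, which(!is.finite(df[[cc]]))[1]), call. = FALSE)
  if (any(df$target_radius < 0))
    stop(sprintf("negative target_radius at row %d",
                 which(df$target_radius < 0)[1]), call. = FALSE)
  for (key in split(seq_len(nrow(df)),
                    paste(df$block_id, df$trial_id, sep = "/"))) {
    dtv <- diff(df$time_s[key])
    if (length(dtv) && any(dtv <= 0))
      stop(sprintf("time not strictly increasing within trial at row %d",
                   key[which(dtv <= 0)[1] + 1L]), call. = FALSE)
  }
  for (rows in split(seq_len(nrow(df)), df$block_id)) {
    tr1 <- df$trial_id[rows[1]]
    dtv <- diff(df$time_s[rows[df$trial_id[rows] == tr1]])
    if (length(dtv) >= 2L && diff(range(dtv)) > 1e-9)
      stop("time step not constant within block", call. = FALSE)
  }
  structure(df, config = cfg, class = c("bci_session", "data.frame"))
}

#' @export
as_fit_data.bci_session <- function(session, block = NULL, ...) {
  cfg <- attr(session, "config")
  df <- as.data.frame(session)
  if (!is.null(block)) df <- df[df$block_id == block, , drop = FALSE]
  if (length(unique(df$block_id)) > 1L)
    stop("session contains multiple blocks; pass 'block' to select one",
         call. = FALSE)
  d <- if (!is.null(cfg$dims)) as.integer(cfg$dims) else
    sum(grepl("^cursor_", names(df)))
  sfx <- dim_suffix(d)
  grab <- function(prefix) as.matrix(df[paste0(prefix, sfx)])
  newtrial <- c(TRUE, df$trial_id[-1] != df$trial_id[-nrow(df)])
  starts0 <- (which(newtrial) - 1L)[cumsum(newtrial)]  # 0-based trial starts
  dt <- if (nrow(df) >= 2L) stats::median(diff(df$time_s[df$trial_id ==
                                                           df$trial_id[1]])) else 0.02
  bid <- df$block_id[1]
  deco <- NULL
  task <- NULL
  if (!is.null(cfg$blocks)) {
    for (b in cfg$blocks) if (identical(as.character(b$block_id),
                                        as.character(bid))) {
      deco <- deserialize_decoder(b$decoder)
      if (!is.null(b$task)) task <- b$task
    }
  }
  list(pos = grab("cursor_"), vel = grab("vel_"), u = grab("u_"),
       targ = grab("target_"), trial_start = starts0, dt = dt, d = d,
       decoder = deco, task = task)
}

#' @export
resample_trials.bci_session <- function(session, idx) {
  df <- as.data.frame(session)
  ids <- unique(df$trial_id)
  parts <- lapply(seq_along(idx), function(k) {
    part <- df[df$trial_id == ids[idx[k]], , drop = FALSE]
    part$trial_id <- k
    part
  })
  structure(do.call(rbind, parts), config = attr(session, "config"),
            class = c("bci_session", "data.frame"))
}

#' Generate a synthetic closed-loop session file
#'
#' Simulates a ground-truth user under the given decoder and task until the
#' requested duration is reached (the final trial is truncated so the table
#' has exactly \code{duration_s / dt} rows) and returns the tabular session
#' with the ground-truth model embedded in the configuration for recovery
#' tests.
#'
#' @param ground_truth a \code{\link{user_model}}.
#' @param decoder a \code{\link{decoder_params}}.
#' @param task a \code{\link{task_spec}}.
#' @param duration_s session duration in seconds.
#' @param seed integer seed.
#' @return a \code{"bci_session"} data.frame (write it with
#'   \code{\link{write_session}}).
#' @export
make_synthetic_session <- function(ground_truth, decoder, task, duration_s,
                                   seed = 1L) {
  n_rows <- round(duration_s / decoder$dt)
  seeds <- trial_seeds(seed, 10000L)
  d <- decoder$dims
  start_pos <- numeric(d)
  trials <- list()
  got <- 0L
  k <- 0L
  while (got < n_rows) {
    k <- k + 1L
    set.seed(seeds[k])
    tg <- task$target_generator(k, start_pos)
    tr <- simulate_trial(ground_truth, decoder, task,
                         start = list(position = start_pos,
                                      velocity = numeric(d)),
                         target = tg$target, radius = tg$radius)
    trials[[k]] <- tr
    got <- got + nrow(tr$u)
    start_pos <- tg$target
  }
  ses <- structure(list(trials = trials, user = ground_truth,
                        decoder = decoder, task = task, seed = seed),
                   class = "simulated_session")
  df <- as_session_frame(ses)
  if (nrow(df) > n_rows) {
    cfg <- attr(df, "config")
    df <- structure(df[seq_len(n_rows), , drop = FALSE], config = cfg,
                    class = c("bci_session", "data.frame"))
  }
  cfg <- attr(df, "config")
  cfg$ground_truth <- serialize_user_model(ground_truth)
  cfg$seed <- seed
  attr(df, "config") <- cfg
  df
}
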