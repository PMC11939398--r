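.traj_colnames <- c("time_s", .state_names,
                    "p_lv", "p_rv", "p_la", "p_ra",
                    "p_ao", "p_svc", "p_pa", "p_pvc",
                    "q_mitral", "q_aortic", "q_tricuspid", "q_pulmonary",
                    "q_systemic", "e_norm")

#' Simulate the circuit over a fixed horizon
#'
#' Integrates the circuit with a fixed-step classical RK4 scheme (forward
#' Euler is available for step-refinement cross-checks) and records every
#' `record_every`-th step: all state volumes, node pressures, valve and
#' loop flows and the normalized elastance.  An optional event schedule
#' mutates parameters at stated times (e.g. stepping the venous-return
#' clamp or changing pump speed); each event is applied at the first step
#' boundary at or after its time.
#'
#' @param params an [mcl_params()] object.
#' @param state named initial state; defaults to `params$initial_state`.
#' @param duration simulated seconds (>= 0).
#' @param dt integration step in seconds (default 0.25 ms; must be <= 1 ms).
#' @param events optional list of events, each a list with `time` (s) and
#'   `set`, a named list of dotted parameter paths to new values, e.g.
#'   `list(time = 5, set = list("vascular.clamp_factor" = 1000))`.
#' @param t0 start time in seconds (sets the elastance phase).
#' @param record_every record every n-th step (default 1).
#' @param method `"rk4"` or `"euler"`.
#' @return an object of class `mcl_sim`: the trajectory matrix with one row
#'   per recorded sample, with attributes `params` (as at the end of the
#'   run), `dt` and `final_state`.
#' @export
mcl_simulate <- function(params, state = NULL, duration, dt = 2.5e-4,
                         events = NULL, t0 = 0, record_every = 1L,
                         method = c("rk4", "euler")) {
  method <- match.arg(method)
  stopifnot(dt > 0, dt <= 1e-3, duration >= 0)
  validate_params(params)
  if (is.null(state)) state <- params$initial_state
  state <- state[.state_names]
  if (duration == 0) {
    aux <- circuit_rhs(t0, state, params)$aux
    traj <- matrix(c(t0, state, aux[1:8], aux[c("q_mitral", "q_aortic",
                     "q_tricuspid", "q_pulmonary", "q_systemic")],
                     normalized_elastance(t0, 60 / params$heart_rate,
                                          params$waveform)),
                   nrow = 1, dimnames = list(NULL, .traj_colnames))
    return(.new_sim(traj, params, dt, state))
  }
  ev_times <- if (length(events)) vapply(events, `[[`, 0, "time") else numeric()
  if (length(events)) {
    o <- order(ev_times)
    events <- events[o]; ev_times <- ev_times[o]
  }
  # segment boundaries at step-aligned event times
  bounds <- unique(c(0, pmin(duration, ceiling(ev_times / dt) * dt), duration))
  bounds <- bounds[bounds <= duration]
  segs <- cbind(head(bounds, -1), tail(bounds, -1))
  pieces <- list()
  ev_idx <- 1
  for (i in seq_len(nrow(segs))) {
    if (i > 1 || segs[i, 1] > 0) {
      while (ev_idx <= length(events) &&
             ceiling(ev_times[ev_idx] / dt) * dt <= segs[i, 1] + dt / 2) {
        for (path in names(events[[ev_idx]]$set))
          params <- set_param(params, path, events[[ev_idx]]$set[[path]])
        ev_idx <- ev_idx + 1
      }
      validate_params(params)
      if (!isTRUE(params$ecmo$enabled)) state[["q_ecmo"]] <- 0
    }
    seg_dur <- segs[i, 2] - segs[i, 1]
    if (seg_dur <= dt / 2) next
    res <- .mcl_core_simulate(.pack_params(params), unname(state),
                              t0 + segs[i, 1], seg_dur, dt,
                              if (method == "rk4") 0L else 1L,
                              as.integer(record_every),
                              params$total_fluid_volume)
    .check_core_status(res)
    colnames(res$traj) <- .traj_colnames
    pieces[[length(pieces) + 1]] <-
      if (length(pieces)) res$traj[-1, , drop = FALSE] else res$traj
    state <- stats::setNames(res$state, .state_names)
  }
  traj <- do.call(rbind, pieces)
  .new_sim(traj, params, dt, state)
}

.new_sim <- function(traj, params, dt, final_state) {
  structure(traj, class = c("mcl_sim", "matrix", "array"),
            params = params, dt = dt, final_state = final_state)
}

.check_core_status <- function(res) {
  if (res$status == 0) return(invisible())
  msg <- switch(as.character(res$status),
    "1" = "integration failure: windkessel chamber flooded",
    "2" = sprintf("integration failure: non-finite value in %s", res$message),
    "3" = sprintf("integration instability: runaway volume in %s", res$message),
    "unknown integration failure")
  stop(msg, call. = FALSE)
}

#' Run the circuit to periodic steady state
#'
#' Integrates beat by beat (applying the Frank-Starling per-beat update in
#' the BVFS configuration) until every beat-mean pressure (mAoP, LAP, RAP,
#' mPAP) changes by less than `tolerance` between consecutive beats for
#' three consecutive beats, or `max_beats` is reached.  Returns the
#' trailing ten beats, their per-beat metrics, and the steady summary.
#'
#' @param params an [mcl_params()] object.
#' @param state optional starting state (defaults to
#'   `params$initial_state`).
#' @param max_beats maximum number of beats (>= 10).
#' @param tolerance convergence tolerance on beat-mean pressures in mmHg.
#' @param dt integration step in seconds.
#' @return an object of class `mcl_steady`: list with `summary` (a
#'   [steady_summary()] over the trailing beats), `beats` (per-beat metric
#'   data frame for the whole run), `trailing` (an `mcl_sim` of the last
#'   ten beats), `state` (final state, at a beat boundary), `params` (with
#'   the controller-adapted `e_max` written back), `converged`, `n_beats`
#'   and the controller trace `fs_trace`.
#' @export
find_steady_state <- function(params, state = NULL, max_beats = 120,
                              tolerance = 0.1, dt = 2.5e-4) {
  stopifnot(max_beats >= 10)
  validate_params(params)
  if (is.null(state)) state <- params$initial_state
  state <- state[.state_names]
  if (!isTRUE(params$ecmo$enabled)) state[["q_ecmo"]] <- 0
  period <- 60 / params$heart_rate
  steps <- round(period / dt)
  pvec <- .pack_params(params)
  fs_on <- isTRUE(params$fs$enabled)
  prev_means <- NULL
  ok_streak <- 0
  converged <- FALSE
  beats <- vector("list", max_beats)
  ring <- vector("list", 10)
  fs_trace <- if (fs_on) vector("list", max_beats) else NULL
  n <- 0
  for (b in seq_len(max_beats)) {
    res <- .mcl_core_simulate(pvec, unname(state), (b - 1) * period,
                              steps * dt, dt, 0L, 1L,
                              params$total_fluid_volume)
    .check_core_status(res)
    colnames(res$traj) <- .traj_colnames
    state <- stats::setNames(res$state, .state_names)
    m <- beat_metrics(res$traj, params)
    n <- b
    beats[[b]] <- m
    ring[[(b - 1) %% 10 + 1]] <- res$traj
    if (fs_on) {
      upd <- fs_beat_update(
        list(current_e_max_lv = params$ventricles$left$e_max,
             current_e_max_rv = params$ventricles$right$e_max,
             e_min_lv = params$ventricles$left$e_min,
             e_min_rv = params$ventricles$right$e_min),
        params$fs, m)
      fs_trace[[b]] <- data.frame(
        beat = b, e_max_lv = upd$current_e_max_lv,
        e_max_rv = upd$current_e_max_rv,
        target_lvesp = upd$last_target_lvesp,
        target_rvesp = upd$last_target_rvesp,
        lvesp = m$lvesp, rvesp = m$rvesp)
      params$ventricles$left$e_max <- upd$current_e_max_lv
      params$ventricles$right$e_max <- upd$current_e_max_rv
      pvec <- .pack_params(params)
    }
    means <- c(m$maop, m$lap, m$rap, m$mpap)
    if (fs_on) {
      # a true steady state requires the controller to have settled too
      means <- c(means,
                 10 * params$ventricles$left$e_max,
                 10 * params$ventricles$right$e_max)
    }
    if (!is.null(prev_means)) {
      ok_streak <- if (max(abs(means - prev_means)) < tolerance)
        ok_streak + 1 else 0
      if (ok_streak >= 3 && b >= 10) { converged <- TRUE; break }
    }
    prev_means <- means
  }
  beats_df <- do.call(rbind, lapply(beats[seq_len(n)], as.data.frame))
  beats_df$beat <- seq_len(n)
  # assemble trailing beats in chronological order
  k <- min(n, 10)
  idx <- ((n - k + 1):n - 1) %% 10 + 1
  trail <- ring[idx]
  trail <- do.call(rbind, c(trail[1], lapply(trail[-1],
                                             function(x) x[-1, , drop = FALSE])))
  trailing <- .new_sim(trail, params, dt, state)
  tail_metrics <- beats[(n - k + 1):n]
  structure(list(
    summary = steady_summary(tail_metrics),
    beats = beats_df,
    trailing = trailing,
    state = state,
    params = params,
    converged = converged,
    n_beats = n,
    fs_trace = if (fs_on) do.call(rbind, fs_trace[seq_len(n)]) else NULL
  ), class = "mcl_steady")
}

#' @export
print.mcl_sim <- function(x, ...) {
  cat(sprintf("Mock-loop simulation: %d samples over %.2f s (dt = %g ms)\n",
              nrow(x), x[nrow(x), "time_s"] - x[1, "time_s"],
              attr(x, "dt") * 1000))
  cat(sprintf("  configuration %s; ECMO %s\n",
              attr(x, "params")$configuration,
              if (isTRUE(attr(x, "params")$ecmo$enabled)) "on" else "off"))
  invisible(x)
}

#' @export
as.data.frame.mcl_sim <- function(x, ...) {
  as.data.frame(unclass(x)[, , drop = FALSE], ...)
}

#' @export
plot.mcl_sim <- function(x, what = c("p_lv", "p_ao", "p_la", "p_ra"),
                         last_beats = NULL, ...) {
  tt <- x[, "time_s"]
  if (!is.null(last_beats)) {
    period <- 60 / attr(x, "params")$heart_rate
    keep <- tt >= max(tt) - last_beats * period
    x <- x[keep, , drop = FALSE]; tt <- tt[keep]
  }
  graphics::matplot(tt, x[, what, drop = FALSE], type = "l", lty = 1,
                    xlab = "time (s)", ylab = "pressure (mmHg)", ...)
  graphics::legend("topright", legend = what, col = seq_along(what),
                   lty = 1, bty = "n")
  invisible(x)
}

#' @export
print.mcl_steady <- function(x, ...) {
  cat(sprintf("Steady state after %d beats (%s)\n", x$n_beats,
              if (x$converged) "converged" else "NOT converged"))
  print(x$summary)
  invisible(x)
}

#' @export
summary.mcl_steady <- function(object, ...) object$summary
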