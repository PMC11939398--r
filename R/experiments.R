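.new_experiment <- function(name, configuration, preset, swept, table,
                            stats = NULL, extra = list()) {
  structure(c(list(experiment_name = name, configuration = configuration,
                   preset = preset, swept_variable = swept,
                   points = table, stats = stats), extra),
            class = "mcl_experiment")
}

#' @export
print.mcl_experiment <- function(x, ...) {
  cat(sprintf("Experiment `%s` (%s configuration, preset %s)\n",
              x$experiment_name, x$configuration, x$preset))
  if (!is.null(x$points)) print(x$points, digits = 4)
  if (!is.null(x$stats)) { cat("--\n"); print(x$stats) }
  invisible(x)
}

#' @export
plot.mcl_experiment <- function(x, y_var = "lap", ...) {
  df <- x$points
  xv <- x$swept_variable
  if (is.null(df) || !xv %in% names(df))
    stop("nothing to plot for this experiment", call. = FALSE)
  graphics::plot(df[[xv]], df[[y_var]], type = "b", pch = 16,
                 xlab = xv, ylab = paste(y_var), ...)
  invisible(x)
}

# Shared helper: steady state for a parameter set with a warm start carried
# between operating points of a sweep.
.steady_point <- function(params, warm = NULL, max_beats = 160,
                          tolerance = 0.04, dt = 2.5e-4) {
  st <- if (is.null(warm)) NULL else warm$state
  if (!is.null(warm)) {
    # carry the controller-adapted contractility over as well
    params$ventricles$left$e_max <- warm$params$ventricles$left$e_max
    params$ventricles$right$e_max <- warm$params$ventricles$right$e_max
  }
  find_steady_state(params, state = st, max_beats = max_beats,
                    tolerance = tolerance, dt = dt)
}

#' Right-atrial inflow clamp test (ventricular interdependence)
#'
#' Runs the loop to steady state, steps the venous-return clamp to
#' `clamp_factor = 1000`, and measures the change in mean RAP and LAP over
#' a 10 s averaging window after a 2 s blanking period, relative to the
#' pre-clamp steady means.  The transmission ratio `dLAP/dRAP` quantifies
#' direct ventricular interaction: near zero for separate ventricles,
#' substantial when septal coupling is active.  The clamp is then released
#' and return to baseline verified.
#'
#' @param params preset parameters (ECMO and the Frank-Starling controller
#'   are disabled for this test).
#' @param configuration `"SV"` or `"BV"`.
#' @param clamp_factor stepped clamp multiplier (default 1000).
#' @param blanking,window post-clamp blanking and averaging window in
#'   seconds.
#' @param recovery_duration seconds simulated after release when checking
#'   return to baseline.
#' @return an `mcl_experiment` with `d_rap`, `d_lap`, `ratio`,
#'   `early_d_lap`/`early_d_rap` (first 3 s means), `recovered` and the
#'   full event log.
#' @export
run_clamp_test <- function(params, configuration = c("BV", "SV"),
                           clamp_factor = 1000, blanking = 2, window = 10,
                           recovery_duration = 60) {
  configuration <- match.arg(configuration)
  preset <- attr(params, "preset_name") %||% "custom"
  params <- set_configuration(params, configuration)
  params <- configure_ecmo(params, enabled = FALSE)
  params$vascular$clamp_factor <- 1
  base <- find_steady_state(params)
  if (!base$converged)
    stop("pre-clamp steady state did not converge", call. = FALSE)
  lap0 <- base$summary$mean[["lap"]]; rap0 <- base$summary$mean[["rap"]]

  clamped <- params
  clamped$vascular$clamp_factor <- clamp_factor
  sim <- mcl_simulate(clamped, state = base$state,
                      duration = blanking + window)
  tt <- sim[, "time_s"]
  win <- tt >= blanking
  lap1 <- .trapz_mean(tt[win], sim[win, "p_la"])
  rap1 <- .trapz_mean(tt[win], sim[win, "p_ra"])
  early <- tt <= 3
  early_d_lap <- .trapz_mean(tt[early], sim[early, "p_la"]) - lap0
  early_d_rap <- .trapz_mean(tt[early], sim[early, "p_ra"]) - rap0

  d_lap <- lap1 - lap0; d_rap <- rap1 - rap0
  ratio <- d_lap / d_rap

  rec <- mcl_simulate(params, state = attr(sim, "final_state"),
                      duration = recovery_duration)
  period <- 60 / params$heart_rate
  rt <- rec[, "time_s"]
  last_beat <- rt >= max(rt) - period
  rec_lap <- .trapz_mean(rt[last_beat], rec[last_beat, "p_la"])
  rec_rap <- .trapz_mean(rt[last_beat], rec[last_beat, "p_ra"])
  recovered <- abs(rec_lap - lap0) < 1 && abs(rec_rap - rap0) < 1

  log <- data.frame(
    time_s = c(0, blanking, blanking + window, blanking + window),
    event = c("clamp applied", "blanking over", "window over",
              "clamp released"))
  .new_experiment(
    "clamp_test", configuration, preset, "clamp_factor",
    data.frame(clamp_factor = c(1, clamp_factor),
               lap = c(lap0, lap1), rap = c(rap0, rap1)),
    extra = list(d_lap = d_lap, d_rap = d_rap, ratio = ratio,
                 early_d_lap = early_d_lap, early_d_rap = early_d_rap,
                 recovered = recovered, baseline = base$summary,
                 event_log = log))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Preload-reduction test of the Frank-Starling response
#'
#' Reproduces the right-atrial inflow clamp maneuver used to demonstrate
#' the Frank-Starling mechanism: from a converged steady state the
#' venous-return clamp is closed and the per-beat RAP, LVESP and LV
#' outflow are tracked while the controller (if active) responds.  Without
#' the controller (BV) the intrinsic response is outflow-dominant: flow
#' collapses while venous back-pressure keeps end-systolic pressure nearly
#' unchanged.  With the controller (BVFS) the falling left atrial pressure
#' lowers the ESP setpoint, so LVESP falls together with outflow.
#'
#' @param params preset parameters (ECMO disabled for this test).
#' @param configuration `"BV"` or `"BVFS"`.
#' @param clamp_factor clamp multiplier applied at the maneuver start.
#' @param n_beats clamped beats simulated.
#' @param tail_beats trailing beats averaged for the post-clamp values.
#' @return an `mcl_experiment`; `points` holds the per-beat trace and
#'   `rel_esp_drop` / `rel_outflow_drop` the relative drops of LVESP and
#'   LV outflow versus baseline.
#' @export
run_fs_validation <- function(params, configuration = c("BV", "BVFS"),
                              clamp_factor = 1000, n_beats = 20,
                              tail_beats = 5) {
  configuration <- match.arg(configuration)
  preset <- attr(params, "preset_name") %||% "custom"
  params <- set_configuration(params, configuration)
  params <- configure_ecmo(params, enabled = FALSE)
  params$vascular$clamp_factor <- 1
  base <- find_steady_state(params)
  if (!base$converged)
    stop("pre-clamp steady state did not converge", call. = FALSE)
  clamped <- base$params
  clamped$vascular$clamp_factor <- clamp_factor
  # run the clamped transient beat by beat with the controller live
  trace <- find_steady_state(clamped, state = base$state,
                             max_beats = max(n_beats, 10), tolerance = 0)
  tab <- trace$beats[, c("beat", "lvesp", "lv_outflow", "lap", "rap",
                         "maop")]
  tail_idx <- tab$beat > n_beats - tail_beats
  esp0 <- base$summary$mean[["lvesp"]]
  out0 <- base$summary$mean[["lv_outflow"]]
  rel_esp <- (esp0 - mean(tab$lvesp[tail_idx])) / esp0
  rel_out <- (out0 - mean(tab$lv_outflow[tail_idx])) / out0
  .new_experiment(
    "fs_validation", configuration, preset, "beat", tab,
    extra = list(rel_esp_drop = rel_esp, rel_outflow_drop = rel_out,
                 baseline = base$summary, clamp_factor = clamp_factor))
}

.table1_bounds <- data.frame(
  state = c("normal", "lvf", "rvf", "bvf"),
  maop_min = c(60, 60, 60, 60),
  lap_max = c(15, NA, 15, NA),
  lap_min = c(NA, 25, NA, 25),
  rap_max = c(10, 10, NA, NA),
  rap_min = c(NA, NA, 25, 25),
  flow_min = c(4, NA, NA, NA),
  flow_max = c(NA, 3, 3, 3)
)

#' Reproduce a cardiac state and check its target bounds
#'
#' Runs a preset to steady state in the BVFS configuration with ECMO
#' disabled and checks the four target bounds for that state (mAoP, LAP,
#' RAP, systemic flow).
#'
#' @param preset preset name (`"normal"`, `"lvf"`, `"rvf"`, `"bvf"`) or an
#'   [mcl_params()] object carrying a `preset_name` attribute.
#' @return an `mcl_experiment` whose `points` lists each bound, the
#'   achieved value and pass/fail, with the [steady_summary()] attached.
#' @export
run_cardiac_state <- function(preset) {
  params <- if (is.character(preset)) mcl_preset(preset) else preset
  name <- attr(params, "preset_name") %||% "custom"
  params <- set_configuration(params, "BVFS")
  params <- configure_ecmo(params, enabled = FALSE)
  st <- find_steady_state(params)
  m <- st$summary$mean
  b <- .table1_bounds[.table1_bounds$state == name, ]
  checks <- data.frame(metric = character(), bound = character(),
                       value = numeric(), pass = logical())
  add <- function(metric, cmp, lim, val) {
    if (is.na(lim)) return(invisible())
    checks <<- rbind(checks, data.frame(
      metric = metric, bound = paste(cmp, lim), value = val,
      pass = if (cmp == ">") val > lim else val < lim))
  }
  if (nrow(b)) {
    add("maop", ">", b$maop_min, m[["maop"]])
    add("lap", "<", b$lap_max, m[["lap"]])
    add("lap", ">", b$lap_min, m[["lap"]])
    add("rap", "<", b$rap_max, m[["rap"]])
    add("rap", ">", b$rap_min, m[["rap"]])
    add("flow", ">", b$flow_min, m[["systemic_flow"]])
    add("flow", "<", b$flow_max, m[["systemic_flow"]])
  }
  .new_experiment("cardiac_state", "BVFS", name, "none", checks,
                  extra = list(summary = st$summary,
                               converged = st$converged,
                               steady = st))
}

#' Trim the circuit to hold a target mean aortic pressure
#'
#' Adjusts a single actuator by bisection on its (monotone) map to steady
#' mAoP until the steady mean aortic pressure is within `tolerance` of the
#' target.  Two actuators are available, matching the two ways the bench
#' can move arterial pressure: `"svr"` scales the upper- and lower-body
#' resistances by a common factor (tubing clamps), and `"volume"` adds or
#' removes working fluid (syringe/reservoir).  Resistance trimming is the
#' natural hold for speed sweeps; with the Frank-Starling controller
#' active the loop defends its pressure setpoint against resistance
#' changes, so aortic-pressure sweeps actuate volume instead.
#'
#' @param params an [mcl_params()] object.
#' @param target_maop target mean aortic pressure in mmHg.
#' @param tolerance acceptance band in mmHg (default 0.5).
#' @param factor_bounds allowed SVR scale range relative to the preset
#'   (`"svr"` actuator).
#' @param volume_bounds allowed fluid change in mL (`"volume"` actuator).
#' @param max_iter bisection iteration cap.
#' @param warm optional warm-start `mcl_steady` from a neighbouring
#'   operating point.
#' @param actuator `"svr"` or `"volume"`.
#' @return list with `params` (trimmed), `achieved` mAoP, `factor` (SVR
#'   scale or fluid delta in mL), `steady` (the converged state at the
#'   returned setting) and `iterations`.
#' @export
hold_maop_trim <- function(params, target_maop, tolerance = 0.5,
                           factor_bounds = c(0.2, 5),
                           volume_bounds = c(-400, 600), max_iter = 25,
                           warm = NULL, actuator = c("svr", "volume")) {
  actuator <- match.arg(actuator)
  scale_svr <- function(p, f) {
    if (actuator == "volume") {
      p$initial_state[["v_la"]] <- p$initial_state[["v_la"]] + f
      p$total_fluid_volume <- sum(p$initial_state[1:8])
      return(p)
    }
    p$vascular$r_upper_body <- p$vascular$r_upper_body * f
    p$vascular$r_lower_body <- p$vascular$r_lower_body * f
    p
  }
  if (actuator == "volume") factor_bounds <- volume_bounds
  last <- warm
  last_f <- if (actuator == "volume") 0 else 1
  evals <- 0
  best <- NULL
  eval_f <- function(f) {
    p <- scale_svr(params, f)
    w <- last
    if (actuator == "volume" && !is.null(w)) {
      # the warm state carries the previous trim volume; inject the delta
      w$state[["v_la"]] <- w$state[["v_la"]] + (f - last_f)
      p$total_fluid_volume <- sum(w$state[1:8])
    }
    st <- .steady_point(p, w)
    last <<- st
    last_f <<- f
    evals <<- evals + 1
    a <- st$summary$mean[["maop"]]
    if (is.null(best) || abs(a - target_maop) < abs(best$a - target_maop))
      best <<- list(f = f, st = st, a = a)
    list(f = f, st = st, a = a)
  }
  neutral <- if (actuator == "volume") 0 else 1
  step_up <- function(f) if (actuator == "volume")
    min(f + 120, factor_bounds[2]) else min(f * 1.6, factor_bounds[2])
  step_dn <- function(f) if (actuator == "volume")
    max(f - 120, factor_bounds[1]) else max(f / 1.6, factor_bounds[1])

  r0 <- eval_f(neutral)
  lo <- hi <- NULL   # bracket: lo achieves below target, hi above
  if (abs(r0$a - target_maop) > tolerance) {
    # expand in the direction an increasing map suggests; if the response
    # moves away from the target, the map is locally inverted there and
    # the neutral point is kept as the best achievable
    dirs <- if (r0$a < target_maop) c(TRUE, FALSE) else c(FALSE, TRUE)
    for (going_up in dirs) {
      cur <- r0
      repeat {
        nxt_f <- if (going_up) step_up(cur$f) else step_dn(cur$f)
        if (nxt_f == cur$f || evals >= max_iter) break
        nxt <- eval_f(nxt_f)
        if ((nxt$a - target_maop) * (cur$a - target_maop) <= 0) {
          # sign change: bracket found regardless of local slope direction
          if (cur$a < target_maop) { lo <- cur; hi <- nxt }
          else { lo <- nxt; hi <- cur }
          break
        }
        if (abs(nxt$a - target_maop) > abs(cur$a - target_maop) + tolerance)
          break  # moving away: non-monotone response in this direction
        cur <- nxt
      }
      if (!is.null(lo) || abs(best$a - target_maop) <= tolerance) break
    }
    if (!is.null(lo)) {
      while (abs(best$a - target_maop) > tolerance && evals < max_iter) {
        mid_f <- if (actuator == "volume") (lo$f + hi$f) / 2
                 else sqrt(lo$f * hi$f)
        mid <- eval_f(mid_f)
        if (mid$a < target_maop) lo <- mid else hi <- mid
        r <- if (actuator == "svr") max(hi$f / lo$f, lo$f / hi$f)
             else abs(hi$f - lo$f)
        if ((actuator == "svr" && r < 1 + 1e-5) ||
            (actuator == "volume" && r < 0.5)) break
      }
    }
  }
  if (abs(best$a - target_maop) > tolerance)
    stop(sprintf(
      "infeasible target: mAoP %.1f mmHg unreachable (closest achieved %.1f mmHg)",
      target_maop, best$a), call. = FALSE)
  list(params = scale_svr(params, best$f),
       achieved = best$a,
       factor = best$f, steady = best$st, iterations = evals)
}

#' ECMO pump-speed sweep
#'
#' Sweeps pump speed across the supported range (14 evenly spaced points by
#' default, so the regression has (1, 12) degrees of freedom), optionally
#' re-trimming systemic resistance at each point to hold mAoP at its value
#' from the first operating point, and fits the LAP-on-speed regression.
#'
#' @param params preset parameters.
#' @param configuration `"SV"`, `"BV"` or `"BVFS"`.
#' @param speeds pump speeds in RPM.
#' @param hold_maop trim SVR to hold mAoP constant across the sweep.
#' @param maop_target optional explicit mAoP to hold (defaults to the
#'   steady mAoP at the first speed with the preset SVR).
#' @param return_site ECMO return site for the sweep.
#' @return an `mcl_experiment` with per-speed steady summaries and an
#'   attached `mcl_regression` of LAP on speed (when >= 3 points).
#' @export
run_speed_sweep <- function(params, configuration = c("BVFS", "BV", "SV"),
                            speeds = seq(1800, 4000, length.out = 14),
                            hold_maop = TRUE, maop_target = NULL,
                            return_site = "retrograde_femoral") {
  configuration <- match.arg(configuration)
  preset <- attr(params, "preset_name") %||% "custom"
  params <- set_configuration(params, configuration)
  params <- configure_ecmo(params, enabled = TRUE, speed = speeds[1],
                           return_site = return_site)
  rows <- list(); warm <- NULL
  target <- maop_target
  for (s in speeds) {
    p <- configure_ecmo(params, speed = s)
    row <- NULL
    if (hold_maop) {
      if (is.null(target)) {
        st0 <- .steady_point(p, warm)
        target <- st0$summary$mean[["maop"]]
        warm <- st0
      }
      tr <- tryCatch(hold_maop_trim(p, target, warm = warm),
                     error = function(e) e)
      if (inherits(tr, "error")) {
        rows[[length(rows) + 1]] <- data.frame(
          speed = s, lap = NA, rap = NA, maop = NA, mpap = NA,
          systemic_flow = NA, ecmo_flow = NA, svr_factor = NA,
          converged = FALSE, feasible = FALSE)
        next
      }
      warm <- tr$steady
      st <- tr$steady
      row <- data.frame(svr_factor = tr$factor)
    } else {
      st <- .steady_point(p, warm)
      warm <- st
      row <- data.frame(svr_factor = 1)
    }
    m <- st$summary$mean
    rows[[length(rows) + 1]] <- cbind(
      data.frame(speed = s, lap = m[["lap"]], rap = m[["rap"]],
                 maop = m[["maop"]], mpap = m[["mpap"]],
                 systemic_flow = m[["systemic_flow"]],
                 ecmo_flow = m[["ecmo_flow"]]),
      row, data.frame(converged = st$converged, feasible = TRUE))
  }
  tab <- do.call(rbind, rows)
  ok <- tab$feasible
  reg <- if (sum(ok) >= 3) linear_regression_f(tab$speed[ok], tab$lap[ok])
  else NULL
  .new_experiment("speed_sweep", configuration, preset, "speed", tab, reg,
                  extra = list(hold_maop = hold_maop,
                               maop_target = target))
}

#' Mean-aortic-pressure sweep at fixed pump speed
#'
#' Holds the ECMO pump at a fixed speed and steps the target mAoP through
#' `maop_targets` by SVR trimming, recording the steady LAP at every
#' achieved pressure, and fits the LAP-on-mAoP regression.  Infeasible
#' targets are flagged and excluded from the fit.
#'
#' @param params preset parameters.
#' @param configuration `"SV"`, `"BV"` or `"BVFS"`.
#' @param maop_targets target mean aortic pressures in mmHg.
#' @param speed fixed pump speed in RPM.
#' @param return_site ECMO return site.
#' @return an `mcl_experiment` with per-target summaries and an attached
#'   regression of LAP on achieved mAoP.
#' @export
run_maop_sweep <- function(params, configuration = c("BVFS", "BV", "SV"),
                           maop_targets = seq(55, 75, by = 5),
                           speed = 3000,
                           return_site = "retrograde_femoral") {
  configuration <- match.arg(configuration)
  preset <- attr(params, "preset_name") %||% "custom"
  if (!length(maop_targets))
    return(.new_experiment("maop_sweep", configuration, preset, "maop",
                           NULL))
  params <- set_configuration(params, configuration)
  params <- configure_ecmo(params, enabled = TRUE, speed = speed,
                           return_site = return_site)
  rows <- list(); warm <- NULL
  for (tg in maop_targets) {
    tr <- tryCatch(hold_maop_trim(params, tg, warm = warm,
                                  actuator = "volume"),
                   error = function(e) e)
    if (inherits(tr, "error")) {
      rows[[length(rows) + 1]] <- data.frame(
        target_maop = tg, maop = NA, lap = NA, rap = NA,
        systemic_flow = NA, ecmo_flow = NA, svr_factor = NA,
        converged = FALSE, feasible = FALSE)
      next
    }
    warm <- tr$steady
    m <- tr$steady$summary$mean
    rows[[length(rows) + 1]] <- data.frame(
      target_maop = tg, maop = m[["maop"]], lap = m[["lap"]],
      rap = m[["rap"]], systemic_flow = m[["systemic_flow"]],
      ecmo_flow = m[["ecmo_flow"]], svr_factor = tr$factor,
      converged = tr$steady$converged, feasible = TRUE)
  }
  tab <- do.call(rbind, rows)
  ok <- tab$feasible
  reg <- if (sum(ok) >= 3) linear_regression_f(tab$maop[ok], tab$lap[ok])
  else NULL
  .new_experiment("maop_sweep", configuration, preset, "maop", tab, reg,
                  extra = list(speed = speed))
}

#' Contractility-by-pump-speed grid
#'
#' Full grid of steady states over LV contractility scales and pump speeds
#' at fixed SVR (no trimming).  In SV/BV the scale multiplies the LV
#' end-systolic elastance; in BVFS it scales the Frank-Starling ESP
#' setpoint (slope and intercept together), the controller's contractility
#' handle.
#'
#' @param params preset parameters.
#' @param configuration `"SV"`, `"BV"` or `"BVFS"`.
#' @param e_max_scales contractility multipliers (1 = preset value).
#' @param speeds pump speeds in RPM.
#' @param return_site ECMO return site.
#' @return an `mcl_experiment` whose `points` grid holds LAP and mAoP per
#'   (scale, speed).
#' @export
run_contractility_grid <- function(params,
                                   configuration = c("BVFS", "BV", "SV"),
                                   e_max_scales = c(0.5, 0.75, 1),
                                   speeds = c(1800, 2600, 3400, 4000),
                                   return_site = "retrograde_femoral") {
  configuration <- match.arg(configuration)
  preset <- attr(params, "preset_name") %||% "custom"
  params <- set_configuration(params, configuration)
  params <- configure_ecmo(params, enabled = TRUE, speed = speeds[1],
                           return_site = return_site)
  rows <- list()
  for (sc in e_max_scales) {
    p_sc <- set_contractility(params, "left", "scale_e_max", sc)
    warm <- NULL
    for (s in speeds) {
      p <- configure_ecmo(p_sc, speed = s)
      st <- .steady_point(p, warm)
      warm <- st
      m <- st$summary$mean
      rows[[length(rows) + 1]] <- data.frame(
        contractility_scale = sc, speed = s,
        lap = m[["lap"]], maop = m[["maop"]], rap = m[["rap"]],
        systemic_flow = m[["systemic_flow"]],
        ecmo_flow = m[["ecmo_flow"]], converged = st$converged)
    }
  }
  .new_experiment("contractility_grid", configuration, preset,
                  "contractility_scale", do.call(rbind, rows))
}

#' Antegrade vs retrograde return comparison
#'
#' Runs the same speed ladder with ECMO return into the proximal aorta
#' (antegrade) and into the femoral node (retrograde) and compares the
#' steady LAP between the two directions with a one-way ANOVA (default 7
#' speeds per direction, i.e. (1, 12) degrees of freedom).
#'
#' @param params preset parameters.
#' @param configuration `"SV"`, `"BV"` or `"BVFS"`.
#' @param speeds pump speeds in RPM (applied to both directions).
#' @return an `mcl_experiment` with per-(speed, direction) summaries, the
#'   per-speed LAP differences and an attached `mcl_anova`.
#' @export
run_direction_comparison <- function(params,
                                     configuration = c("BVFS", "BV", "SV"),
                                     speeds = seq(1800, 4000,
                                                  length.out = 7)) {
  configuration <- match.arg(configuration)
  preset <- attr(params, "preset_name") %||% "custom"
  params <- set_configuration(params, configuration)
  rows <- list()
  for (dir in c("antegrade_aorta", "retrograde_femoral")) {
    warm <- NULL
    for (s in speeds) {
      p <- configure_ecmo(params, enabled = TRUE, speed = s,
                          return_site = dir)
      st <- .steady_point(p, warm)
      warm <- st
      m <- st$summary$mean
      rows[[length(rows) + 1]] <- data.frame(
        return_site = dir, speed = s, lap = m[["lap"]],
        maop = m[["maop"]], rap = m[["rap"]],
        ecmo_flow = m[["ecmo_flow"]], converged = st$converged)
    }
  }
  tab <- do.call(rbind, rows)
  groups <- split(tab$lap, tab$return_site)
  an <- one_way_anova(groups)
  ante <- tab[tab$return_site == "antegrade_aorta", ]
  retro <- tab[tab$return_site == "retrograde_femoral", ]
  diffs <- merge(ante[, c("speed", "lap")], retro[, c("speed", "lap")],
                 by = "speed", suffixes = c("_antegrade", "_retrograde"))
  diffs$lap_difference <- diffs$lap_antegrade - diffs$lap_retrograde
  .new_experiment("direction_comparison", configuration, preset,
                  "return_site", tab, an,
                  extra = list(per_speed = diffs))
}
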