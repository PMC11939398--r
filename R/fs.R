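#' Frank-Starling end-systolic pressure setpoint
#'
#' The controller's setpoint law is linear in the mean atrial pressure,
#' analogous to an end-systolic pressure-volume relationship:
#' `esp_target = slope * atrial_pressure + intercept`, floored at zero.
#'
#' @param mean_atrial_pressure beat-mean atrial pressure in mmHg.
#' @param slope dimensionless (mmHg ESP per mmHg atrial pressure).
#' @param intercept mmHg.
#' @return target end-systolic pressure in mmHg (>= 0).
#' @export
#' @examples
#' fs_target_esp(12, slope = 4, intercept = 20)  # 68 mmHg
fs_target_esp <- function(mean_atrial_pressure, slope, intercept) {
  pmax(0, slope * mean_atrial_pressure + intercept)
}

#' Per-beat Frank-Starling controller update
#'
#' Discrete integral control acting once per beat: for each side the ESP
#' error (setpoint from the atrial pressure minus the measured ESP) drives
#' a multiplicative, relative-error update of the end-systolic elastance,
#' clipped to the configured bounds:
#' `e_max <- clip(e_max * (1 + gain * error / max(measured ESP, 1)))`.
#' The update is applied at the next beat boundary only.
#'
#' @param ctrl controller state: `current_e_max_lv`, `current_e_max_rv`
#'   (mmHg/mL).
#' @param fs the `fs` block of an [mcl_params()] object.
#' @param measured a [beat_metrics()] record for the completed beat.
#' @return updated controller state, with the measured atrial pressures,
#'   ESPs and targets recorded.
#' @export
fs_beat_update <- function(ctrl, fs, measured) {
  tgt_l <- fs_target_esp(measured$lap, fs$slope_lv, fs$intercept_lv)
  tgt_r <- fs_target_esp(measured$rap, fs$slope_rv, fs$intercept_rv)
  upd <- function(e, target, esp, bounds, e_min) {
    err <- target - esp
    e <- e * (1 + fs$gain * err / max(esp, 1))
    # never drive systolic elastance at or below the diastolic one
    min(max(e, bounds[1], 1.05 * e_min), bounds[2])
  }
  list(
    current_e_max_lv = upd(ctrl$current_e_max_lv, tgt_l, measured$lvesp,
                           fs$e_max_bounds$left, ctrl$e_min_lv %||% 0),
    current_e_max_rv = upd(ctrl$current_e_max_rv, tgt_r, measured$rvesp,
                           fs$e_max_bounds$right, ctrl$e_min_rv %||% 0),
    last_beat_mean_lap = measured$lap,
    last_beat_mean_rap = measured$rap,
    last_lvesp = measured$lvesp,
    last_rvesp = measured$rvesp,
    last_target_lvesp = tgt_l,
    last_target_rvesp = tgt_r
  )
}

#' Set ventricular contractility
#'
#' In the SV and BV configurations contractility is the end-systolic
#' elastance itself and only `scale_e_max` is legal (the bench analogue is
#' scaling the pneumatic driving pressure).  In the BVFS configuration the
#' controller owns `e_max`, so contractility is instead altered through the
#' Frank-Starling setpoint law: `fs_slope` / `fs_intercept` set the named
#' coefficient, and `scale_e_max` scales both coefficients (scaling the
#' whole ESP target), which is how graded contractility sweeps are run.
#'
#' @param params an [mcl_params()] object.
#' @param side `"left"` or `"right"`.
#' @param mode `"scale_e_max"`, `"fs_slope"` or `"fs_intercept"`.
#' @param value multiplier (for `scale_e_max`) or new coefficient value.
#' @return the modified `mcl_params` object.
#' @export
set_contractility <- function(params, side = c("left", "right"),
                              mode = c("scale_e_max", "fs_slope",
                                       "fs_intercept"),
                              value) {
  side <- match.arg(side)
  mode <- match.arg(mode)
  if (mode != "scale_e_max" && !isTRUE(params$fs$enabled))
    stop("configuration error: ", mode,
         " requires the Frank-Starling controller (BVFS configuration)",
         call. = FALSE)
  sfx <- if (side == "left") "lv" else "rv"
  if (mode == "scale_e_max") {
    if (isTRUE(params$fs$enabled)) {
      params$fs[[paste0("slope_", sfx)]] <-
        params$fs[[paste0("slope_", sfx)]] * value
      params$fs[[paste0("intercept_", sfx)]] <-
        params$fs[[paste0("intercept_", sfx)]] * value
    } else {
      # driver voltage scaling: both the elastance and the line-pressure
      # ceiling scale with the delivered driving pressure
      params$ventricles[[side]]$e_max <-
        params$ventricles[[side]]$e_max * value
      params$ventricles[[side]]$p_drive_cap <-
        params$ventricles[[side]]$p_drive_cap * value
    }
  } else if (mode == "fs_slope") {
    params$fs[[paste0("slope_", sfx)]] <- value
  } else {
    params$fs[[paste0("intercept_", sfx)]] <- value
  }
  validate_params(params)
  params
}
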