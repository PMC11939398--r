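.trapz <- function(t, y) {
  n <- length(t)
  sum((y[-1] + y[-n]) * diff(t)) / 2
}

.trapz_mean <- function(t, y) .trapz(t, y) / (t[length(t)] - t[1])

#' Split a trajectory into whole-beat windows
#'
#' Windows are aligned to elastance-cycle boundaries (times at integer
#' multiples of the period); a partial trailing beat is discarded.
#'
#' @param sim an `mcl_sim` trajectory (or a matrix with a `time_s` column).
#' @param period beat period in seconds (defaults to the simulation's).
#' @return list of row-index vectors, one per complete beat; empty when
#'   the trajectory is shorter than one period.
#' @export
segment_beats <- function(sim, period = NULL) {
  if (is.null(period)) period <- 60 / attr(sim, "params")$heart_rate
  tt <- sim[, "time_s"]
  dt <- tt[2] - tt[1]
  first <- ceiling((tt[1] - dt / 2) / period)
  windows <- list()
  k <- first
  repeat {
    lo <- k * period; hi <- (k + 1) * period
    idx <- which(tt >= lo - dt / 2 & tt <= hi + dt / 2)
    if (!length(idx) || tt[max(idx)] < hi - dt / 2) break
    # clip to exactly one period of samples
    idx <- idx[tt[idx] >= lo - dt / 2 & tt[idx] <= hi + dt / 2]
    windows[[length(windows) + 1]] <- idx
    k <- k + 1
  }
  windows
}

#' Per-beat hemodynamic metrics
#'
#' Extracts the reported quantities from one full beat window: time-mean
#' pressures (mAoP, LAP, RAP, mPAP) by trapezoidal integration, end-systolic
#' ventricular pressures at outflow-valve closure (or at peak elastance if
#' the valve never opens), beat-mean systemic and ECMO flows in L/min, and
#' stroke volumes as the integral of outflow-valve flow.
#'
#' @param window trajectory rows spanning exactly one beat (an `mcl_sim`
#'   slice or matrix with the standard columns).
#' @param params the [mcl_params()] in effect for the beat.
#' @return a `beat_metrics` list: `maop`, `lap`, `rap`, `mpap`, `lvesp`,
#'   `rvesp` (mmHg), `systemic_flow`, `ecmo_flow`, `lv_outflow` (L/min),
#'   `lv_stroke_volume`, `rv_stroke_volume` (mL), `aortic_valve_opened`.
#' @export
beat_metrics <- function(window, params) {
  tt <- window[, "time_s"]
  esp <- function(qcol, pcol) {
    open <- which(window[, qcol] > 0)
    if (length(open)) window[max(open), pcol]
    else window[which.max(window[, "e_norm"]), pcol]
  }
  sv_l <- .trapz(tt, window[, "q_aortic"])
  sv_r <- .trapz(tt, window[, "q_pulmonary"])
  period <- tt[length(tt)] - tt[1]
  m <- list(
    maop = .trapz_mean(tt, window[, "p_ao"]),
    lap = .trapz_mean(tt, window[, "p_la"]),
    rap = .trapz_mean(tt, window[, "p_ra"]),
    mpap = .trapz_mean(tt, window[, "p_pa"]),
    lvesp = esp("q_aortic", "p_lv"),
    rvesp = esp("q_pulmonary", "p_rv"),
    systemic_flow = .trapz_mean(tt, window[, "q_systemic"]) * 0.06,
    ecmo_flow = .trapz_mean(tt, window[, "q_ecmo"]) * 0.06,
    lv_outflow = sv_l / period * 0.06,
    lv_stroke_volume = sv_l,
    rv_stroke_volume = sv_r,
    aortic_valve_opened = any(window[, "q_aortic"] > 0)
  )
  class(m) <- c("beat_metrics", "list")
  m
}

#' @export
as.data.frame.beat_metrics <- function(x, ...) {
  as.data.frame(unclass(x), ...)
}

#' Mean and spread of trailing steady beats
#'
#' Fieldwise mean and standard deviation over at least three per-beat
#' metric records; the standard deviations quantify how steady the declared
#' steady state is.
#'
#' @param beats list of [beat_metrics()] records (>= 3).
#' @return a `steady_summary` list with `mean` and `sd` beat-metric
#'   vectors and `n_beats`.
#' @export
steady_summary <- function(beats) {
  if (length(beats) < 3)
    stop("insufficient data: steady summary needs at least 3 beats",
         call. = FALSE)
  df <- do.call(rbind, lapply(beats, as.data.frame))
  num <- names(df)[vapply(df, is.numeric, TRUE)]
  structure(list(
    mean = vapply(df[num], mean, 0),
    sd = vapply(df[num], stats::sd, 0),
    aortic_valve_opened = any(df$aortic_valve_opened),
    n_beats = nrow(df)
  ), class = "steady_summary")
}

#' @export
print.steady_summary <- function(x, ...) {
  m <- x$mean; s <- x$sd
  cat(sprintf("  mAoP %6.1f (sd %.2f) mmHg   LAP %6.1f (sd %.2f) mmHg\n",
              m[["maop"]], s[["maop"]], m[["lap"]], s[["lap"]]))
  cat(sprintf("  RAP  %6.1f (sd %.2f) mmHg   mPAP %5.1f (sd %.2f) mmHg\n",
              m[["rap"]], s[["rap"]], m[["mpap"]], s[["mpap"]]))
  cat(sprintf("  systemic flow %.2f L/min   ECMO flow %.2f L/min   LVESP %.1f   RVESP %.1f\n",
              m[["systemic_flow"]], m[["ecmo_flow"]],
              m[["lvesp"]], m[["rvesp"]]))
  invisible(x)
}
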