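#' Gauge pressure of a gas-column Windkessel chamber
#'
#' The sealed chambers trap an air column above the working fluid; adding
#' water compresses the air isothermally, so the absolute pressure follows
#' `P = pressure_abs_ref * air_volume_ref / air_volume` with
#' `air_volume = air_volume_ref - (water_volume - water_volume_ref)`.
#' The returned value is gauge (atmosphere = 0 at 760 mmHg absolute).  The
#' small-signal compliance at the reference fill is
#' `air_volume_ref / pressure_abs_ref` mL/mmHg, which is how the bench
#' syringe adjusts compliance by moving the water level.
#'
#' @param chamber list with `air_volume_ref`, `pressure_abs_ref`,
#'   `water_volume_ref` and current `water_volume` (mL / mmHg absolute).
#' @return gauge pressure in mmHg.
#' @export
#' @examples
#' ch <- list(air_volume_ref = 1500, pressure_abs_ref = 760,
#'            water_volume_ref = 1000, water_volume = 1100)
#' chamber_pressure(ch)
chamber_pressure <- function(chamber) {
  air <- chamber$air_volume_ref -
    (chamber$water_volume - chamber$water_volume_ref)
  if (any(air <= 0))
    stop("degenerate chamber: flooded (non-positive air volume)", call. = FALSE)
  chamber$pressure_abs_ref * chamber$air_volume_ref / air - 760
}

#' Instantaneous ventricular pressures with interventricular coupling
#'
#' Free-wall pressures follow the time-varying elastance law
#' `p_free = E(t) (V - v0)`; the coupled pressures add a fraction of the
#' contralateral free-wall pressure (septal cross-talk) and, when enabled, a
#' common pericardial term proportional to total heart-volume excess:
#' `p_lv = p_lv_free + alpha_rl p_rv_free + p_peri` and symmetrically for
#' the RV.  The transmitted contralateral pressure is clipped at
#' `transmission_cap` (the septal displacement limit), so cross-talk is
#' linear over the physiologic range and saturates at extremes.  In the SV
#' configuration both alphas are zero and the free-wall pressures are
#' returned unchanged.
#'
#' @param state named state vector (see [initial_state()]).
#' @param t time in seconds (sets the elastance phase).
#' @param params an [mcl_params()] object.
#' @return named vector `c(p_lv, p_rv)` in mmHg.
#' @export
ventricular_pressures <- function(state, t, params) {
  period <- 60 / params$heart_rate
  en <- normalized_elastance(t, period, params$waveform)
  vl <- params$ventricles$left; vr <- params$ventricles$right
  # active pressure saturates at the pneumatic driver line pressure
  act_lv <- min((vl$e_max - vl$e_min) * (state[["v_lv"]] - vl$v0),
                vl$p_drive_cap)
  act_rv <- min((vr$e_max - vr$e_min) * (state[["v_rv"]] - vr$v0),
                vr$p_drive_cap)
  p_lv_free <- vl$e_min * (state[["v_lv"]] - vl$v0) + en * act_lv
  p_rv_free <- vr$e_min * (state[["v_rv"]] - vr$v0) + en * act_rv
  cp <- params$coupling
  p_peri <- 0
  if (isTRUE(cp$pericardial_enabled)) {
    excess <- state[["v_lv"]] + state[["v_rv"]] +
      state[["v_la"]] + state[["v_ra"]] - cp$pericardial_v0
    p_peri <- cp$pericardial_stiffness * max(0, excess)
  }
  sat <- cp$transmission_cap
  x_rv <- min(max(p_rv_free, -sat), sat)
  x_lv <- min(max(p_lv_free, -sat), sat)
  c(p_lv = p_lv_free + cp$alpha_rl * x_rv + p_peri,
    p_rv = p_rv_free + cp$alpha_lr * x_lv + p_peri)
}

#' Flow through an ideal-diode valve
#'
#' Mechanical bi-leaflet valves are modelled as ideal diodes with a linear
#' forward resistance: `flow = max(0, dP) / resistance`.  Flow is never
#' negative and is continuous at closure.
#'
#' @param p_upstream,p_downstream pressures in mmHg.
#' @param resistance forward resistance in mmHg s/mL (> 0).
#' @return flow in mL/s.
#' @export
#' @examples
#' valve_flow(10, 0, 0.05)   # 200 mL/s
#' valve_flow(0, 5, 0.05)    # closed: 0
valve_flow <- function(p_upstream, p_downstream, resistance) {
  stopifnot(resistance > 0)
  pmax(0, p_upstream - p_downstream) / resistance
}

#' Circuit right-hand side (reference implementation)
#'
#' Node-balance derivative of the full state: each compliant-node volume
#' changes by inflows minus outflows, with ideal-diode valve flows and
#' linear pressure-driven vascular flows; the ECMO branch flow is a state
#' driven by the pump head minus back-pressure and cannula losses through a
#' small inertance.  The sum of all volume derivatives is zero by
#' construction (the loop conserves fluid; the ECMO branch transports, it
#' does not store).
#'
#' This R function is the readable definition of the model; simulation uses
#' a C++ transcription of the same equations (verified equal in the test
#' suite).
#'
#' @param t time in seconds.
#' @param state named state vector.
#' @param params an [mcl_params()] object.
#' @return list with `dstate` (named derivative vector) and `aux` (named
#'   vector of node pressures and flows at `(t, state)`).
#' @export
circuit_rhs <- function(t, state, params) {
  if (any(!is.finite(state)))
    stop(sprintf("integration failure: non-finite state component `%s`",
                 paste(.state_names[!is.finite(state)], collapse = ", ")),
         call. = FALSE)
  vp <- ventricular_pressures(state, t, params)
  vs <- params$vascular
  p_la <- (state[["v_la"]] - vs$v0_la) / vs$c_la
  p_ra <- (state[["v_ra"]] - vs$v0_ra) / vs$c_ra
  chp <- function(nm, w) {
    ch <- params$chambers[[nm]]
    ch$water_volume <- w
    chamber_pressure(ch)
  }
  p_ao <- chp("aoc", state[["water_aoc"]])
  p_svc <- chp("svc", state[["water_svc"]])
  p_pa <- chp("pac", state[["water_pac"]])
  p_pvc <- chp("pvc", state[["water_pvc"]])

  vv <- params$valves
  q_mi <- valve_flow(p_la, vp[["p_lv"]], vv$mitral)
  q_av <- valve_flow(vp[["p_lv"]], p_ao, vv$aortic)
  q_tri <- valve_flow(p_ra, vp[["p_rv"]], vv$tricuspid)
  q_pval <- valve_flow(vp[["p_rv"]], p_pa, vv$pulmonary)

  ec <- params$ecmo
  ecmo_on <- isTRUE(ec$enabled)
  retro <- ec$return_site == "retrograde_femoral"
  q_e <- if (ecmo_on) state[["q_ecmo"]] else 0
  q_fem_in <- if (ecmo_on && retro) q_e else 0

  q_ub <- (p_ao - p_svc) / vs$r_upper_body
  r_half <- vs$r_lower_body / 2
  p_fem <- (p_ao + p_svc + q_fem_in * r_half) / 2
  q_lb1 <- (p_ao - p_fem) / r_half
  q_lb2 <- (p_fem - p_svc) / r_half

  q_vr <- (p_svc - p_ra) / (vs$r_venous_return * vs$clamp_factor)
  q_part <- (p_pa - p_pvc) / vs$r_pulmonary
  q_pven <- (p_pvc - p_la) / vs$r_pulm_venous

  dq_e <- 0
  if (ecmo_on) {
    head <- pump_head(ec$speed, q_e * 0.06, ec)
    p_ret <- if (retro) p_fem else p_ao
    dq_e <- (p_ra + head - p_ret - (ec$r_drainage + ec$r_return) * q_e) /
      ec$inertance
  }

  dstate <- c(
    v_lv = q_mi - q_av,
    v_rv = q_tri - q_pval,
    v_la = q_pven - q_mi,
    v_ra = q_vr - q_tri - q_e,
    water_aoc = q_av - q_ub - q_lb1 + (if (ecmo_on && !retro) q_e else 0),
    water_svc = q_ub + q_lb2 - q_vr,
    water_pac = q_pval - q_part,
    water_pvc = q_part - q_pven,
    q_ecmo = dq_e
  )
  aux <- c(p_lv = unname(vp[["p_lv"]]), p_rv = unname(vp[["p_rv"]]),
           p_la = p_la, p_ra = p_ra, p_ao = p_ao, p_svc = p_svc,
           p_pa = p_pa, p_pvc = p_pvc,
           q_mitral = q_mi, q_aortic = q_av, q_tricuspid = q_tri,
           q_pulmonary = q_pval, q_systemic = q_vr, q_ecmo = q_e)
  list(dstate = dstate, aux = aux)
}
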