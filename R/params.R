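#' Construct a full circuit parameter set
#'
#' Builds the complete parameter description of the mock loop: a pneumatic
#' twin-ventricle heart (time-varying elastance), four gas-column Windkessel
#' compliance chambers (aortic, systemic venous, pulmonary arterial,
#' pulmonary venous), upper/lower-body systemic branches, passive linear
#' atria, an optional interventricular/pericardial coupling, an optional
#' per-beat Frank-Starling controller and an optional VA-ECMO branch.
#'
#' The `configuration` gates the physiology switches:
#' \describe{
#'   \item{SV}{separate ventricles: coupling zeroed, pericardium off,
#'     Frank-Starling controller off.}
#'   \item{BV}{biventricular: coupling active, controller off.}
#'   \item{BVFS}{biventricular with active Frank-Starling controller.}
#' }
#'
#' Units are mmHg, mL and seconds internally; flows are reported in L/min at
#' user-facing interfaces.
#'
#' @param configuration one of `"SV"`, `"BV"`, `"BVFS"`.
#' @param heart_rate beats per minute.
#' @param ventricles list with `left`/`right`, each `e_max`, `e_min`
#'   (mmHg/mL), `v0` (mL) and `p_drive_cap` (mmHg), the pneumatic-driver
#'   line pressure that saturates the active (systolic) pressure the
#'   diaphragm can generate.
#' @param coupling list: `alpha_rl`, `alpha_lr` (dimensionless additive
#'   pressure cross-talk), `transmission_cap` (mmHg, saturation of the
#'   transmitted pressure), `pericardial_enabled`, `pericardial_stiffness`
#'   (mmHg/mL), `pericardial_v0` (mL).
#' @param valves named resistances (mmHg s/mL) for `mitral`, `aortic`,
#'   `tricuspid`, `pulmonary`.
#' @param vascular list of vascular resistances (mmHg s/mL), atrial
#'   compliances `c_la`/`c_ra` (mL/mmHg) with unstressed volumes
#'   `v0_la`/`v0_ra` (mL), and the venous-return `clamp_factor` (>= 1).
#' @param chambers list of four Windkessel chambers (`aoc`, `svc`, `pac`,
#'   `pvc`), each with `air_volume_ref`, `pressure_abs_ref`,
#'   `water_volume_ref` and the initial `water_volume` (all mL / mmHg abs).
#' @param ecmo ECMO branch: `enabled`, `speed` (RPM, 1800--4000 when
#'   enabled), `return_site` (`"antegrade_aorta"` or
#'   `"retrograde_femoral"`), pump head coefficients `c0` (mmHg/RPM^2),
#'   `c1` (mmHg/(RPM L/min)), `c2` (mmHg/(L/min)^2), cannula resistances
#'   `r_drainage`/`r_return` and `inertance` (mmHg s^2/mL).
#' @param fs Frank-Starling controller: `enabled`, per-side linear setpoint
#'   `slope_*` (mmHg ESP per mmHg atrial pressure) and `intercept_*`
#'   (mmHg), integral `gain` (per beat), and per-side `e_max_bounds`.
#' @param waveform normalized elastance shape (double-Hill):
#'   `systolic_fraction`, exponents `n1`, `n2`, time constants `tau1`,
#'   `tau2` as fractions of the beat period.
#' @param initial_state optional named state vector (see
#'   [initial_state()]); defaults are derived from the chamber fills.
#' @return an object of class `mcl_params`.
#' @export
mcl_params <- function(configuration = c("BVFS", "BV", "SV"),
                       heart_rate = 60,
                       ventricles = list(),
                       coupling = list(),
                       valves = list(),
                       vascular = list(),
                       chambers = list(),
                       ecmo = list(),
                       fs = list(),
                       waveform = list(),
                       initial_state = NULL) {
  configuration <- match.arg(configuration)
  p <- list(
    configuration = configuration,
    heart_rate = heart_rate,
    ventricles = utils::modifyList(list(
      left  = list(e_max = 2.5, e_min = 0.055, v0 = 10, p_drive_cap = 80),
      right = list(e_max = 0.6, e_min = 0.05, v0 = 10, p_drive_cap = 60)
    ), ventricles),
    coupling = utils::modifyList(list(
      alpha_rl = 0.2852, alpha_lr = 0.0713,
      transmission_cap = 12,
      pericardial_enabled = FALSE,
      pericardial_stiffness = 0.5, pericardial_v0 = 400
    ), coupling),
    valves = utils::modifyList(list(
      mitral = 0.005, aortic = 0.01, tricuspid = 0.005, pulmonary = 0.01
    ), valves),
    vascular = utils::modifyList(list(
      r_upper_body = 1.52, r_lower_body = 1.52,
      r_pulmonary = 0.07, r_venous_return = 0.08, r_pulm_venous = 0.018,
      c_la = 4, c_ra = 9, v0_la = 5, v0_ra = 5,
      clamp_factor = 1
    ), vascular),
    chambers = utils::modifyList(list(
      aoc = list(air_volume_ref = 1500, pressure_abs_ref = 760,
                 water_volume_ref = 1000, water_volume = 1110),
      svc = list(air_volume_ref = 250, pressure_abs_ref = 760,
                 water_volume_ref = 2100, water_volume = 2105),
      pac = list(air_volume_ref = 1200, pressure_abs_ref = 760,
                 water_volume_ref = 1300, water_volume = 1327),
      pvc = list(air_volume_ref = 2000, pressure_abs_ref = 760,
                 water_volume_ref = 500, water_volume = 531)
    ), chambers),
    ecmo = utils::modifyList(list(
      enabled = FALSE, speed = 3000, return_site = "retrograde_femoral",
      c0 = 1.3e-5, c1 = -0.002, c2 = -0.6,
      r_drainage = 0.25, r_return = 0.45, inertance = 0.01
    ), ecmo),
    fs = utils::modifyList(list(
      enabled = (configuration == "BVFS"),
      slope_lv = 4, intercept_lv = 20,
      slope_rv = 2, intercept_rv = 8,
      gain = 0.3,
      e_max_bounds = list(left = c(0.1, 10), right = c(0.03, 8))
    ), fs),
    waveform = utils::modifyList(list(
      systolic_fraction = 0.36, n1 = 1.32, n2 = 21.9,
      tau1 = 0.269, tau2 = 0.452
    ), waveform)
  )
  class(p) <- "mcl_params"
  p <- set_configuration(p, configuration)
  p$initial_state <- if (is.null(initial_state)) initial_state(p) else {
    stopifnot(setequal(names(initial_state), .state_names))
    initial_state[.state_names]
  }
  p$total_fluid_volume <- sum(p$initial_state[1:8])
  validate_params(p)
  p
}

.state_names <- c("v_lv", "v_rv", "v_la", "v_ra",
                  "water_aoc", "water_svc", "water_pac", "water_pvc",
                  "q_ecmo")

#' Apply a model configuration and its physiology gating
#'
#' `SV` zeroes the coupling, disables the pericardium and the
#' Frank-Starling controller; `BV` keeps coupling but disables the
#' controller; `BVFS` enables both.  Other parameters are untouched, so a
#' single calibrated preset can be run in all three configurations.
#'
#' @param params an [mcl_params()] object.
#' @param configuration `"SV"`, `"BV"` or `"BVFS"`.
#' @return the modified `mcl_params` object.
#' @export
set_configuration <- function(params, configuration = c("BVFS", "BV", "SV")) {
  configuration <- match.arg(configuration)
  params$configuration <- configuration
  if (configuration == "SV") {
    params$coupling$alpha_rl <- 0
    params$coupling$alpha_lr <- 0
    params$coupling$pericardial_enabled <- FALSE
    params$fs$enabled <- FALSE
  } else if (configuration == "BV") {
    params$fs$enabled <- FALSE
  } else {
    params$fs$enabled <- TRUE
  }
  params
}

#' Validate a circuit parameter set
#'
#' Checks the structural invariants (positive resistances and compliances,
#' ordered elastance pairs, coupling fractions in \[0, 1), ECMO speed range
#' when enabled, configuration gating, positive air columns) and fails with
#' an informative error naming the offending field.
#'
#' @param params an [mcl_params()] object.
#' @return `params`, invisibly, if valid.
#' @export
validate_params <- function(params) {
  fail <- function(field, msg) {
    stop(sprintf("invalid parameter `%s`: %s", field, msg), call. = FALSE)
  }
  if (!params$configuration %in% c("SV", "BV", "BVFS"))
    fail("configuration", "must be SV, BV or BVFS")
  if (!is.numeric(params$heart_rate) || params$heart_rate <= 0)
    fail("heart_rate", "must be positive")
  for (side in c("left", "right")) {
    v <- params$ventricles[[side]]
    if (!(v$e_max > v$e_min && v$e_min > 0))
      fail(paste0("ventricles$", side), "requires e_max > e_min > 0")
    if (v$v0 < 0) fail(paste0("ventricles$", side, "$v0"), "must be >= 0")
    if (v$p_drive_cap <= 0)
      fail(paste0("ventricles$", side, "$p_drive_cap"), "must be > 0")
  }
  cp <- params$coupling
  if (cp$alpha_rl < 0 || cp$alpha_rl >= 1 || cp$alpha_lr < 0 || cp$alpha_lr >= 1)
    fail("coupling", "alpha terms must lie in [0, 1)")
  if (cp$transmission_cap <= 0)
    fail("coupling$transmission_cap", "must be > 0")
  if (params$configuration == "SV" &&
      (cp$alpha_rl != 0 || cp$alpha_lr != 0 || isTRUE(cp$pericardial_enabled)))
    fail("coupling", "SV configuration requires zero coupling")
  if (params$configuration != "BVFS" && isTRUE(params$fs$enabled))
    fail("fs$enabled", "Frank-Starling controller requires BVFS configuration")
  for (nm in names(params$valves))
    if (params$valves[[nm]] <= 0) fail(paste0("valves$", nm), "must be > 0")
  vs <- params$vascular
  for (nm in c("r_upper_body", "r_lower_body", "r_pulmonary",
               "r_venous_return", "r_pulm_venous", "c_la", "c_ra"))
    if (vs[[nm]] <= 0) fail(paste0("vascular$", nm), "must be > 0")
  if (vs$clamp_factor < 1) fail("vascular$clamp_factor", "must be >= 1")
  for (nm in names(params$chambers)) {
    ch <- params$chambers[[nm]]
    if (ch$air_volume_ref <= 0) fail(paste0("chambers$", nm), "air_volume_ref must be > 0")
    if (ch$water_volume < 0) fail(paste0("chambers$", nm), "water_volume must be >= 0")
    if (ch$air_volume_ref - (ch$water_volume - ch$water_volume_ref) <= 0)
      fail(paste0("chambers$", nm), "chamber flooded (non-positive air column)")
  }
  ec <- params$ecmo
  if (isTRUE(ec$enabled) && (ec$speed < 1800 || ec$speed > 4000))
    fail("ecmo$speed", "must lie in [1800, 4000] RPM when enabled")
  if (!ec$return_site %in% c("antegrade_aorta", "retrograde_femoral"))
    fail("ecmo$return_site", "must be antegrade_aorta or retrograde_femoral")
  if (ec$c0 <= 0) fail("ecmo$c0", "must be > 0")
  if (ec$c2 >= 0) fail("ecmo$c2", "must be < 0")
  if (ec$inertance <= 0) fail("ecmo$inertance", "must be > 0")
  fs <- params$fs
  if (fs$slope_lv < 0 || fs$slope_rv < 0) fail("fs", "slopes must be >= 0")
  if (fs$gain <= 0) fail("fs$gain", "must be > 0")
  for (side in c("left", "right")) {
    b <- fs$e_max_bounds[[side]]
    if (length(b) != 2 || b[1] >= b[2])
      fail(paste0("fs$e_max_bounds$", side), "must be an ordered pair")
  }
  wf <- params$waveform
  if (wf$systolic_fraction <= 0 || wf$systolic_fraction >= 1)
    fail("waveform$systolic_fraction", "must lie in (0, 1)")
  invisible(params)
}

#' Default initial state for a parameter set
#'
#' Returns the named state vector (ventricular, atrial and chamber water
#' volumes in mL plus the ECMO branch flow in mL/s).  Atrial volumes are
#' seeded at plausible filling pressures and chamber waters at their stored
#' values; the steady-state operating point depends only on the total fluid
#' volume, not on its initial distribution.
#'
#' @param params an [mcl_params()] object.
#' @return named numeric vector of length 9.
#' @export
initial_state <- function(params) {
  vs <- params$vascular
  s <- c(
    v_lv = 120, v_rv = 110,
    v_la = vs$v0_la + 10 * vs$c_la,
    v_ra = vs$v0_ra + 6 * vs$c_ra,
    water_aoc = params$chambers$aoc$water_volume,
    water_svc = params$chambers$svc$water_volume,
    water_pac = params$chambers$pac$water_volume,
    water_pvc = params$chambers$pvc$water_volume,
    q_ecmo = 0
  )
  s
}

# Flattens an mcl_params object into the slot vector consumed by the C++
# core.  Order must match enum ParSlot in src/mcl_core.cpp.
.pack_params <- function(params) {
  wf <- params$waveform
  scale <- wf$systolic_fraction / 0.3
  tau1 <- wf$tau1 * scale
  tau2 <- wf$tau2 * scale
  k <- .hill_norm_constant(wf$n1, wf$n2, tau1, tau2)
  vl <- params$ventricles$left; vr <- params$ventricles$right
  cp <- params$coupling; vv <- params$valves; vs <- params$vascular
  ch <- params$chambers; ec <- params$ecmo
  c(
    params$heart_rate, wf$systolic_fraction, wf$n1, wf$n2, tau1, tau2, k,
    vl$e_max, vl$e_min, vl$v0, vl$p_drive_cap,
    vr$e_max, vr$e_min, vr$v0, vr$p_drive_cap,
    cp$alpha_rl, cp$alpha_lr, cp$transmission_cap,
    as.numeric(isTRUE(cp$pericardial_enabled)),
    cp$pericardial_stiffness, cp$pericardial_v0,
    vv$mitral, vv$aortic, vv$tricuspid, vv$pulmonary,
    vs$r_upper_body, vs$r_lower_body, vs$r_pulmonary, vs$r_venous_return,
    vs$r_pulm_venous, vs$clamp_factor,
    vs$c_la, vs$v0_la, vs$c_ra, vs$v0_ra,
    ch$aoc$air_volume_ref, ch$aoc$pressure_abs_ref, ch$aoc$water_volume_ref,
    ch$svc$air_volume_ref, ch$svc$pressure_abs_ref, ch$svc$water_volume_ref,
    ch$pac$air_volume_ref, ch$pac$pressure_abs_ref, ch$pac$water_volume_ref,
    ch$pvc$air_volume_ref, ch$pvc$pressure_abs_ref, ch$pvc$water_volume_ref,
    as.numeric(isTRUE(ec$enabled)), ec$speed,
    as.numeric(ec$return_site == "retrograde_femoral"),
    ec$c0, ec$c1, ec$c2, ec$r_drainage, ec$r_return, ec$inertance,
    760
  )
}

# Dotted-path parameter accessors used by the event machinery and CLI.
set_param <- function(params, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  params[[keys]] <- value
  params
}

get_param <- function(params, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  params[[keys]]
}

#' @export
print.mcl_params <- function(x, ...) {
  cat(sprintf("Mock-loop circuit parameters (%s configuration)\n",
              x$configuration))
  cat(sprintf("  heart rate %.0f bpm, total fluid %.0f mL\n",
              x$heart_rate, x$total_fluid_volume))
  cat(sprintf("  LV e_max %.2f / RV e_max %.2f mmHg/mL; coupling alpha_rl %.3f, alpha_lr %.3f\n",
              x$ventricles$left$e_max, x$ventricles$right$e_max,
              x$coupling$alpha_rl, x$coupling$alpha_lr))
  cat(sprintf("  SVR (parallel) %.2f, PVR %.2f mmHg s/mL, clamp factor %.0f\n",
              1 / (1 / x$vascular$r_upper_body + 1 / x$vascular$r_lower_body),
              x$vascular$r_pulmonary, x$vascular$clamp_factor))
  if (isTRUE(x$ecmo$enabled))
    cat(sprintf("  ECMO on: %.0f RPM, %s return\n", x$ecmo$speed,
                sub("_.*", "", x$ecmo$return_site)))
  else cat("  ECMO off\n")
  if (isTRUE(x$fs$enabled))
    cat(sprintf("  Frank-Starling on: LV ESP = %.2f LAP + %.1f; RV ESP = %.2f RAP + %.1f\n",
                x$fs$slope_lv, x$fs$intercept_lv,
                x$fs$slope_rv, x$fs$intercept_rv))
  invisible(x)
}
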