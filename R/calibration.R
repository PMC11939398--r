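# Free calibration knobs.  Each maps a scalar onto a parameter-set edit:
# multiplicative scales on contractility (direct e_max in SV/BV, the
# Frank-Starling setpoint in BVFS), SVR and PVR, an additive total-fluid
# shift (into the compliant left atrium; the steady state depends only on
# the total), and chamber-fill shifts which move the Windkessel reference
# water level (the bench syringe: they retune the chamber's compliance
# curve and add fluid).
.apply_free_param <- function(params, name, value) {
  v <- params$vascular
  switch(name,
    contractility_lv = set_contractility(params, "left", "scale_e_max", value),
    contractility_rv = set_contractility(params, "right", "scale_e_max", value),
    e_max_lv = { params$ventricles$left$e_max <- value; params },
    e_max_rv = { params$ventricles$right$e_max <- value; params },
    diastolic_lv = {
      params$ventricles$left$e_min <- params$ventricles$left$e_min * value
      params
    },
    diastolic_rv = {
      params$ventricles$right$e_min <- params$ventricles$right$e_min * value
      params
    },
    svr_scale = {
      params$vascular$r_upper_body <- v$r_upper_body * value
      params$vascular$r_lower_body <- v$r_lower_body * value
      params
    },
    pvr_scale = {
      params$vascular$r_pulmonary <- v$r_pulmonary * value
      params
    },
    rvr_scale = {
      params$vascular$r_venous_return <- v$r_venous_return * value
      params
    },
    volume_shift = {
      params$initial_state[["v_la"]] <- params$initial_state[["v_la"]] + value
      params$total_fluid_volume <- sum(params$initial_state[1:8])
      params
    },
    fill_aoc = .shift_fill(params, "aoc", value),
    fill_svc = .shift_fill(params, "svc", value),
    fill_pac = .shift_fill(params, "pac", value),
    fill_pvc = .shift_fill(params, "pvc", value),
    stop("unknown free parameter: ", name, call. = FALSE)
  )
}

.shift_fill <- function(params, chamber, delta) {
  ch <- params$chambers[[chamber]]
  ch$water_volume_ref <- ch$water_volume_ref + delta
  ch$air_volume_ref <- ch$air_volume_ref - delta
  ch$water_volume <- ch$water_volume + delta
  params$chambers[[chamber]] <- ch
  key <- paste0("water_", chamber)
  params$initial_state[[key]] <- params$initial_state[[key]] + delta
  params$total_fluid_volume <- sum(params$initial_state[1:8])
  params
}

#' Define a calibration problem
#'
#' Names the free parameters with their bounds, the steady-state targets
#' (mAoP, LAP, RAP in mmHg; systemic flow in L/min) with weights, and the
#' search budget.
#'
#' @param free named list of `c(lower, upper)` bounds, one per free
#'   parameter; supported names: `contractility_lv`, `contractility_rv`,
#'   `e_max_lv`, `e_max_rv`, `diastolic_lv`, `diastolic_rv`, `svr_scale`,
#'   `pvr_scale`, `rvr_scale`, `volume_shift`,
#'   `fill_aoc`, `fill_svc`, `fill_pac`, `fill_pvc`.
#' @param targets named numeric: any of `maop`, `lap`, `rap`, `flow`.
#' @param weights optional named weights (default 1 each).
#' @param max_eval objective-evaluation budget per start.
#' @param seed RNG seed for restart perturbations.
#' @return a `calibration_spec` list.
#' @export
calibration_spec <- function(free, targets, weights = NULL, max_eval = 200,
                             seed = 1) {
  stopifnot(length(free) > 0, all(vapply(free, length, 0L) == 2))
  stopifnot(all(names(targets) %in% c("maop", "lap", "rap", "flow")))
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(targets)),
                                                   names(targets))
  structure(list(free = free, targets = targets, weights = weights,
                 max_eval = max_eval, seed = seed),
            class = "calibration_spec")
}

.steady_targets <- function(params) {
  st <- tryCatch(find_steady_state(params), error = function(e) NULL)
  if (is.null(st)) return(NULL)
  m <- st$summary$mean
  list(achieved = c(maop = m[["maop"]], lap = m[["lap"]], rap = m[["rap"]],
                    flow = m[["systemic_flow"]]),
       steady = st)
}

#' Calibrate a preset against steady-state targets
#'
#' Minimizes the weighted sum of squared relative errors between the
#' steady-state summary and the targets over the named free parameters,
#' with a derivative-free Nelder-Mead search from the given start,
#' restarting up to `restarts` times from seeded random perturbations when
#' the objective remains above `restart_threshold`.  Candidates whose
#' simulation fails or does not converge are penalized, not fatal.
#'
#' @param spec a [calibration_spec()].
#' @param base starting [mcl_params()] object.
#' @param start optional named start values (defaults to bound midpoints,
#'   or 1/0 for scale/shift parameters).
#' @param restarts maximum number of perturbed restarts.
#' @param restart_threshold objective value below which no restart is
#'   attempted.
#' @return list with `params` (best calibrated set, its converged
#'   `initial_state` written back), `achieved` metrics, `values` (best
#'   free-parameter values), `objective`, and the evaluation `trace`.
#' @export
calibrate_preset <- function(spec, base, start = NULL, restarts = 3,
                             restart_threshold = 1e-3) {
  nm <- names(spec$free)
  lower <- vapply(spec$free, `[`, 0, 1)
  upper <- vapply(spec$free, `[`, 0, 2)
  if (is.null(start)) {
    start <- ifelse(grepl("shift|fill", nm), 0, 1)
    start <- pmin(pmax(start, lower), upper)
    names(start) <- nm
  }
  trace <- list()
  tn <- names(spec$targets)
  objective <- function(theta) {
    # box-constrain by logistic folding onto the bounds
    th <- pmin(pmax(theta, lower), upper)
    penalty <- sum((theta - th)^2)
    p <- base
    for (i in seq_along(nm)) p <- .apply_free_param(p, nm[i], th[i])
    res <- tryCatch(.steady_targets(p), error = function(e) NULL)
    if (is.null(res)) {
      obj <- 100 + penalty
    } else {
      rel <- (res$achieved[tn] - spec$targets) / spec$targets
      obj <- sum(spec$weights[tn] * rel^2) + penalty
      if (!res$steady$converged) obj <- obj + 10
    }
    trace[[length(trace) + 1]] <<- c(stats::setNames(th, nm),
                                     objective = obj)
    obj
  }
  set.seed(spec$seed)
  best <- NULL
  theta0 <- start
  for (r in 0:restarts) {
    opt <- if (length(nm) == 1) {
      stats::optim(theta0, objective, method = "Brent",
                   lower = lower, upper = upper,
                   control = list(maxit = spec$max_eval))
    } else {
      stats::optim(theta0, objective, method = "Nelder-Mead",
                   control = list(maxit = spec$max_eval, reltol = 1e-6))
    }
    if (is.null(best) || opt$value < best$value) best <- opt
    if (best$value < restart_threshold) break
    span <- pmax(upper - lower, 1e-6)
    theta0 <- pmin(pmax(best$par + stats::runif(length(nm), -0.1, 0.1) *
                          span, lower), upper)
  }
  th <- pmin(pmax(best$par, lower), upper)
  p <- base
  for (i in seq_along(nm)) p <- .apply_free_param(p, nm[i], th[i])
  res <- .steady_targets(p)
  # write the converged operating point back into the preset so it ships
  # warm: the state and the controller-adapted contractility
  p$initial_state <- res$steady$state
  p$ventricles$left$e_max <- res$steady$params$ventricles$left$e_max
  p$ventricles$right$e_max <- res$steady$params$ventricles$right$e_max
  list(params = p,
       achieved = res$achieved,
       values = stats::setNames(th, nm),
       objective = best$value,
       trace = do.call(rbind, trace))
}

#' Calibrate the interventricular coupling to a clamp-transmission ratio
#'
#' One-dimensional search over a common coupling scale `s` (with
#' `alpha_rl = s` and `alpha_lr = s/4`) until the [run_clamp_test()]
#' LAP/RAP transmission ratio in the BV configuration matches the target.
#' The scale-to-ratio map is empirically monotone over the bracket;
#' bracketing is verified before bisection.
#'
#' @param base BV preset parameters (convergent without clamp).
#' @param target target transmission ratio.
#' @param tolerance acceptance band on the ratio.
#' @param bracket search interval for the coupling scale `alpha_rl`.
#' @param max_iter bisection cap.
#' @return list with `alpha_rl`, `alpha_lr`, the achieved `ratio`, and the
#'   evaluation `trace`.
#' @export
calibrate_coupling <- function(base, target = 0.47, tolerance = 0.02,
                               bracket = c(0, 0.9), max_iter = 20) {
  trace <- list()
  ratio_at <- function(s) {
    p <- base
    p$coupling$alpha_rl <- s
    p$coupling$alpha_lr <- s / 4
    r <- run_clamp_test(p, "BV")$ratio
    trace[[length(trace) + 1]] <<- c(scale = s, ratio = r)
    r
  }
  lo <- bracket[1]; hi <- bracket[2]
  r_lo <- ratio_at(lo); r_hi <- ratio_at(hi)
  if (target < min(r_lo, r_hi) - tolerance ||
      target > max(r_lo, r_hi) + tolerance)
    stop(sprintf(
      "target ratio %.2f outside achievable interval [%.3f, %.3f]",
      target, min(r_lo, r_hi), max(r_lo, r_hi)), call. = FALSE)
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    r_mid <- ratio_at(mid)
    if (abs(r_mid - target) <= tolerance) {
      return(list(alpha_rl = mid, alpha_lr = mid / 4, ratio = r_mid,
                  trace = do.call(rbind, trace)))
    }
    if ((r_mid < target) == (r_lo < target)) { lo <- mid; r_lo <- r_mid }
    else { hi <- mid; r_hi <- r_mid }
  }
  mid <- (lo + hi) / 2
  list(alpha_rl = mid, alpha_lr = mid / 4, ratio = ratio_at(mid),
       trace = do.call(rbind, trace))
}
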