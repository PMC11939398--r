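#' Centrifugal pump head-flow characteristic
#'
#' Quadratic head map of the ECMO centrifugal pump:
#' `head = c0 speed^2 + c1 speed flow + c2 flow^2` (mmHg), decreasing in
#' flow for non-negative flow since `c2 < 0` and `c1 <= 0`.  With the
#' default coefficients the zero-flow head at 3000 RPM is about 90 mmHg,
#' an HVAD-like operating point.
#'
#' @param speed impeller speed in RPM (>= 0).
#' @param flow pump flow in L/min.
#' @param p ECMO parameter block (`c0`, `c1`, `c2`; see [mcl_params()]).
#' @param check_range when `TRUE`, error if an enabled pump is driven
#'   outside the supported 1800--4000 RPM range.
#' @return pump head in mmHg.
#' @export
#' @examples
#' p <- mcl_params()$ecmo
#' pump_head(3000, 0, p)
pump_head <- function(speed, flow, p, check_range = isTRUE(p$enabled)) {
  stopifnot(all(speed >= 0))
  if (check_range && any(speed < 1800 | speed > 4000))
    stop("pump speed out of range: enabled pump supports 1800-4000 RPM",
         call. = FALSE)
  p$c0 * speed^2 + p$c1 * speed * flow + p$c2 * flow^2
}

#' ECMO branch flow derivative
#'
#' Momentum balance of the drainage-pump-return branch: the branch flow is
#' a state driven through a small inertance by the pump head plus the
#' drainage-site pressure (right atrium) minus the return-node pressure and
#' cannula losses.  The return node is the aortic compliance node for
#' antegrade return or the femoral (lower-body) node for retrograde return.
#' Flow may transiently go negative (there is no check valve in the
#' branch).
#'
#' @param state named state vector.
#' @param params an [mcl_params()] object with `ecmo$enabled = TRUE`.
#' @param t time in seconds (elastance phase; irrelevant for the branch
#'   itself).
#' @return `dq_ecmo/dt` in mL/s^2.
#' @export
ecmo_flow_rhs <- function(state, params, t = 0) {
  if (!isTRUE(params$ecmo$enabled))
    stop("ECMO branch is disabled", call. = FALSE)
  circuit_rhs(t, state, params)$dstate[["q_ecmo"]]
}

#' Configure the ECMO branch
#'
#' Sets the enable flag, pump speed and return site, leaving every other
#' parameter untouched.  Disabling zeroes the branch flow at the next
#' simulation start or event boundary.
#'
#' @param params an [mcl_params()] object.
#' @param enabled logical.
#' @param speed pump speed in RPM (validated against 1800--4000 when
#'   enabling).
#' @param return_site `"antegrade_aorta"` or `"retrograde_femoral"`.
#' @return the modified `mcl_params` object.
#' @export
configure_ecmo <- function(params, enabled = NULL, speed = NULL,
                           return_site = NULL) {
  if (!is.null(enabled)) params$ecmo$enabled <- enabled
  if (!is.null(speed)) params$ecmo$speed <- speed
  if (!is.null(return_site)) {
    return_site <- match.arg(return_site,
                             c("antegrade_aorta", "retrograde_femoral"))
    params$ecmo$return_site <- return_site
  }
  validate_params(params)
  if (!isTRUE(params$ecmo$enabled)) params$initial_state[["q_ecmo"]] <- 0
  params
}
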