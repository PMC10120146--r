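# Inverse solvers: ventilator-setting targets achieving a requested
# hazard (or safety) ratio.
#
# Drive route: solve HR_drive = (2 DP + Pt - Ps)(Ps - Pt)/DP^2 for DP with
# Ps and Pt held fixed. The quadratic has roots DP = (Ps - Pt)(1 ± sqrt(1-h))/h;
# the physical (smaller) root is the printed target. We evaluate it in the
# equivalent cancellation-free form (Ps - Pt)/(1 + sqrt(1 - h)), which is
# continuous through h = 0 where it takes the analytic limit (Ps - Pt)/2.
#
# Elastic route: solve HR_elastic = (Ps^2 - Pt^2)/(Ps^2 - PEEP^2) for Ps with
# Pt and PEEP held fixed: Target Ps = sqrt((Pt^2 - h PEEP^2)/(1 - h)).

#' Target driving pressure for a requested drive hazard ratio
#'
#' Driving pressure at which the drive hazard ratio equals `h`, holding the
#' plateau-to-threshold gap `ps - pt` fixed:
#' `Target DP = (1 - sqrt(1 - h))/h * (Ps - Pt)`, evaluated in the stable
#' equivalent form `(Ps - Pt)/(1 + sqrt(1 - h))`. At `h = 0` this is the
#' analytic limit `(Ps - Pt)/2`; at `h = 1` it is `Ps - Pt`.
#'
#' @param h requested drive hazard ratio, in \[0, 1\].
#' @param ps plateau pressure, cmH2O.
#' @param pt threshold pressure, cmH2O (`pt <= ps`).
#' @return target driving pressure, cmH2O. Vectorised.
#' @examples
#' target_dp(0.4375, ps = 25, pt = 20) # 2.857143
#' target_dp(0, ps = 25, pt = 20)      # limit (ps - pt)/2 = 2.5
#' @seealso [target_ps()], [target_vt()], [prescribe_targets()]
#' @export
target_dp <- function(h, ps, pt) {
  if (any(h < 0 | h > 1)) abort("h must lie in [0, 1]")
  if (any(pt > ps)) abort("pt must not exceed ps")
  (ps - pt) / (1 + sqrt(1 - h))
}

#' Target plateau pressure for a requested elastic hazard ratio
#'
#' Plateau pressure at which the all-inclusive elastic hazard ratio equals
#' `h`, holding PEEP and the threshold fixed:
#' `Target Ps = sqrt((Pt^2 - h PEEP^2)/(1 - h))`. At `h = 0` the target is
#' the threshold itself; as `h -> 1` the target is unbounded (an error).
#'
#' @param h requested elastic hazard ratio, in \[0, 1).
#' @param pt threshold pressure, cmH2O.
#' @param peep end-expiratory pressure, cmH2O (`peep <= pt`).
#' @return target plateau pressure, cmH2O. Vectorised.
#' @examples
#' target_ps(0.375, pt = 20, peep = 5) # 25
#' @export
target_ps <- function(h, pt, peep) {
  if (any(h < 0 | h > 1)) abort("h must lie in [0, 1]")
  if (any(h == 1)) abort("h = 1 leaves the target plateau pressure unbounded")
  if (any(peep > pt)) abort("peep must not exceed pt")
  sqrt((pt^2 - h * peep^2) / (1 - h))
}

#' Tidal volume rescaled to a target driving or plateau pressure
#'
#' With linear compliance, tidal volume scales with driving pressure, so
#' `Target V_T = (Target DP / DP) V_T`, or equivalently
#' `((Target Ps - PEEP)/DP) V_T` when a plateau-pressure target is supplied.
#' Exactly one of `target_dp` and `target_ps` must be given.
#'
#' @param vt current tidal volume, L.
#' @param dp current driving pressure, cmH2O.
#' @param target_dp target driving pressure, cmH2O (drive route).
#' @param target_ps target plateau pressure, cmH2O (elastic route; requires
#'   `peep`).
#' @param peep end-expiratory pressure, cmH2O; needed with `target_ps`.
#' @return target tidal volume, L. Vectorised.
#' @examples
#' target_vt(0.5, dp = 20, target_dp = 2.857143)
#' target_vt(0.5, dp = 20, target_ps = 25, peep = 5) # unchanged: 0.5
#' @export
target_vt <- function(vt, dp, target_dp = NULL, target_ps = NULL, peep = NULL) {
  if (is.null(target_dp) == is.null(target_ps)) {
    abort("supply exactly one of target_dp and target_ps")
  }
  if (any(vt <= 0)) abort("vt must be > 0")
  if (any(dp <= 0)) abort("dp must be > 0")
  if (!is.null(target_ps)) {
    if (is.null(peep)) abort("peep is required with target_ps")
    if (any(target_ps <= peep)) abort("target_ps must exceed peep")
    target_dp <- target_ps - peep
  }
  (target_dp / dp) * vt
}

#' Prescribe ventilator-setting targets for a requested hazard or safety ratio
#'
#' For each scenario row, inverse-solves the chosen hazard-ratio variant for
#' the ventilator target that achieves `desired_ratio`. In `"drive"` variant
#' the solved quantity is the driving pressure ([target_dp()], holding `ps`
#' and `pt` fixed); in `"elastic"` variant it is the plateau pressure
#' ([target_ps()], holding `peep` and `pt` fixed). The tidal volume is then
#' rescaled with [target_vt()]. `mode = "safe"` requests a safety ratio and
#' converts through the complement `HR = 1 - SR` before solving.
#'
#' @param data a scenario data frame (validated via [as_scenarios()]).
#' @param desired_ratio requested ratio, in \[0, 1\] (scalar or one per row).
#' @param variant `"drive"` or `"elastic"`: which energy accounting the
#'   ratio refers to.
#' @param mode `"hazard"` (default) or `"safe"`.
#' @param tol relative tolerance for scenario validation.
#' @return a tibble of class `target_prescription` with the scenario
#'   columns plus `requested_ratio`, `variant`, `mode`, `hr_requested`
#'   (the hazard-scale equivalent), `target_dp`, `target_ps`, `target_vt`,
#'   `achieved_ratio` (the hazard ratio recovered by re-inserting the target
#'   into its formula) and `held_fixed`.
#' @examples
#' ventilation_scenarios(ps = 25, peep = 5, vt = 0.5, f = 20, pt = 20) |>
#'   prescribe_targets(0.625, variant = "elastic", mode = "safe")
#' @export
prescribe_targets <- function(data, desired_ratio,
                              variant = c("drive", "elastic"),
                              mode = c("hazard", "safe"),
                              tol = 1e-9) {
  variant <- match.arg(variant)
  mode <- match.arg(mode)
  if (any(desired_ratio < 0 | desired_ratio > 1)) {
    abort("desired_ratio must lie in [0, 1]")
  }
  sc <- as_scenarios(data, tol = tol)
  h <- if (mode == "safe") 1 - desired_ratio else desired_ratio

  out <- dplyr::mutate(sc, requested_ratio = desired_ratio,
                       variant = variant, mode = mode, hr_requested = h)
  if (variant == "drive") {
    out <- dplyr::mutate(
      out,
      target_dp = target_dp(.data$hr_requested, .data$ps, .data$pt),
      target_ps = .data$ps,
      target_vt = target_vt(.data$vt, .data$dp, target_dp = .data$target_dp),
      achieved_ratio = hr_drive_given_dp(.data$target_dp, .data$ps, .data$pt),
      held_fixed = "ps,pt"
    )
  } else {
    out <- dplyr::mutate(
      out,
      target_ps = target_ps(.data$hr_requested, .data$pt, .data$peep),
      target_dp = .data$target_ps - .data$peep,
      target_vt = target_vt(.data$vt, .data$dp, target_ps = .data$target_ps,
                            peep = .data$peep),
      achieved_ratio = hr_elastic(.data$target_ps, .data$peep, .data$pt),
      held_fixed = "peep,pt"
    )
  }
  class(out) <- c("target_prescription", class(out))
  out
}
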