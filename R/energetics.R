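# Closed-form per-cycle energy accounting and hazard/safety partitioning.
#
# Geometry: with linear compliance the elastic pressure rises linearly with
# inflated volume from PEEP to Ps. Per-cycle elastic energy is the P-V area
# under that line; the threshold pressure Pt splits it into an infra-threshold
# ("safe") and a supra-threshold ("hazardous") block. Two accountings exist:
#   drive   - only the tidal (driving-pressure) energy, excluding the PEEP block
#   elastic - all conserved energy including the PEEP block

# Pt-out-of-range policy shared by the hazard-ratio functions.
resolve_pt <- function(ps, peep, pt, policy = c("clamp", "strict")) {
  policy <- match.arg(policy)
  if (policy == "strict" && any(pt < peep | pt > ps)) {
    abort("pt outside [peep, ps]; use policy = \"clamp\" to saturate instead")
  }
  pmin(pmax(pt, peep), ps)
}

#' Per-cycle elastic energy of a passive inflation
#'
#' Total conserved (elastic) energy per breath, the full P-V area including
#' the PEEP block: `W_elastic = 1/2 (Ps + PEEP) V_T`, equivalently
#' `V_T^2/(2C) + V_T PEEP`. This total is the same for every inspiratory
#' flow waveform.
#'
#' @param ps plateau pressure, cmH2O.
#' @param peep end-expiratory pressure, cmH2O.
#' @param vt tidal volume, L.
#' @return energy in cmH2O·L. Vectorised.
#' @examples
#' w_elastic(25, 5, 0.5) # 7.5 cmH2O·L
#' @seealso [w_drive()], [partition_energy()]
#' @export
w_elastic <- function(ps, peep, vt) {
  check_pressures(ps, peep)
  if (any(vt <= 0)) abort("vt must be > 0")
  0.5 * (ps + peep) * vt
}

#' Per-cycle drive energy of a passive inflation
#'
#' The purely tidal component of elastic energy, excluding the PEEP block:
#' `W_drive = 1/2 DP V_T = V_T^2/(2C)` with `DP = Ps - PEEP`. Equals
#' [w_elastic()] when PEEP = 0.
#'
#' @inheritParams w_elastic
#' @return energy in cmH2O·L. Vectorised.
#' @examples
#' w_drive(25, 5, 0.5) # 5 cmH2O·L
#' @export
w_drive <- function(ps, peep, vt) {
  check_pressures(ps, peep)
  if (any(vt <= 0)) abort("vt must be > 0")
  0.5 * (ps - peep) * vt
}

check_pressures <- function(ps, peep) {
  if (any(!is.finite(ps) | !is.finite(peep))) abort("pressures must be finite")
  if (any(peep < 0)) abort("peep must be >= 0")
  if (any(ps <= peep)) abort("ps must exceed peep (degenerate cycle, DP = 0)")
  invisible(NULL)
}

#' Hazard ratio of drive energy
#'
#' Fraction of the per-cycle drive energy delivered while the elastic
#' pressure exceeds the threshold `pt`:
#' `HR_drive = (2 DP + Pt - Ps)(Ps - Pt) / DP^2`, computed here in the
#' algebraically identical form `1 - ((Pt - PEEP)/DP)^2` =
#' `(DP^2 - (Pt - PEEP)^2)/DP^2`, which returns the boundary values 0 (at
#' `pt = ps`) and 1 (at `pt = peep`) exactly.
#'
#' @inheritParams w_elastic
#' @param pt threshold elastic pressure, cmH2O.
#' @param policy what to do when `pt` falls outside `[peep, ps]`:
#'   `"clamp"` (default) saturates the ratio at 0 / 1, matching the area
#'   geometry; `"strict"` raises an error.
#' @return hazard ratio in \[0, 1\]. Vectorised.
#' @examples
#' hr_drive(25, 5, 20) # 0.4375
#' @seealso [hr_elastic()], [safety_ratios()], [oracle_hr()]
#' @export
hr_drive <- function(ps, peep, pt, policy = c("clamp", "strict")) {
  check_pressures(ps, peep)
  pt <- resolve_pt(ps, peep, pt, policy)
  dp <- ps - peep
  ifelse(pt >= ps, 0,
         ifelse(pt <= peep, 1, (dp^2 - (pt - peep)^2) / dp^2))
}

#' Hazard ratio of total elastic energy
#'
#' Fraction of the per-cycle elastic energy (PEEP block included) delivered
#' above the threshold: `HR_elastic = (Ps^2 - Pt^2)/(Ps^2 - PEEP^2)`.
#'
#' @inheritParams hr_drive
#' @return hazard ratio in \[0, 1\]. Vectorised.
#' @examples
#' hr_elastic(25, 5, 20) # 0.375
#' @export
hr_elastic <- function(ps, peep, pt, policy = c("clamp", "strict")) {
  check_pressures(ps, peep)
  pt <- resolve_pt(ps, peep, pt, policy)
  ifelse(pt >= ps, 0,
         ifelse(pt <= peep, 1, (ps^2 - pt^2) / (ps^2 - peep^2)))
}

# The printed product form of HR_drive as a function of an arbitrary driving
# pressure with Ps and Pt held fixed. This is the form under which the
# target-DP inversion closes its round trip; for dp below the geometric value
# it extrapolates the area algebra outside the clamped domain. Internal.
hr_drive_given_dp <- function(dp, ps, pt) {
  (2 * dp + pt - ps) * (ps - pt) / dp^2
}

#' Safety ratios (complements of the hazard ratios)
#'
#' `SR = 1 - HR` for both the drive and the all-inclusive elastic
#' accounting: the infra-threshold ("safe") fraction of per-cycle energy.
#'
#' @inheritParams hr_drive
#' @return a tibble with columns `sr_drive`, `sr_elastic`.
#' @examples
#' safety_ratios(25, 5, 20) # 0.5625, 0.625
#' @export
safety_ratios <- function(ps, peep, pt, policy = c("clamp", "strict")) {
  tibble::tibble(
    sr_drive = 1 - hr_drive(ps, peep, pt, policy),
    sr_elastic = 1 - hr_elastic(ps, peep, pt, policy)
  )
}

#' Partition per-cycle energy and per-minute power at the threshold pressure
#'
#' For each scenario row, computes the per-cycle energies ([w_drive()],
#' [w_elastic()]), their hazard/safety split at the threshold `pt`
#' ([hr_drive()], [hr_elastic()]), the supra-threshold (hazardous) energies,
#' and the per-minute powers: `elastic_power = f * w_elastic`,
#' `driving_power = f * w_drive`, and the damaging powers
#' `f * HR * W` that count only supra-threshold energy. Powers are reported
#' both in cmH2O·L/min and (columns suffixed `_J`) in J/min.
#'
#' @param data a scenario data frame (see [as_scenarios()]; validation and
#'   completion are applied here).
#' @param policy Pt-out-of-range policy, `"clamp"` (default) or `"strict"`;
#'   see [hr_drive()].
#' @param tol relative tolerance for the mechanics consistency check.
#' @return a tibble of class `energy_partition`: the completed scenario
#'   columns plus `w_elastic`, `w_drive`, `hr_drive`, `hr_elastic`,
#'   `sr_drive`, `sr_elastic`, `hazardous_energy_drive`,
#'   `hazardous_energy_elastic`, `driving_power`, `elastic_power`,
#'   `damaging_power_drive`, `damaging_power_elastic` and their `_J`
#'   counterparts.
#' @examples
#' ventilation_scenarios(ps = 25, peep = 5, vt = 0.5, f = 20, pt = 20) |>
#'   partition_energy()
#' @export
partition_energy <- function(data, policy = c("clamp", "strict"), tol = 1e-9) {
  policy <- match.arg(policy)
  sc <- as_scenarios(data, tol = tol)
  out <- dplyr::mutate(
    sc,
    w_elastic = w_elastic(.data$ps, .data$peep, .data$vt),
    w_drive = w_drive(.data$ps, .data$peep, .data$vt),
    hr_drive = hr_drive(.data$ps, .data$peep, .data$pt, policy),
    hr_elastic = hr_elastic(.data$ps, .data$peep, .data$pt, policy),
    sr_drive = 1 - .data$hr_drive,
    sr_elastic = 1 - .data$hr_elastic,
    hazardous_energy_drive = .data$hr_drive * .data$w_drive,
    hazardous_energy_elastic = .data$hr_elastic * .data$w_elastic,
    driving_power = .data$f * .data$w_drive,
    elastic_power = .data$f * .data$w_elastic,
    damaging_power_drive = .data$f * .data$hazardous_energy_drive,
    damaging_power_elastic = .data$f * .data$hazardous_energy_elastic,
    driving_power_J = cmh2o_l_to_joules(.data$driving_power),
    elastic_power_J = cmh2o_l_to_joules(.data$elastic_power),
    damaging_power_drive_J = cmh2o_l_to_joules(.data$damaging_power_drive),
    damaging_power_elastic_J = cmh2o_l_to_joules(.data$damaging_power_elastic)
  )
  class(out) <- c("energy_partition", class(out))
  out
}
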