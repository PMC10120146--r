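# broom-style tidiers for the result tibbles.

#' Tidy an energy partition into long form
#'
#' One row per scenario x quantity, with the unit spelled out. Energies are
#' per cycle (cmH2O·L), powers per minute (cmH2O·L/min), ratios
#' dimensionless.
#'
#' @param x an [partition_energy()] result.
#' @param ... unused.
#' @return a tibble with columns `name`, `quantity`, `value`, `unit`.
#' @method tidy energy_partition
#' @export
tidy.energy_partition <- function(x, ...) {
  units <- c(
    w_elastic = "cmH2O.L", w_drive = "cmH2O.L",
    hr_drive = "ratio", hr_elastic = "ratio",
    sr_drive = "ratio", sr_elastic = "ratio",
    hazardous_energy_drive = "cmH2O.L", hazardous_energy_elastic = "cmH2O.L",
    driving_power = "cmH2O.L/min", elastic_power = "cmH2O.L/min",
    damaging_power_drive = "cmH2O.L/min", damaging_power_elastic = "cmH2O.L/min",
    driving_power_J = "J/min", elastic_power_J = "J/min",
    damaging_power_drive_J = "J/min", damaging_power_elastic_J = "J/min"
  )
  tibble::as_tibble(x) |>
    dplyr::select("name", dplyr::all_of(names(units))) |>
    tidyr::pivot_longer(-"name", names_to = "quantity", values_to = "value") |>
    dplyr::mutate(unit = unname(units[.data$quantity]))
}

#' Summarise an energy partition in one row
#'
#' @param x an [partition_energy()] result.
#' @param ... unused.
#' @return a one-row tibble: scenario count, mean hazard ratios, total
#'   elastic and damaging power across scenarios.
#' @method glance energy_partition
#' @export
glance.energy_partition <- function(x, ...) {
  tibble::tibble(
    n_scenarios = nrow(x),
    mean_hr_drive = mean(x$hr_drive),
    mean_hr_elastic = mean(x$hr_elastic),
    total_elastic_power = sum(x$elastic_power),
    total_damaging_power_drive = sum(x$damaging_power_drive),
    total_damaging_power_elastic = sum(x$damaging_power_elastic)
  )
}

#' Tidy a target prescription
#'
#' @param x a [prescribe_targets()] result.
#' @param ... unused.
#' @return a tibble with one row per scenario: the requested ratio, the
#'   solved targets and the achieved (round-trip) ratio.
#' @method tidy target_prescription
#' @export
tidy.target_prescription <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::select("name", "variant", "mode", "requested_ratio",
                  "hr_requested", "target_dp", "target_ps", "target_vt",
                  "achieved_ratio", "held_fixed")
}

#' Summarise a target prescription in one row
#'
#' @param x a [prescribe_targets()] result.
#' @param ... unused.
#' @return a one-row tibble with the worst round-trip error across rows.
#' @method glance target_prescription
#' @export
glance.target_prescription <- function(x, ...) {
  tibble::tibble(
    n_scenarios = nrow(x),
    variant = x$variant[1],
    mode = x$mode[1],
    max_roundtrip_error = max(abs(x$achieved_ratio - x$hr_requested))
  )
}
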