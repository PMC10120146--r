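# Regional thresholds along the gravitational axis.
#
# Transpulmonary pressure - the true distending stress - varies with height
# because pleural pressure follows a gravitational gradient. At equal airway
# pressure, non-dependent (upper) regions carry higher transpulmonary
# pressure, so their local damage threshold expressed on the airway-pressure
# scale is LOWER (more vulnerable); dependent regions are the converse.
# We model the local threshold as linear in normalised height and centred on
# the whole-lung average:
#     Pt_local(x) = Pt_avg + span * (1/2 - x),  x in [0, 1]
# with x = 0 the most dependent and x = 1 the most non-dependent position,
# and `span` the total pleural-pressure difference across the lung. This
# linear substitution model is a design choice of this package (the simplest
# form consistent with a uniform gradient), not a published parameterisation.
# Prone positioning flattens the pleural gradient, so its span is smaller.

# Illustrative defaults (cmH2O); user-configurable, not measured values.
.POSTURE_SPANS <- c(supine = 7.5, prone = 3.0)

#' Local threshold pressure along the gravitational axis
#'
#' Linear model of the regional damage threshold:
#' `pt_local = pt_average + span * (1/2 - position)`, with `position = 0`
#' the most dependent and `position = 1` the most non-dependent region.
#' Non-dependent regions get a lower threshold (more vulnerable to
#' overstretch), dependent regions a higher one; position 1/2 recovers the
#' whole-lung average.
#'
#' @param pt_average whole-lung average threshold pressure, cmH2O.
#' @param span total pleural-pressure difference across the lung, cmH2O
#'   (>= 0).
#' @param position normalised height along the gravitational axis, in
#'   \[0, 1\].
#' @return local threshold pressure, cmH2O. Vectorised.
#' @examples
#' local_pt(20, 6, c(0, 0.5, 1)) # 23, 20, 17
#' @export
local_pt <- function(pt_average, span, position) {
  if (any(span < 0)) abort("span must be >= 0")
  if (any(position < 0 | position > 1)) abort("position must lie in [0, 1]")
  pt_average + span * (0.5 - position)
}

#' Regional hazard profile along the gravitational axis
#'
#' Evaluates the hazard ratios of each scenario at a grid of positions along
#' the gravitational axis, substituting the position's local threshold
#' ([local_pt()]) into the whole-lung formulas ([hr_drive()],
#' [hr_elastic()], clamped mode). Regional vulnerability enters only through
#' the threshold; airway pressures are applied uniformly to all open units.
#'
#' @param data a scenario data frame; the scenario `pt` column is used as
#'   the whole-lung average threshold unless `pt_average` is given.
#' @param posture `"supine"` (default) or `"prone"`; sets the default
#'   pleural-gradient span (supine 7.5, prone 3.0 cmH2O — illustrative
#'   defaults, override with `span`). Prone flattens the gradient, so the
#'   regional spread of vulnerability narrows.
#' @param span total pleural-pressure difference across the lung, cmH2O;
#'   overrides the posture default.
#' @param n_positions number of evenly spaced positions in \[0, 1\]
#'   (default 11).
#' @param pt_average optional whole-lung average threshold, cmH2O;
#'   defaults to each scenario's `pt`.
#' @param tol relative tolerance for scenario validation.
#' @return a long tibble of class `regional_profile`: one row per scenario
#'   x position with `position`, `pt_local`, `hr_drive_local`,
#'   `hr_elastic_local`, `posture`, `span`.
#' @examples
#' ventilation_scenarios(ps = 25, peep = 5, vt = 0.5, f = 20, pt = 20) |>
#'   regional_hazard(span = 6)
#' @export
regional_hazard <- function(data, posture = c("supine", "prone"), span = NULL,
                            n_positions = 11, pt_average = NULL, tol = 1e-9) {
  posture <- match.arg(posture)
  span <- span %||% unname(.POSTURE_SPANS[posture])
  if (span < 0) abort("span must be >= 0")
  if (n_positions < 2) abort("n_positions must be >= 2")
  sc <- as_scenarios(data, tol = tol)
  if (!is.null(pt_average)) sc$pt <- pt_average

  positions <- seq(0, 1, length.out = n_positions)
  out <- dplyr::cross_join(dplyr::mutate(sc, .row = dplyr::row_number()),
                           tibble::tibble(position = positions)) |>
    dplyr::mutate(
      pt_local = local_pt(.data$pt, span, .data$position),
      hr_drive_local = hr_drive(.data$ps, .data$peep, .data$pt_local,
                                policy = "clamp"),
      hr_elastic_local = hr_elastic(.data$ps, .data$peep, .data$pt_local,
                                    policy = "clamp"),
      posture = posture,
      span = span
    ) |>
    dplyr::arrange(.data$.row, .data$position) |>
    dplyr::select(-".row")
  class(out) <- c("regional_profile", class(out))
  out
}
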