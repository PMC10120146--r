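# ggplot2 views of the three result types.

#' Pressure-volume partition diagram for one scenario
#'
#' Draws the elastic P-V line of one scenario and shades the infra-threshold
#' ("safe") and supra-threshold ("hazardous") energy areas, for either the
#' drive accounting (tidal area only) or the all-inclusive elastic
#' accounting (PEEP block included).
#'
#' @param data a scenario data frame or [partition_energy()] result.
#' @param row which scenario row to draw (default 1).
#' @param which `"elastic"` or `"drive"` accounting.
#' @return a ggplot object.
#' @examples
#' sc <- ventilation_scenarios(ps = 25, peep = 5, vt = 0.5, f = 20, pt = 20)
#' plot_pv_partition(sc)
#' @export
plot_pv_partition <- function(data, row = 1, which = c("elastic", "drive")) {
  which <- match.arg(which)
  sc <- as_scenarios(tibble::as_tibble(data)[row, , drop = FALSE])
  base <- if (which == "elastic") 0 else sc$peep
  ptc <- min(max(sc$pt, sc$peep), sc$ps)
  vc <- sc$c * (ptc - sc$peep)  # volume at the threshold crossing

  poly <- function(vlo, vhi, lab) {
    tibble::tibble(
      volume = c(vlo, vhi, vhi, vlo),
      pressure = c(base, base, sc$peep + vhi / sc$c, sc$peep + vlo / sc$c),
      region = lab
    )
  }
  shade <- dplyr::bind_rows(poly(0, vc, "safe"), poly(vc, sc$vt, "hazardous"))
  line <- tibble::tibble(volume = c(0, sc$vt),
                         pressure = c(sc$peep, sc$ps))

  ggplot2::ggplot(shade, ggplot2::aes(x = .data$volume, y = .data$pressure)) +
    ggplot2::geom_polygon(ggplot2::aes(fill = .data$region), alpha = 0.55) +
    ggplot2::geom_line(data = line, linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = sc$pt, linetype = "dashed") +
    ggplot2::annotate("text", x = 0, y = sc$pt, hjust = 0, vjust = -0.4,
                      label = "P[t]", parse = TRUE) +
    ggplot2::scale_fill_manual(values = c(safe = "#4d9960", hazardous = "#c23b3b")) +
    ggplot2::labs(x = "inflated volume (L)",
                  y = expression(elastic~pressure~(cmH[2]*O)),
                  fill = NULL,
                  title = sprintf("%s energy partition: %s", which, sc$name)) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_pv_partition autoplot method for [partition_energy()]
#'   results.
#' @param object an `energy_partition` tibble.
#' @param ... passed to [plot_pv_partition()].
#' @method autoplot energy_partition
#' @export
autoplot.energy_partition <- function(object, ...) {
  plot_pv_partition(object, ...)
}

#' Plot a regional hazard profile
#'
#' Local hazard ratios against normalised gravitational position (0 =
#' dependent, 1 = non-dependent), one line per scenario and accounting.
#'
#' @param object a [regional_hazard()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot regional_profile
#' @export
autoplot.regional_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("hr_drive_local", "hr_elastic_local"),
                              names_to = "accounting", values_to = "hr")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$position, y = .data$hr,
                                     colour = .data$name,
                                     linetype = .data$accounting)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position (0 = dependent, 1 = non-dependent)",
                  y = "local hazard ratio", colour = NULL, linetype = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a simulated inflation cycle
#'
#' Facetted time courses of flow, volume, pressures (elastic and airway)
#' and cumulative elastic energy, with the threshold pressure marked.
#'
#' @param object a [simulate_cycle()] trace.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot cycle_trace
#' @export
autoplot.cycle_trace <- function(object, ...) {
  sc <- attr(object, "scenario")
  long <- tibble::as_tibble(object) |>
    dplyr::select("t", "flow", "volume", "p_elastic", "p_airway",
                  "cum_energy") |>
    tidyr::pivot_longer(-"t", names_to = "signal", values_to = "value") |>
    dplyr::mutate(signal = factor(.data$signal, levels = c(
      "flow", "volume", "p_elastic", "p_airway", "cum_energy")))
  thr <- tibble::tibble(signal = factor("p_elastic", levels = levels(long$signal)),
                        value = if (!is.null(sc)) sc$pt else NA_real_)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(data = thr, ggplot2::aes(yintercept = .data$value),
                        linetype = "dashed", na.rm = TRUE) +
    ggplot2::facet_wrap(~signal, scales = "free_y", ncol = 1,
                        strip.position = "left") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}
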