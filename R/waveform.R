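# Time-resolved single-compartment simulation of one passive inflation.
#
# Equation of motion (inspiration only, linear mechanics):
#   P_aw(t) = R * flow(t) + V(t)/C + PEEP
# The conserved (elastic) pressure is P_el(t) = V(t)/C + PEEP; the resistive
# component R*flow is dissipated and does not enter the elastic energy.
# Whatever the inspiratory flow waveform, the cumulative elastic energy
# integral(P_el dV) over the full breath equals 1/2 (Ps + PEEP) V_T, because
# P_el is a function of volume alone. The waveform does change the PACE of
# delivery (intracycle power) and the time per cycle spent above the
# threshold Pt.

#' Describe an inspiratory flow profile
#'
#' Builds a flow-profile object for [simulate_cycle()]. Built-in kinds:
#' `"constant"` (square flow `vt/ti`) and `"decelerating"` (linear ramp from
#' peak `2 vt/ti` down to zero at end-inspiration). A `"custom"` profile is
#' given as non-negative flow samples on `[0, ti]` and is rescaled so that
#' its integral equals the delivered volume `vt`.
#'
#' @param kind `"constant"`, `"decelerating"`, or `"custom"`.
#' @param ti inspiratory time, s (> 0).
#' @param vt delivered tidal volume, L (> 0).
#' @param time,flow for `kind = "custom"`: sample times in `[0, ti]`
#'   (increasing, spanning 0 to `ti`) and non-negative flow values (L/s).
#' @return an object of class `flow_profile`.
#' @examples
#' flow_profile("decelerating", ti = 1, vt = 0.5)
#' @export
flow_profile <- function(kind = c("constant", "decelerating", "custom"),
                         ti, vt, time = NULL, flow = NULL) {
  kind <- match.arg(kind)
  if (ti <= 0) abort("ti must be > 0")
  if (vt <= 0) abort("vt must be > 0")
  prof <- list(kind = kind, ti = ti, vt = vt)
  if (kind == "custom") {
    if (is.null(time) || is.null(flow) || length(time) != length(flow) ||
        length(time) < 2) {
      abort("custom profiles need matching time and flow vectors (length >= 2)")
    }
    if (any(flow < 0)) abort("flow must be non-negative during inspiration")
    if (is.unsorted(time, strictly = TRUE)) abort("time must be increasing")
    if (abs(time[1]) > 1e-12 || abs(time[length(time)] - ti) > 1e-9 * ti) {
      abort("custom time samples must span [0, ti]")
    }
    area <- pracma::trapz(time, flow)
    if (area <= 0) abort("custom profile delivers no volume")
    prof$time <- time
    prof$flow <- flow * vt / area  # renormalise so integral(flow) = vt
  }
  structure(prof, class = "flow_profile")
}

# Flow samples of a profile on an arbitrary time grid.
profile_flow <- function(profile, t) {
  switch(profile$kind,
    constant = rep(profile$vt / profile$ti, length(t)),
    decelerating = 2 * profile$vt / profile$ti * (1 - t / profile$ti),
    custom = approx(profile$time, profile$flow, xout = t, rule = 2)$y
  )
}

#' Simulate one passive inflation under a flow profile
#'
#' Integrates the single-compartment equation of motion on a uniform time
#' grid over the inspiratory phase, returning the time-resolved volume,
#' elastic and airway pressures, cumulative elastic energy, intracycle
#' elastic power `P_el * flow`, and the time spent above the scenario's
#' threshold pressure. Expiration is not modelled: the energy accounting is
#' inflation-only.
#'
#' @param data a single-scenario data frame (one row; see [as_scenarios()]).
#' @param profile a [flow_profile()]; its `vt` must match the scenario's.
#'   If `NULL`, a profile of the given `kind` is built from `ti` and the
#'   scenario tidal volume.
#' @param kind,ti used to build a default profile when `profile` is `NULL`.
#' @param r airway resistance, cmH2O·s/L (default 10). Affects only the
#'   resistive (airway) pressure, never the elastic energy.
#' @param n_steps number of uniform grid intervals (default 2000, minimum
#'   100). Cumulative energy uses the trapezoid rule in volume.
#' @return a tibble of class `cycle_trace` with columns `t`, `flow`,
#'   `volume`, `p_elastic`, `p_airway`, `cum_energy`, `power`, and
#'   attributes `scenario` (one-row tibble) and `time_above_pt` (s).
#' @examples
#' sc <- ventilation_scenarios(ps = 25, peep = 5, vt = 0.5, f = 20, pt = 20)
#' tr <- simulate_cycle(sc, kind = "constant", ti = 1)
#' attr(tr, "time_above_pt") # 0.25 s
#' @export
simulate_cycle <- function(data, profile = NULL,
                           kind = c("constant", "decelerating", "custom"),
                           ti = 1, r = 10, n_steps = 2000) {
  sc <- as_scenarios(data)
  if (nrow(sc) != 1) abort("simulate_cycle() takes a single scenario row")
  if (n_steps < 100) abort("n_steps must be >= 100")
  if (r < 0) abort("r must be >= 0")
  if (is.null(profile)) {
    kind <- match.arg(kind)
    profile <- flow_profile(kind, ti = ti, vt = sc$vt)
  }
  if (!inherits(profile, "flow_profile")) abort("profile must be a flow_profile")
  if (abs(profile$vt - sc$vt) > 1e-9 * sc$vt) {
    abort(sprintf("profile delivers %.6g L but the scenario tidal volume is %.6g L",
                  profile$vt, sc$vt))
  }

  t <- seq(0, profile$ti, length.out = n_steps + 1)
  flow <- profile_flow(profile, t)
  volume <- switch(profile$kind,
    # closed-form volumes for the built-in profiles
    constant = sc$vt * t / profile$ti,
    decelerating = sc$vt * (2 * t / profile$ti - (t / profile$ti)^2),
    custom = {
      v <- pracma::cumtrapz(t, flow)[, 1]
      # regridding perturbs the integral by O(h^2); rescale so the full
      # tidal volume is delivered exactly, preserving monotonicity
      v * sc$vt / v[length(v)]
    }
  )
  p_elastic <- volume / sc$c + sc$peep
  p_airway <- r * flow + p_elastic
  cum_energy <- pracma::cumtrapz(volume, p_elastic)[, 1]
  power <- p_elastic * flow

  out <- tibble::tibble(t = t, flow = flow, volume = volume,
                        p_elastic = p_elastic, p_airway = p_airway,
                        cum_energy = cum_energy, power = power)
  class(out) <- c("cycle_trace", class(out))
  attr(out, "scenario") <- sc
  attr(out, "time_above_pt") <- time_above_threshold(out, sc$pt)
  out
}

#' Time per cycle spent above a threshold elastic pressure
#'
#' Measure of the inspiratory time during which the elastic pressure of a
#' simulated cycle exceeds `pt`. Crossings are refined by linear
#' interpolation between grid points, so for the built-in profiles the value
#' converges quadratically with the grid.
#'
#' @param trace a [simulate_cycle()] result (or any data frame with `t` and
#'   `p_elastic` columns).
#' @param pt threshold pressure, cmH2O; defaults to the threshold of the
#'   scenario attached to the trace.
#' @return duration in seconds.
#' @examples
#' sc <- ventilation_scenarios(ps = 25, peep = 5, vt = 0.5, f = 20, pt = 20)
#' time_above_threshold(simulate_cycle(sc, kind = "constant", ti = 1), 20)
#' @export
time_above_threshold <- function(trace, pt = NULL) {
  if (is.null(pt)) {
    sc <- attr(trace, "scenario")
    if (is.null(sc)) abort("pt not given and the trace carries no scenario")
    pt <- sc$pt
  }
  t <- trace$t
  p <- trace$p_elastic
  above <- p > pt
  if (!any(above)) return(0)
  if (all(above)) return(t[length(t)] - t[1])
  total <- 0
  n <- length(t)
  # sum interval contributions, interpolating partial intervals linearly
  for (i in seq_len(n - 1)) {
    a <- above[i]; b <- above[i + 1]
    dt <- t[i + 1] - t[i]
    if (a && b) {
      total <- total + dt
    } else if (xor(a, b)) {
      frac <- (pt - p[i]) / (p[i + 1] - p[i])
      total <- total + if (b) (1 - frac) * dt else frac * dt
    }
  }
  total
}

#' Write a cycle trace to a tidy CSV file
#'
#' Columns: `t`, `flow`, `volume`, `p_elastic`, `p_airway`, `cum_energy`.
#'
#' @param trace a [simulate_cycle()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  readr::write_csv(
    dplyr::select(tibble::as_tibble(trace), "t", "flow", "volume",
                  "p_elastic", "p_airway", "cum_energy"),
    path)
  invisible(path)
}
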