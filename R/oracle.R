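# Independent numeric verification of the closed-form hazard ratios.
#
# The hazard ratio is a ratio of P-V areas along the linear elastic line
# V = C (P - PEEP). Compliance cancels in the ratio, so we integrate with
# C = 1: V runs from 0 to Ps - PEEP and P(V) = PEEP + V. The supra-threshold
# region starts at the volume where P(V) crosses Pt, located numerically by
# uniroot; each side is then integrated by the trapezoid rule on a uniform
# grid. This route never touches the closed-form hazard-ratio algebra.

#' Numeric pressure-volume area oracle for the hazard ratios
#'
#' Computes the supra-threshold fraction of per-cycle energy by direct
#' numeric integration of the P-V areas, independently of the closed forms
#' in [hr_drive()] and [hr_elastic()]. Intended for verification: the
#' closed forms must agree with this oracle to well below 1e-9.
#'
#' @param ps plateau pressure, cmH2O.
#' @param peep end-expiratory pressure, cmH2O.
#' @param pt threshold pressure, cmH2O (values outside `[peep, ps]` saturate
#'   the ratio at 1 / 0, matching the clamped geometry).
#' @param variant `"drive"` (integrand `P - PEEP`, the tidal area only) or
#'   `"elastic"` (integrand `P`, PEEP block included).
#' @param n_panels number of trapezoid panels per side (default 1e5,
#'   minimum 1000).
#' @return the supra-threshold energy fraction, a scalar in \[0, 1\].
#'   Vectorised over `ps`, `peep`, `pt`.
#' @examples
#' oracle_hr(25, 5, 20, "drive")   # ~0.4375
#' oracle_hr(25, 5, 20, "elastic") # ~0.375
#' @export
oracle_hr <- function(ps, peep, pt, variant = c("drive", "elastic"),
                      n_panels = 1e5) {
  variant <- match.arg(variant)
  if (n_panels < 1000) abort("n_panels must be >= 1000")
  check_pressures(ps, peep)
  n <- max(length(ps), length(peep), length(pt))
  ps <- rep_len(ps, n); peep <- rep_len(peep, n); pt <- rep_len(pt, n)
  vapply(seq_len(n), function(i) {
    oracle_hr_one(ps[i], peep[i], pt[i], variant, n_panels)
  }, numeric(1))
}

oracle_hr_one <- function(ps, peep, pt, variant, n_panels) {
  if (pt >= ps) return(0)
  if (pt <= peep) return(1)
  vmax <- ps - peep               # total volume with C = 1
  pfun <- function(v) peep + v    # linear elastic line
  g <- if (variant == "drive") function(v) pfun(v) - peep else pfun
  # volume at which the elastic line crosses the threshold
  vc <- uniroot(function(v) pfun(v) - pt, c(0, vmax), tol = 1e-14)$root
  supra <- trapz_on(g, vc, vmax, n_panels)
  total <- trapz_on(g, 0, vmax, n_panels)
  supra / total
}

# trapezoid rule on a uniform grid: h * (sum(y) - (y_first + y_last)/2)
trapz_on <- function(g, lo, hi, n_panels) {
  v <- seq.int(lo, hi, length.out = n_panels + 1)
  y <- g(v)
  (hi - lo) / n_panels * (sum(y) - 0.5 * (y[1] + y[length(y)]))
}
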