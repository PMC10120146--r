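# Scenario table: one row per passive ventilation pattern.
# Canonical columns (units): ps (cmH2O), peep (cmH2O), vt (L),
# c (L/cmH2O, optional - derivable), f (breaths/min), pt (cmH2O).
# All pressures are elastic airway pressures referenced to atmosphere;
# chest-wall elastance is deliberately ignored (single-compartment lung).

.SCENARIO_COLS <- c("ps", "peep", "vt", "c", "f", "pt")

#' Build a ventilation scenario table
#'
#' Constructs a tibble of passive ventilation scenarios from vectors of
#' ventilator settings and respiratory mechanics. Exactly one of `ps`
#' (plateau pressure) and `c` (compliance) may be omitted; the missing one
#' is derived from `ps = vt/c + peep`. If both are supplied they must be
#' mutually consistent.
#'
#' @param ps plateau pressure, cmH2O (static end-inspiratory elastic
#'   pressure). Optional if `c` is given.
#' @param peep positive end-expiratory pressure, cmH2O.
#' @param vt tidal volume, L.
#' @param c respiratory-system compliance, L/cmH2O. Optional if `ps` is given.
#' @param f ventilating frequency, breaths/min.
#' @param pt threshold elastic pressure partitioning safe from hazardous
#'   energy, cmH2O, referenced to atmosphere.
#' @param name optional scenario labels; defaults to `scenario_1`, ...
#' @return a validated scenario tibble (see [as_scenarios()]).
#' @examples
#' ventilation_scenarios(ps = 25, peep = 5, vt = 0.5, f = 20, pt = 20)
#' @export
ventilation_scenarios <- function(ps = NULL, peep, vt, c = NULL, f, pt,
                                  name = NULL) {
  n <- max(lengths(list(ps, peep, vt, c, f, pt)))
  out <- tibble::tibble(
    name = name %||% paste0("scenario_", seq_len(n)),
    ps = if (is.null(ps)) NA_real_ else as.numeric(ps),
    peep = as.numeric(peep),
    vt = as.numeric(vt),
    c = if (is.null(c)) NA_real_ else as.numeric(c),
    f = as.numeric(f),
    pt = as.numeric(pt)
  )
  as_scenarios(out)
}

# Per-row validation messages; NA_character_ where the row is valid.
# Used both by as_scenarios() (which stops) and run_report() (which collects).
scenario_row_errors <- function(data, tol = 1e-9) {
  need <- c("peep", "vt", "f", "pt")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("scenario table lacks required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!("ps" %in% names(data)) && !("c" %in% names(data))) {
    abort("scenario table must contain at least one of 'ps' and 'c'")
  }
  ps <- if ("ps" %in% names(data)) as.numeric(data$ps) else rep(NA_real_, nrow(data))
  cc <- if ("c" %in% names(data)) as.numeric(data$c) else rep(NA_real_, nrow(data))
  peep <- as.numeric(data$peep); vt <- as.numeric(data$vt)
  f <- as.numeric(data$f); pt <- as.numeric(data$pt)

  vapply(seq_len(nrow(data)), function(i) {
    msgs <- character()
    if (!is.finite(peep[i]) || peep[i] < 0) msgs <- c(msgs, "peep must be >= 0")
    if (!is.finite(vt[i]) || vt[i] <= 0) msgs <- c(msgs, "vt must be > 0")
    if (!is.finite(f[i]) || f[i] <= 0) msgs <- c(msgs, "f must be > 0")
    if (!is.finite(pt[i])) msgs <- c(msgs, "pt must be a finite pressure")
    has_ps <- is.finite(ps[i]); has_c <- is.finite(cc[i])
    if (!has_ps && !has_c) {
      msgs <- c(msgs, "one of ps or c is required")
    } else {
      if (has_c && cc[i] <= 0) msgs <- c(msgs, "c must be > 0")
      if (has_ps && has_c && cc[i] > 0 && is.finite(vt[i]) && vt[i] > 0 &&
          is.finite(peep[i])) {
        implied <- vt[i] / cc[i] + peep[i]
        if (abs(ps[i] - implied) > tol * max(1, abs(ps[i]))) {
          msgs <- c(msgs, sprintf(
            "inconsistent mechanics: ps = %.6g but vt/c + peep = %.6g",
            ps[i], implied))
        }
      }
      ps_eff <- if (has_ps) ps[i] else vt[i] / cc[i] + peep[i]
      if (is.finite(ps_eff) && is.finite(peep[i]) && ps_eff <= peep[i]) {
        msgs <- c(msgs, "ps must exceed peep (driving pressure must be > 0)")
      }
    }
    if (length(msgs) == 0) NA_character_ else paste(msgs, collapse = "; ")
  }, character(1))
}

#' Validate and complete a scenario table
#'
#' Checks the physical invariants of each scenario row (PEEP >= 0, V_T > 0,
#' f > 0, Ps > PEEP) and completes the mechanics: a missing plateau pressure
#' is derived as `ps = vt/c + peep`, a missing compliance as
#' `c = vt/(ps - peep)`. When both `ps` and `c` are present they must agree
#' to a relative tolerance of `tol`.
#'
#' @param data data frame with columns `peep`, `vt`, `f`, `pt` and at least
#'   one of `ps`, `c` (an optional `name` column is preserved).
#' @param tol relative tolerance for the `ps = vt/c + peep` consistency
#'   check (default 1e-9).
#' @return a tibble with all of `name, ps, peep, vt, c, f, pt` populated,
#'   plus the driving pressure `dp = ps - peep`.
#' @examples
#' df <- data.frame(peep = 5, vt = 0.5, c = 0.025, f = 20, pt = 20)
#' as_scenarios(df)
#' @export
as_scenarios <- function(data, tol = 1e-9) {
  errs <- scenario_row_errors(data, tol = tol)
  if (any(!is.na(errs))) {
    bad <- which(!is.na(errs))
    abort(paste0(
      "invalid scenario row(s):\n",
      paste(sprintf("  row %d: %s", head(bad, 5), errs[head(bad, 5)]),
            collapse = "\n"),
      if (length(bad) > 5) sprintf("\n  ... and %d more", length(bad) - 5) else ""
    ))
  }
  complete_scenarios(data)
}

# Fill derived columns without re-validating (rows already checked).
complete_scenarios <- function(data) {
  out <- tibble::as_tibble(data)
  if (!("name" %in% names(out))) {
    out <- dplyr::mutate(out, name = paste0("scenario_", dplyr::row_number()))
  }
  if (!("ps" %in% names(out))) out$ps <- NA_real_
  if (!("c" %in% names(out))) out$c <- NA_real_
  out <- dplyr::mutate(
    out,
    ps = ifelse(is.finite(.data$ps), .data$ps, .data$vt / .data$c + .data$peep),
    c = ifelse(is.finite(.data$c), .data$c,
               .data$vt / (.data$ps - .data$peep)),
    dp = .data$ps - .data$peep
  )
  dplyr::relocate(out, "name", "ps", "peep", "dp", "vt", "c", "f", "pt")
}

#' Plateau pressure implied by tidal volume, compliance and PEEP
#'
#' For a passive single-compartment system with linear compliance, the
#' end-inspiratory elastic (plateau) pressure is `Ps = V_T / C + PEEP`.
#'
#' @param vt tidal volume, L (> 0).
#' @param c compliance, L/cmH2O (> 0).
#' @param peep end-expiratory pressure, cmH2O (>= 0).
#' @return plateau pressure, cmH2O. Vectorised over its arguments.
#' @examples
#' plateau_from_mechanics(0.5, 0.025, 5) # 25 cmH2O
#' @export
plateau_from_mechanics <- function(vt, c, peep) {
  if (any(!is.finite(vt) | vt <= 0)) abort("vt must be finite and > 0")
  if (any(!is.finite(c) | c <= 0)) abort("c must be finite and > 0")
  if (any(!is.finite(peep) | peep < 0)) abort("peep must be finite and >= 0")
  vt / c + peep
}
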