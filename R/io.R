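# Scenario I/O, batch reports, seeded fixture generation.
#
# Scenario file schema (units: pressures cmH2O, volumes L, times s):
#   keys/columns: name?, ps, peep, vt, c?, f, pt, and optionally
#   ti, r, waveform, posture, gradient_span for the simulation/regional
#   layers. JSON files hold one flat object per scenario (a single object
#   or an array of objects); CSV files use the same names as headers.

#' Read a scenario batch from JSON or CSV
#'
#' JSON files may contain one flat scenario object or an array of them;
#' CSV files one scenario per row. Column/key names follow the scenario
#' schema (`name, ps, peep, vt, c, f, pt`, plus optional `ti, r, waveform,
#' posture, gradient_span`). The table is returned as read; validation
#' happens in the consuming computation ([partition_energy()],
#' [run_report()], ...).
#'
#' @param path file path; format inferred from the `.json` / `.csv`
#'   extension unless `format` is given.
#' @param format `"json"` or `"csv"`.
#' @return a tibble, one row per scenario.
#' @export
read_scenarios <- function(path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "json") {
    parsed <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    if (!is.data.frame(parsed)) parsed <- tibble::as_tibble(parsed)
    tibble::as_tibble(parsed)
  } else {
    readr::read_csv(path, show_col_types = FALSE)
  }
}

#' Generate a reproducible randomised scenario batch
#'
#' Draws `n` valid scenarios spanning the clinically plausible ranges
#' PEEP 0-15 cmH2O, DP 5-25 cmH2O, Pt uniform on \[PEEP, Ps\], V_T 0.2-0.8 L
#' and f 10-35 breaths/min. Compliance is derived as `vt/dp`. The same seed
#' always yields the identical batch; the caller's RNG state is untouched.
#'
#' @param seed integer seed.
#' @param n number of scenarios (> 0).
#' @return a validated scenario tibble (see [as_scenarios()]).
#' @examples
#' generate_fixtures(seed = 1, n = 3)
#' @export
generate_fixtures <- function(seed, n) {
  if (n <= 0) abort("n must be > 0")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  peep <- runif(n, 0, 15)
  dp <- runif(n, 5, 25)
  ps <- peep + dp
  pt <- peep + runif(n) * dp
  vt <- runif(n, 0.2, 0.8)
  f <- runif(n, 10, 35)
  as_scenarios(tibble::tibble(
    name = sprintf("fixture_%03d", seq_len(n)),
    ps = ps, peep = peep, vt = vt, f = f, pt = pt
  ))
}

#' Batch report: energy partition, optional targets, regional and waveform summaries
#'
#' Runs the full per-cycle accounting over a batch of scenarios. Invalid
#' rows never abort the batch: they are carried through with their
#' validation message in the `error` column and `NA` results. Output row
#' order follows the input.
#'
#' @param data a scenario data frame (one row per scenario; an optional
#'   `name` column is preserved).
#' @param desired_ratio if non-`NULL`, also inverse-solve targets for this
#'   ratio via [prescribe_targets()] (columns `target_dp`, `target_ps`,
#'   `target_vt`, `achieved_ratio`, `held_fixed`).
#' @param variant,mode passed to [prescribe_targets()].
#' @param regional if `TRUE`, append regional hazard summaries
#'   (`hr_drive_nondep`, `hr_drive_dep`, `hr_drive_spread` at the given
#'   `posture`/`span`) from [regional_hazard()].
#' @param posture,span,n_positions regional parameters, see
#'   [regional_hazard()].
#' @param policy Pt-out-of-range policy, `"clamp"` or `"strict"`.
#' @param tol relative tolerance for the mechanics consistency check.
#' @return a tibble with one row per input scenario and an `error` column
#'   (`NA` for valid rows).
#' @examples
#' run_report(generate_fixtures(seed = 1, n = 3))
#' @export
run_report <- function(data, desired_ratio = NULL,
                       variant = c("drive", "elastic"),
                       mode = c("hazard", "safe"),
                       regional = FALSE, posture = "supine", span = NULL,
                       n_positions = 11,
                       policy = c("clamp", "strict"), tol = 1e-9) {
  variant <- match.arg(variant)
  mode <- match.arg(mode)
  policy <- match.arg(policy)
  data <- tibble::as_tibble(data)
  if (nrow(data) == 0) {
    return(tibble::tibble(name = character(), error = character()))
  }
  if (!("name" %in% names(data))) {
    data$name <- paste0("scenario_", seq_len(nrow(data)))
  }
  errs <- scenario_row_errors(data, tol = tol)
  ok <- is.na(errs)
  pieces <- purrr::map(seq_len(nrow(data)), function(i) {
    row <- data[i, , drop = FALSE]
    if (!ok[i]) {
      return(tibble::tibble(name = as.character(row$name), error = errs[i]))
    }
    res <- partition_energy(row, policy = policy, tol = tol)
    res <- tibble::as_tibble(res)
    if (!is.null(desired_ratio)) {
      tg <- prescribe_targets(row, desired_ratio, variant = variant,
                              mode = mode, tol = tol)
      res <- dplyr::bind_cols(res, dplyr::select(
        tibble::as_tibble(tg), "requested_ratio", "target_dp", "target_ps",
        "target_vt", "achieved_ratio", "held_fixed"))
    }
    if (isTRUE(regional)) {
      rp <- regional_hazard(row, posture = posture, span = span,
                            n_positions = n_positions, tol = tol)
      res$hr_drive_nondep <- rp$hr_drive_local[which.max(rp$position)]
      res$hr_drive_dep <- rp$hr_drive_local[which.min(rp$position)]
      res$hr_drive_spread <- max(rp$hr_drive_local) - min(rp$hr_drive_local)
    }
    res$error <- NA_character_
    res
  })
  report <- dplyr::bind_rows(pieces)
  n_bad <- sum(!ok)
  message(sprintf("run_report: %d scenario(s), %d valid, %d with errors",
                  nrow(data), sum(ok), n_bad))
  report
}

#' Write a batch report to TSV or JSON
#'
#' TSV preserves the stable column order of [run_report()]; JSON writes an
#' array of flat row objects.
#'
#' @param report a [run_report()] tibble.
#' @param path output path; format inferred from the extension unless given.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  }
  if (format == "json") {
    jsonlite::write_json(report, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  } else {
    readr::write_tsv(report, path, na = "")
  }
  invisible(path)
}
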