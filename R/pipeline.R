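# Run orchestration: configuration, scenario parsing, end-to-end execution
# with validated inputs, written output tables and a machine-readable
# manifest.

#' Parse a scenario string
#'
#' Accepts `"baseline"`, `"proportional:<r>"` (e.g. `"proportional:0.10"`)
#' and `"quintile:<k>"` (k-th quintile from the bottom; `"quintile:1"` is the
#' first-quintile counterfactual).
#'
#' @param x Scenario string.
#' @return A [scenarios] object.
#' @export
parse_scenario <- function(x) {
  parts <- strsplit(x, ":", fixed = TRUE)[[1]]
  switch(parts[1],
    baseline = scenario_baseline(),
    proportional = {
      if (length(parts) != 2L) stop("use proportional:<r>", call. = FALSE)
      scenario_reduction(as.numeric(parts[2]))
    },
    quintile = {
      k <- if (length(parts) == 2L) as.numeric(parts[2]) else 1
      scenario_quintile(q = 0.2 * k)
    },
    stop("unknown scenario syntax: ", x, call. = FALSE))
}

#' Run configuration
#'
#' @param exposure_file,events_file Paths to the stratified input tables.
#' @param rr_file Optional path to an RR table; defaults to the pooled
#'   relative risks of [default_rr_specs()].
#' @param scenarios Character vector of scenario strings (see
#'   [parse_scenario()]) or a list of [scenarios] objects.
#' @param grid_step,m PIF integration controls.
#' @param mc An [mc_config()] or `NULL` to skip the Monte Carlo stage.
#' @param sensitivity Named list of [sensitivity_scenario()] objects or
#'   `NULL` to skip the sensitivity stage.
#' @param out_dir Output directory.
#' @return An object of class `run_config`.
#' @export
run_config <- function(exposure_file, events_file, rr_file = NULL,
                       scenarios = c("proportional:0.10", "proportional:0.20",
                                     "proportional:0.50", "quintile:1"),
                       grid_step = 0.1, m = 100, mc = mc_config(),
                       sensitivity = default_sensitivity_scenarios(),
                       out_dir = "upf-cra-output") {
  for (f in c(exposure_file, events_file, rr_file))
    if (!is.null(f) && !file.exists(f))
      stop("input file not found: ", f, call. = FALSE)
  if (is.character(scenarios))
    scenarios <- lapply(scenarios, parse_scenario)
  if (!length(scenarios)) stop("scenario list must be non-empty", call. = FALSE)
  if (is.null(names(scenarios)))
    names(scenarios) <- vapply(scenarios, `[[`, "", "label")
  structure(list(exposure_file = exposure_file, events_file = events_file,
                 rr_file = rr_file, scenarios = scenarios,
                 grid_step = grid_step, m = m, mc = mc,
                 sensitivity = sensitivity, out_dir = out_dir),
            class = "run_config")
}

#' Execute the full comparative-risk-assessment pipeline
#'
#' Load -> validate -> baseline and scenario PIFs -> burden accounting ->
#' Monte Carlo -> sensitivity.  Validation failures abort before anything is
#' written; outputs (`cells.csv`, `totals.csv`, `mc.csv`, `sensitivity.csv`,
#' `manifest.json`) are written atomically at the end, so no partial bundle
#' appears on error.  Each stage logs a row count via [message()].
#'
#' @param config A [run_config()].
#' @param quiet Suppress stage messages.
#' @return Invisibly, a list with `cells`, `totals`, `mc`, `sensitivity`,
#'   `manifest` and the output paths.
#' @export
run_model <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)

  exposure <- read_exposure_table(config$exposure_file)
  events <- read_event_table(config$events_file)
  rr_specs <- if (is.null(config$rr_file)) default_rr_specs()
              else read_rr_table(config$rr_file)
  say("loaded ", nrow(exposure), " exposure strata, ", nrow(events),
      " event rows, ", length(rr_specs), " RR specs")

  cells <- compute_burden(exposure, events, rr_specs, config$scenarios,
                          config$grid_step, config$m)
  totals <- aggregate_burden(cells)
  say("computed ", nrow(cells), " burden cells, ", nrow(totals),
      " aggregate rows")

  mc_summary <- NULL
  if (!is.null(config$mc)) {
    mc_summary <- run_monte_carlo(exposure, events, rr_specs,
                                  config$scenarios, config$mc,
                                  config$grid_step, config$m)$summary
    say("Monte Carlo: ", config$mc$n_draws, " draws, seed ", config$mc$seed)
  }
  sens <- NULL
  if (!is.null(config$sensitivity) && length(config$sensitivity)) {
    sens <- run_sensitivity(exposure, events, rr_specs, config$sensitivity,
                            config$grid_step, config$m)
    say("sensitivity: ", length(config$sensitivity), " scenarios")
  }

  manifest <- list(
    package = "upfburden",
    version = as.character(packageVersion("upfburden")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    inputs = list(exposure = config$exposure_file,
                  events = config$events_file,
                  rr = if (is.null(config$rr_file)) "default pooled RRs"
                       else config$rr_file),
    scenarios = names(config$scenarios),
    grid_step = config$grid_step, m = config$m,
    mc = if (is.null(config$mc)) NULL
         else config$mc[c("n_draws", "seed", "perturb")])

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(cells = file.path(config$out_dir, "cells.csv"),
             totals = file.path(config$out_dir, "totals.csv"))
  write.csv(cells, paths[["cells"]], row.names = FALSE)
  tot_out <- totals
  tot_out$averted_rounded <- report_rounding(tot_out$averted)
  write.csv(tot_out, paths[["totals"]], row.names = FALSE)
  if (!is.null(mc_summary)) {
    paths[["mc"]] <- file.path(config$out_dir, "mc.csv")
    mc_out <- mc_summary
    for (cn in c("median", "ui_low", "ui_high"))
      mc_out[[paste0(cn, "_rounded")]] <- report_rounding(mc_out[[cn]])
    write.csv(mc_out, paths[["mc"]], row.names = FALSE)
  }
  if (!is.null(sens)) {
    paths[["sensitivity"]] <- file.path(config$out_dir, "sensitivity.csv")
    write.csv(sens, paths[["sensitivity"]], row.names = FALSE)
  }
  paths[["manifest"]] <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE)
  say("wrote ", length(paths), " files to ", config$out_dir)

  invisible(list(cells = cells, totals = totals, mc = mc_summary,
                 sensitivity = sens, manifest = manifest, paths = paths))
}
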