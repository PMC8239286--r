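# Report writers: each command-style function runs one of the four analyses
# from a cea_inputs object (or a config path) and writes CSV tables plus a
# JSON run manifest into an output directory. All outputs are pure functions
# of (inputs, flags, seed); re-running reproduces the tables byte-for-byte
# (the manifest carries a timestamp).

.resolve_inputs <- function(inputs, horizon_months = NULL, wtp = NULL, discount = NULL) {
  if (is.character(inputs)) inputs <- read_cea_config(inputs)
  stopifnot(inherits(inputs, "cea_inputs"))
  s <- inputs$settings
  inputs$settings <- econ_settings(
    annual_discount_rate = discount %||% s$annual_discount_rate,
    horizon_months = horizon_months %||% s$horizon_months,
    wtp = wtp %||% s$wtp,
    cost_scaling_mode = s$cost_scaling_mode)
  inputs
}

.write_manifest <- function(out_dir, command, config = NA, seed = NA,
                            extra = list()) {
  manifest <- c(list(command = command,
                     config = config,
                     seed = seed,
                     tool = "pscea",
                     version = as.character(utils::packageVersion("pscea")),
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
                extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

.prep_dir <- function(out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  out_dir
}

#' Run the base-case analysis and write its report files
#'
#' Writes `arm_results.csv` (per-arm totals and cost breakdown),
#' `comparison.csv` (two-arm table with incremental cost/effect, NMB and
#' ICER), per-arm occupancy traces and `manifest.json`.
#'
#' @param inputs A [cea_inputs()] object or the path to a YAML config file.
#' @param out_dir Output directory (created if missing).
#' @param horizon_months,wtp,discount Optional overrides of the configured
#'   settings.
#' @return The `base_case_result`, invisibly.
#' @export
report_base_case <- function(inputs, out_dir, horizon_months = NULL, wtp = NULL,
                             discount = NULL) {
  config <- if (is.character(inputs)) inputs else NA
  inputs <- .resolve_inputs(inputs, horizon_months, wtp, discount)
  .prep_dir(out_dir)
  bc <- run_base_case(inputs)
  arm_rows <- do.call(rbind, lapply(list(bc$intervention, bc$comparator), function(a) {
    data.frame(arm = a$name, total_cost = a$total_cost, total_qaly = a$total_qaly,
               cost_state = a$cost_breakdown[["state"]],
               cost_onetime = a$cost_breakdown[["onetime"]],
               cost_end_of_life = a$cost_breakdown[["end_of_life"]])
  }))
  utils::write.csv(arm_rows, file.path(out_dir, "arm_results.csv"), row.names = FALSE)
  cea_table(bc, file.path(out_dir, "comparison.csv"))
  for (a in list(bc$intervention, bc$comparator)) {
    write_trace_csv(a, inputs$costs, inputs$utilities, inputs$settings,
                    file.path(out_dir, sprintf("trace_%s.csv", a$name)))
  }
  .write_manifest(out_dir, "base-case", config = config,
                  extra = list(horizon_months = inputs$settings$horizon_months,
                               wtp = inputs$settings$wtp,
                               discount = inputs$settings$annual_discount_rate))
  invisible(bc)
}

#' Run the one-way DSA and write the tornado table
#'
#' @inheritParams report_base_case
#' @param ranges [param_range()] rows; defaults to [sabr_comet_dsa_ranges()]
#'   on the resolved inputs.
#' @param metric Tornado metric, `"icer"` or `"inmb"`.
#' @return The `tornado` data frame, invisibly.
#' @export
report_dsa <- function(inputs, out_dir, ranges = NULL, metric = "icer",
                       horizon_months = NULL, wtp = NULL, discount = NULL) {
  config <- if (is.character(inputs)) inputs else NA
  inputs <- .resolve_inputs(inputs, horizon_months, wtp, discount)
  .prep_dir(out_dir)
  if (is.null(ranges)) ranges <- sabr_comet_dsa_ranges(inputs)
  tor <- one_way_dsa(inputs, ranges, metric = metric)
  utils::write.csv(tor, file.path(out_dir, "tornado.csv"), row.names = FALSE)
  .write_manifest(out_dir, "dsa", config = config,
                  extra = list(metric = metric, n_parameters = nrow(tor),
                               horizon_months = inputs$settings$horizon_months,
                               wtp = inputs$settings$wtp))
  invisible(tor)
}

#' Run the SABR unit-cost threshold search and write its report
#'
#' @inheritParams report_base_case
#' @return The `threshold_result`, invisibly.
#' @export
report_threshold <- function(inputs, out_dir, horizon_months = NULL, wtp = NULL,
                             discount = NULL) {
  config <- if (is.character(inputs)) inputs else NA
  inputs <- .resolve_inputs(inputs, horizon_months, wtp, discount)
  .prep_dir(out_dir)
  thr <- threshold_search(inputs)
  jsonlite::write_json(unclass(thr), file.path(out_dir, "threshold.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  .write_manifest(out_dir, "threshold", config = config,
                  extra = list(horizon_months = inputs$settings$horizon_months,
                               wtp = inputs$settings$wtp))
  invisible(thr)
}

#' Run the PSA and write iteration-level, CEAC and summary tables
#'
#' Writes `psa_iterations.csv` (one row per Monte Carlo draw), `ceac.csv`
#' (acceptability over a WTP grid), `psa_summary.csv` and `manifest.json`.
#'
#' @inheritParams report_base_case
#' @param n Number of iterations.
#' @param seed RNG seed (recorded in the manifest and summary).
#' @return The `psa_result`, invisibly.
#' @export
report_psa <- function(inputs, out_dir, n = 10000, seed = 1,
                       horizon_months = NULL, wtp = NULL, discount = NULL) {
  config <- if (is.character(inputs)) inputs else NA
  inputs <- .resolve_inputs(inputs, horizon_months, wtp, discount)
  .prep_dir(out_dir)
  psa <- run_psa(inputs, n = n, seed = seed)
  utils::write.csv(psa$iterations, file.path(out_dir, "psa_iterations.csv"),
                   row.names = FALSE)
  utils::write.csv(ceac(psa), file.path(out_dir, "ceac.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(psa$summary[c("n", "wtp", "acceptability_pct",
                                               "dominant_pct", "mean_delta_cost",
                                               "mean_delta_effect", "icer_of_means")]),
                   file.path(out_dir, "psa_summary.csv"), row.names = FALSE)
  .write_manifest(out_dir, "psa", config = config, seed = seed,
                  extra = list(n = n, horizon_months = inputs$settings$horizon_months,
                               wtp = inputs$settings$wtp))
  invisible(psa)
}

#' Generate and write the synthetic pooled reference curve
#'
#' @param out_dir Output directory.
#' @param horizon_years Support of the generated curve.
#' @return The reference [survival_curve()], invisibly.
#' @export
report_reference <- function(out_dir, horizon_years = 20) {
  .prep_dir(out_dir)
  ref <- generate_reference_survival(synthetic_reference_specs(),
                                     horizon_years = horizon_years)
  write_survival_curve_csv(ref, file.path(out_dir, "reference_curve.csv"))
  .write_manifest(out_dir, "gen-reference",
                  extra = list(horizon_years = horizon_years,
                               note = paste("synthetic stand-in mixture; published",
                                            "long-term results used registry data")))
  invisible(ref)
}
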