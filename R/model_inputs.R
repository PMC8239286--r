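#' Annual and one-time health-care cost inputs
#'
#' @param annual_omd_cost Annual cost of care in the oligometastatic (OMD,
#'   progression-free) state, USD/year.
#' @param annual_pmd_cost Annual cost of care in the polymetastatic (PMD,
#'   progressed) state, USD/year.
#' @param end_of_life_cost One-time cost attached to the death event (care in
#'   the last 180 days), USD.
#' @param palliative_rt_unit_cost Cost of one course of palliative
#'   radiotherapy, USD.
#' @param sabr_unit_cost Cost of one SABR treatment, USD.
#' @return An object of class `state_costs`.
#' @export
state_costs <- function(annual_omd_cost, annual_pmd_cost, end_of_life_cost,
                        palliative_rt_unit_cost, sabr_unit_cost) {
  x <- structure(list(annual_omd_cost = as.numeric(annual_omd_cost),
                      annual_pmd_cost = as.numeric(annual_pmd_cost),
                      end_of_life_cost = as.numeric(end_of_life_cost),
                      palliative_rt_unit_cost = as.numeric(palliative_rt_unit_cost),
                      sabr_unit_cost = as.numeric(sabr_unit_cost)),
                 class = "state_costs")
  bad <- names(x)[vapply(x, function(v) length(v) != 1 || is.na(v) || v < 0, TRUE)]
  if (length(bad)) stop("state_costs: negative or missing value(s): ", paste(bad, collapse = ", "))
  x
}

#' Health-state utility weights
#'
#' Utility weights on the 0-1 dead/full-health scale for the oligometastatic
#' and polymetastatic states. If the ordering `u_pmd <= u_omd` is violated the
#' constructor warns (a progressed state should not be valued above the
#' progression-free state) but does not fail, so users can explore
#' unconventional configurations.
#'
#' @param u_omd,u_pmd Utility weights in `[0, 1]`.
#' @return An object of class `health_utilities`.
#' @export
health_utilities <- function(u_omd, u_pmd) {
  u_omd <- as.numeric(u_omd); u_pmd <- as.numeric(u_pmd)
  if (u_omd < 0 || u_omd > 1 || u_pmd < 0 || u_pmd > 1) {
    stop("health_utilities: utilities must lie in [0, 1]")
  }
  if (u_pmd > u_omd) {
    warning("health_utilities: u_pmd > u_omd; progressed state valued above progression-free")
  }
  structure(list(u_omd = u_omd, u_pmd = u_pmd), class = "health_utilities")
}

#' Specification of one strategy arm
#'
#' Bundles everything specific to a strategy arm: its OS and PFS curves, the
#' systemic-therapy fraction that scales ongoing state costs, one-time
#' adverse-event cost and disutility (applied at the start of the simulation;
#' the disutility is stored as a positive magnitude and subtracted once), and
#' the salvage-treatment head-counts whose expected per-patient cost is also
#' charged at the start.
#'
#' @param name Arm label (e.g. `"SABR"`, `"SC"`).
#' @param os,pfs [survival_curve()] objects for overall and progression-free
#'   survival.
#' @param arm_size Number of patients in the arm (denominator for salvage
#'   head-counts).
#' @param systemic_therapy_fraction Fraction of the arm receiving systemic
#'   therapy, in `[0, 1]`.
#' @param ae_onetime_cost One-time adverse-event treatment cost, USD.
#' @param ae_onetime_disutility One-time adverse-event QALY decrement
#'   (positive magnitude).
#' @param salvage_rt_count Patients receiving salvage palliative radiotherapy.
#' @param salvage_sabr_count Patients receiving salvage SABR.
#' @param receives_primary_sabr Whether the arm receives the primary SABR
#'   course (its unit cost charged once at the start).
#' @return An object of class `arm_spec`.
#' @export
arm_spec <- function(name, os, pfs, arm_size, systemic_therapy_fraction,
                     ae_onetime_cost, ae_onetime_disutility,
                     salvage_rt_count, salvage_sabr_count,
                     receives_primary_sabr) {
  stopifnot(inherits(os, "survival_curve"), inherits(pfs, "survival_curve"))
  arm_size <- as.numeric(arm_size)
  if (length(arm_size) != 1 || arm_size <= 0 || arm_size != round(arm_size)) {
    stop("arm_spec: arm_size must be a positive integer")
  }
  f <- as.numeric(systemic_therapy_fraction)
  if (f < 0 || f > 1) stop("arm_spec: systemic_therapy_fraction must lie in [0, 1]")
  if (salvage_rt_count < 0 || salvage_sabr_count < 0 ||
      salvage_rt_count > arm_size || salvage_sabr_count > arm_size) {
    stop("arm_spec: salvage counts must lie in [0, arm_size]")
  }
  if (ae_onetime_cost < 0) stop("arm_spec: ae_onetime_cost must be non-negative")
  if (ae_onetime_disutility < 0) {
    stop("arm_spec: ae_onetime_disutility is a positive magnitude; got a negative value")
  }
  structure(list(name = as.character(name),
                 os = os, pfs = pfs,
                 arm_size = arm_size,
                 systemic_therapy_fraction = f,
                 ae_onetime_cost = as.numeric(ae_onetime_cost),
                 ae_onetime_disutility = as.numeric(ae_onetime_disutility),
                 salvage_rt_count = as.numeric(salvage_rt_count),
                 salvage_sabr_count = as.numeric(salvage_sabr_count),
                 receives_primary_sabr = isTRUE(receives_primary_sabr)),
            class = "arm_spec")
}

#' Economic settings of the simulation
#'
#' @param annual_discount_rate Annual discount rate applied to costs and
#'   QALYs (default 0.03).
#' @param horizon_months Simulation horizon in monthly cycles (72 for the
#'   trial duration, 192 for the long-term analysis).
#' @param wtp Willingness-to-pay threshold, USD per QALY (default 100,000).
#' @param cycle_length_months Cycle length; fixed at 1 month.
#' @param cost_scaling_mode `"systemic_fraction"` (annual state costs are
#'   multiplied by the arm's systemic-therapy fraction) or `"none"`.
#' @return An object of class `econ_settings`.
#' @export
econ_settings <- function(annual_discount_rate = 0.03, horizon_months = 72,
                          wtp = 1e5, cycle_length_months = 1,
                          cost_scaling_mode = c("systemic_fraction", "none")) {
  cost_scaling_mode <- match.arg(cost_scaling_mode)
  if (annual_discount_rate < 0) stop("econ_settings: discount rate must be >= 0")
  if (cycle_length_months != 1) stop("econ_settings: cycle length is fixed at 1 month")
  if (horizon_months <= 0 || horizon_months %% cycle_length_months != 0) {
    stop("econ_settings: horizon must be a positive multiple of the cycle length")
  }
  if (wtp < 0) stop("econ_settings: wtp must be >= 0")
  structure(list(annual_discount_rate = as.numeric(annual_discount_rate),
                 horizon_months = as.integer(horizon_months),
                 wtp = as.numeric(wtp),
                 cycle_length_months = 1,
                 cost_scaling_mode = cost_scaling_mode),
            class = "econ_settings")
}

#' Complete model input set
#'
#' @param intervention,comparator [arm_spec()] objects; the intervention is
#'   compared against the comparator in all incremental outputs.
#' @param costs A [state_costs()] object.
#' @param utilities A [health_utilities()] object.
#' @param settings An [econ_settings()] object.
#' @return An object of class `cea_inputs`.
#' @export
cea_inputs <- function(intervention, comparator, costs, utilities, settings) {
  stopifnot(inherits(intervention, "arm_spec"), inherits(comparator, "arm_spec"),
            inherits(costs, "state_costs"), inherits(utilities, "health_utilities"),
            inherits(settings, "econ_settings"))
  structure(list(intervention = intervention, comparator = comparator,
                 costs = costs, utilities = utilities, settings = settings),
            class = "cea_inputs")
}

#' @export
print.cea_inputs <- function(x, ...) {
  cat(sprintf("<cea_inputs: %s vs %s, horizon %d months, discount %.1f%%, WTP $%s/QALY>\n",
              x$intervention$name, x$comparator$name, x$settings$horizon_months,
              100 * x$settings$annual_discount_rate,
              format(x$settings$wtp, big.mark = ",", scientific = FALSE)))
  invisible(x)
}

#' Published SABR-COMET model inputs
#'
#' The complete input set of the SABR-versus-standard-care cost-effectiveness
#' model: annual OS/PFS anchors per arm from the SABR-COMET trial, annual
#' state costs, one-time costs, utilities, adverse-event burden and economic
#' settings (1-month cycles, 3% annual discount, $100,000/QALY
#' willingness-to-pay, 72-month trial-duration horizon). Arm sizes (66 SABR,
#' 33 standard care) are the trial's randomized group sizes.
#'
#' @param horizon_months Simulation horizon; defaults to the 72-month trial
#'   duration.
#' @return A [cea_inputs()] object with the SABR arm as intervention.
#' @export
#' @examples
#' inputs <- sabr_comet_inputs()
#' inputs$utilities$u_omd
sabr_comet_inputs <- function(horizon_months = 72) {
  yrs <- 0:6
  os_sabr <- survival_curve(yrs, c(1, 0.88, 0.69, 0.62, 0.52, 0.42, 0.42), "OS SABR")
  pfs_sabr <- survival_curve(yrs, c(1, 0.50, 0.38, 0.30, 0.21, 0.18, 0.18), "PFS SABR")
  os_sc <- survival_curve(yrs, c(1, 0.88, 0.58, 0.38, 0.18, 0.18, 0.18), "OS SC")
  pfs_sc <- survival_curve(yrs, c(1, 0.19, 0.13, 0.07, 0.04, 0.00, 0.00), "PFS SC")
  cea_inputs(
    intervention = arm_spec(
      name = "SABR", os = os_sabr, pfs = pfs_sabr, arm_size = 66,
      systemic_therapy_fraction = 0.55,
      ae_onetime_cost = 1443, ae_onetime_disutility = 0.002,
      salvage_rt_count = 16, salvage_sabr_count = 9,
      receives_primary_sabr = TRUE),
    comparator = arm_spec(
      name = "SC", os = os_sc, pfs = pfs_sc, arm_size = 33,
      systemic_therapy_fraction = 0.636,
      ae_onetime_cost = 997, ae_onetime_disutility = 0.0008,
      salvage_rt_count = 23, salvage_sabr_count = 0,
      receives_primary_sabr = FALSE),
    costs = state_costs(annual_omd_cost = 97440, annual_pmd_cost = 189840,
                        end_of_life_cost = 19174, palliative_rt_unit_cost = 11070,
                        sabr_unit_cost = 11700),
    utilities = health_utilities(u_omd = 0.82, u_pmd = 0.59),
    settings = econ_settings(annual_discount_rate = 0.03,
                             horizon_months = horizon_months, wtp = 1e5)
  )
}

# ---- configuration file I/O (YAML) -----------------------------------------

.arm_keys <- c("name", "arm_size", "systemic_therapy_fraction", "ae_onetime_cost",
               "ae_onetime_disutility", "salvage_rt_count", "salvage_sabr_count",
               "receives_primary_sabr", "os", "pfs")
.cost_keys <- c("annual_omd_cost", "annual_pmd_cost", "end_of_life_cost",
                "palliative_rt_unit_cost", "sabr_unit_cost")
.settings_keys <- c("annual_discount_rate", "horizon_months", "wtp",
                    "cycle_length_months", "cost_scaling_mode")

.check_keys <- function(x, allowed, required, section) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown)) {
    stop(sprintf("config: unknown key(s) in %s: %s", section,
                 paste(unknown, collapse = ", ")))
  }
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    stop(sprintf("config: missing field(s) in %s: %s", section,
                 paste(missing, collapse = ", ")))
  }
}

.curve_from_config <- function(x, section) {
  .check_keys(x, c("time_years", "survival"), c("time_years", "survival"), section)
  tryCatch(survival_curve(unlist(x$time_years), unlist(x$survival), name = section),
           error = function(e) stop(sprintf("config: %s", conditionMessage(e)), call. = FALSE))
}

.arm_from_config <- function(x, section) {
  .check_keys(x, .arm_keys, .arm_keys, section)
  arm_spec(name = x$name,
           os = .curve_from_config(x$os, paste0(section, "$os")),
           pfs = .curve_from_config(x$pfs, paste0(section, "$pfs")),
           arm_size = x$arm_size,
           systemic_therapy_fraction = x$systemic_therapy_fraction,
           ae_onetime_cost = x$ae_onetime_cost,
           ae_onetime_disutility = x$ae_onetime_disutility,
           salvage_rt_count = x$salvage_rt_count,
           salvage_sabr_count = x$salvage_sabr_count,
           receives_primary_sabr = x$receives_primary_sabr)
}

#' Read and write model configurations
#'
#' The configuration is a YAML file mirroring the model's input tables:
#' top-level sections `intervention`, `comparator`, `state_costs`, `utilities`
#' and `settings`, with survival curves as `{time_years: [...], survival:
#' [...]}` blocks. Unknown keys are rejected with a message naming the key;
#' missing fields raise a validation error listing them. An omitted `wtp`
#' defaults to $100,000/QALY and an omitted discount rate to 3%/year.
#'
#' @param path Path to a YAML configuration file.
#' @param inputs A [cea_inputs()] object (for writing).
#' @return `read_cea_config()` returns a [cea_inputs()] object;
#'   `write_cea_config()` returns `path` invisibly.
#' @seealso [sabr_comet_inputs()] for the bundled published input set.
#' @export
read_cea_config <- function(path) {
  if (!file.exists(path)) stop("read_cea_config: file not found: ", path)
  cfg <- yaml::read_yaml(path)
  .check_keys(cfg, c("intervention", "comparator", "state_costs", "utilities", "settings"),
              c("intervention", "comparator", "state_costs", "utilities"), "top level")
  cc <- cfg$state_costs
  .check_keys(cc, .cost_keys, .cost_keys, "state_costs")
  uu <- cfg$utilities
  .check_keys(uu, c("u_omd", "u_pmd"), c("u_omd", "u_pmd"), "utilities")
  ss <- if (is.null(cfg$settings)) list() else cfg$settings
  .check_keys(ss, .settings_keys, character(0), "settings")
  settings <- econ_settings(
    annual_discount_rate = ss$annual_discount_rate %||% 0.03,
    horizon_months = ss$horizon_months %||% 72,
    wtp = ss$wtp %||% 1e5,
    cycle_length_months = ss$cycle_length_months %||% 1,
    cost_scaling_mode = ss$cost_scaling_mode %||% "systemic_fraction")
  cea_inputs(
    intervention = .arm_from_config(cfg$intervention, "intervention"),
    comparator = .arm_from_config(cfg$comparator, "comparator"),
    costs = do.call(state_costs, cc[.cost_keys]),
    utilities = health_utilities(uu$u_omd, uu$u_pmd),
    settings = settings)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.arm_to_config <- function(a) {
  list(name = a$name, arm_size = a$arm_size,
       systemic_therapy_fraction = a$systemic_therapy_fraction,
       ae_onetime_cost = a$ae_onetime_cost,
       ae_onetime_disutility = a$ae_onetime_disutility,
       salvage_rt_count = a$salvage_rt_count,
       salvage_sabr_count = a$salvage_sabr_count,
       receives_primary_sabr = a$receives_primary_sabr,
       os = list(time_years = a$os$time, survival = a$os$survival),
       pfs = list(time_years = a$pfs$time, survival = a$pfs$survival))
}

#' @rdname read_cea_config
#' @export
write_cea_config <- function(inputs, path) {
  stopifnot(inherits(inputs, "cea_inputs"))
  cfg <- list(intervention = .arm_to_config(inputs$intervention),
              comparator = .arm_to_config(inputs$comparator),
              state_costs = unclass(inputs$costs),
              utilities = unclass(inputs$utilities),
              settings = unclass(inputs$settings))
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' Flat CSV export of a model input set
#'
#' Writes every scalar input as a `(section, parameter, value)` row and each
#' survival anchor as its own row, for inspection outside R.
#'
#' @param inputs A [cea_inputs()] object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_inputs_csv <- function(inputs, path) {
  rows <- list()
  add <- function(section, parameter, value) {
    rows[[length(rows) + 1]] <<- data.frame(section = section, parameter = parameter,
                                            value = value)
  }
  for (nm in names(inputs$costs)) add("state_costs", nm, inputs$costs[[nm]])
  for (nm in names(inputs$utilities)) add("utilities", nm, inputs$utilities[[nm]])
  for (nm in setdiff(names(inputs$settings), "cost_scaling_mode")) {
    add("settings", nm, inputs$settings[[nm]])
  }
  for (role in c("intervention", "comparator")) {
    a <- inputs[[role]]
    for (nm in c("arm_size", "systemic_therapy_fraction", "ae_onetime_cost",
                 "ae_onetime_disutility", "salvage_rt_count", "salvage_sabr_count")) {
      add(paste0(role, ":", a$name), nm, a[[nm]])
    }
    add(paste0(role, ":", a$name), "receives_primary_sabr", as.numeric(a$receives_primary_sabr))
    for (cv in c("os", "pfs")) {
      cu <- a[[cv]]
      for (i in seq_along(cu$time)) {
        add(paste0(role, ":", a$name), sprintf("%s_year_%g", cv, cu$time[i]), cu$survival[i])
      }
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
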