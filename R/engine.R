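#' State occupancy of the partitioned survival model
#'
#' State occupancy is read directly off the survival curves at each month
#' boundary: OMD (progression-free) = PFS, PMD (progressed) = OS - PFS,
#' dead = 1 - OS. The caller must enforce PFS <= OS first (see
#' [enforce_dominance()]); a violation here is an error.
#'
#' @param os,pfs `monthly_survival` vectors of equal length (months `0..H`).
#' @return An `occupancy_trace` data frame with columns `month`, `omd`, `pmd`,
#'   `dead`, one row per month boundary `0..H`.
#' @export
compute_trace <- function(os, pfs) {
  if (length(os) != length(pfs)) stop("compute_trace: os and pfs must have equal length")
  if (any(pfs > os + 1e-12)) {
    stop("compute_trace: PFS exceeds OS; clip with enforce_dominance() first")
  }
  pfs <- pmin(pfs, os)
  structure(data.frame(month = seq_along(os) - 1L,
                       omd = as.numeric(pfs),
                       pmd = as.numeric(os - pfs),
                       dead = as.numeric(1 - os)),
            class = c("occupancy_trace", "data.frame"))
}

#' Discount factor at a point in time
#'
#' `(1 + annual_rate)^(-t_months / 12)`. The engine evaluates each cycle's
#' accrual at mid-cycle, i.e. at `t = month - 0.5`.
#'
#' @param t_months Time in months (non-negative; may be fractional).
#' @param annual_rate Annual discount rate (>= 0).
#' @return Numeric vector of discount factors.
#' @export
#' @examples
#' discount_factor(12, 0.03)  # 1/1.03
discount_factor <- function(t_months, annual_rate) {
  if (any(t_months < 0)) stop("discount_factor: time must be non-negative")
  if (annual_rate < 0) stop("discount_factor: rate must be non-negative")
  (1 + annual_rate)^(-t_months / 12)
}

# mid-cycle occupancy and discount weights shared by cost and QALY accrual
.cycle_weights <- function(trace, settings) {
  h <- length(trace$omd) - 1L
  m <- seq_len(h)
  list(m = m,
       disc = discount_factor(m - 0.5, settings$annual_discount_rate),
       omd = (trace$omd[m] + trace$omd[m + 1]) / 2,
       pmd = (trace$pmd[m] + trace$pmd[m + 1]) / 2,
       ddead = trace$dead[m + 1] - trace$dead[m])
}

#' Accrue discounted quality-adjusted life years
#'
#' Each monthly cycle contributes `(omd * u_omd + pmd * u_pmd) / 12` QALYs,
#' with state membership evaluated at mid-cycle (mean of the month-start and
#' month-end occupancies) and discounted at the mid-cycle time. The one-time
#' adverse-event disutility is subtracted once, undiscounted (it is incurred
#' at the start of the simulation).
#'
#' @param trace An `occupancy_trace` from [compute_trace()].
#' @param utilities A [health_utilities()] object.
#' @param ae_disutility One-time QALY decrement (positive magnitude).
#' @param settings An [econ_settings()] object.
#' @return Discounted QALY total (scalar).
#' @export
accrue_qalys <- function(trace, utilities, ae_disutility, settings) {
  w <- .cycle_weights(trace, settings)
  sum((w$omd * utilities$u_omd + w$pmd * utilities$u_pmd) / 12 * w$disc) - ae_disutility
}

#' Accrue discounted costs with a labelled breakdown
#'
#' Three components:
#' \describe{
#'   \item{state}{Ongoing care: `(omd * annual_omd_cost + pmd *
#'     annual_pmd_cost) * s / 12` per cycle at mid-cycle occupancy and
#'     discount, where `s` is the arm's systemic-therapy fraction under
#'     `cost_scaling_mode = "systemic_fraction"` and 1 under `"none"`.}
#'   \item{onetime}{Charged undiscounted at the start: the primary SABR course
#'     (if the arm receives it), the expected salvage cost
#'     `(salvage_rt_count / arm_size) * palliative_rt_unit_cost +
#'     (salvage_sabr_count / arm_size) * sabr_unit_cost`, and the one-time
#'     adverse-event cost.}
#'   \item{end_of_life}{`end_of_life_cost` on each cycle's increment of the
#'     dead state, discounted at mid-cycle. Patients still alive at the
#'     horizon never accrue it.}
#' }
#'
#' @param trace An `occupancy_trace` from [compute_trace()].
#' @param costs A [state_costs()] object.
#' @param arm An [arm_spec()] object.
#' @param settings An [econ_settings()] object.
#' @return A list with `total` and a named `breakdown` vector
#'   (`state`, `onetime`, `end_of_life`) summing to `total`.
#' @export
accrue_costs <- function(trace, costs, arm, settings) {
  if (arm$arm_size <= 0) stop("accrue_costs: arm_size must be positive")
  w <- .cycle_weights(trace, settings)
  s <- if (settings$cost_scaling_mode == "systemic_fraction") {
    arm$systemic_therapy_fraction
  } else 1
  state <- sum((w$omd * costs$annual_omd_cost + w$pmd * costs$annual_pmd_cost) *
                 s / 12 * w$disc)
  onetime <- (if (arm$receives_primary_sabr) costs$sabr_unit_cost else 0) +
    (arm$salvage_rt_count / arm$arm_size) * costs$palliative_rt_unit_cost +
    (arm$salvage_sabr_count / arm$arm_size) * costs$sabr_unit_cost +
    arm$ae_onetime_cost
  eol <- sum(w$ddead * costs$end_of_life_cost * w$disc)
  breakdown <- c(state = state, onetime = onetime, end_of_life = eol)
  list(total = sum(breakdown), breakdown = breakdown)
}

#' Run one strategy arm through the partitioned survival model
#'
#' Deterministic composition: expand the arm's OS and PFS anchors to monthly
#' survival, clip PFS to OS, derive the occupancy trace, and accrue discounted
#' costs and QALYs.
#'
#' @param arm An [arm_spec()] object.
#' @param costs A [state_costs()] object.
#' @param utilities A [health_utilities()] object.
#' @param settings An [econ_settings()] object.
#' @return An object of class `arm_result`: list with `name`, `total_cost`,
#'   `total_qaly`, `trace` and `cost_breakdown`.
#' @export
#' @examples
#' inputs <- sabr_comet_inputs()
#' res <- run_arm(inputs$intervention, inputs$costs, inputs$utilities, inputs$settings)
#' res$total_qaly
run_arm <- function(arm, costs, utilities, settings) {
  h <- settings$horizon_months
  os <- interpolate_monthly(arm$os, h)
  pfs <- interpolate_monthly(arm$pfs, h)
  pfs <- enforce_dominance(os, pfs)
  trace <- compute_trace(os, pfs)
  cost <- accrue_costs(trace, costs, arm, settings)
  qaly <- accrue_qalys(trace, utilities, arm$ae_onetime_disutility, settings)
  structure(list(name = arm$name, total_cost = cost$total, total_qaly = qaly,
                 trace = trace, cost_breakdown = cost$breakdown),
            class = "arm_result")
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf("<arm_result %s: cost $%s, %.4g QALY over %d months>\n",
              x$name, format(round(x$total_cost), big.mark = ",", scientific = FALSE),
              x$total_qaly, nrow(x$trace) - 1))
  invisible(x)
}

#' Run the full base-case comparison
#'
#' Runs both arms of a [cea_inputs()] set and compares them at the configured
#' willingness-to-pay.
#'
#' @param inputs A [cea_inputs()] object.
#' @return A list of class `base_case_result` with elements `intervention`,
#'   `comparator` (both `arm_result`) and `comparison` ([compare_arms()]).
#' @export
#' @examples
#' bc <- run_base_case(sabr_comet_inputs())
#' bc$comparison
run_base_case <- function(inputs) {
  stopifnot(inherits(inputs, "cea_inputs"))
  a <- run_arm(inputs$intervention, inputs$costs, inputs$utilities, inputs$settings)
  b <- run_arm(inputs$comparator, inputs$costs, inputs$utilities, inputs$settings)
  structure(list(intervention = a, comparator = b,
                 comparison = compare_arms(a, b, inputs$settings$wtp)),
            class = "base_case_result")
}

#' @export
print.base_case_result <- function(x, ...) {
  print(x$intervention); print(x$comparator); print(x$comparison)
  invisible(x)
}

#' Export an occupancy trace with per-cycle accruals as CSV
#'
#' @param result An `arm_result` from [run_arm()].
#' @param costs,utilities,settings The inputs the arm was run with.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(result, costs, utilities, settings, path) {
  trace <- result$trace
  w <- .cycle_weights(trace, settings)
  out <- trace
  out$cost_m <- c(0, (w$omd * costs$annual_omd_cost + w$pmd * costs$annual_pmd_cost) /
                    12 * w$disc)
  out$qaly_m <- c(0, (w$omd * utilities$u_omd + w$pmd * utilities$u_pmd) / 12 * w$disc)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
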