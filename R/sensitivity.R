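# ---- parameter registry ------------------------------------------------------
#
# Scalar parameters are addressed by stable ids shared by the DSA and PSA:
#   annual_omd_cost, annual_pmd_cost, end_of_life_cost,
#   palliative_rt_unit_cost, sabr_unit_cost       (state_costs fields)
#   utility_omd, utility_pmd                       (health_utilities fields)
#   ae_cost_intervention, ae_cost_comparator,
#   ae_disutility_intervention, ae_disutility_comparator  (arm fields)
# Survival-curve parameters are addressed as os_/pfs_ + role and take a
# multiplicative factor applied to every anchor after time 0, with clipping to
# [0, 1] and re-enforced monotonicity.

.scalar_param_ids <- c("annual_omd_cost", "annual_pmd_cost", "end_of_life_cost",
                       "palliative_rt_unit_cost", "sabr_unit_cost",
                       "utility_omd", "utility_pmd",
                       "ae_cost_intervention", "ae_cost_comparator",
                       "ae_disutility_intervention", "ae_disutility_comparator")
.curve_param_ids <- c("os_intervention", "os_comparator",
                      "pfs_intervention", "pfs_comparator")

is_curve_param <- function(id) id %in% .curve_param_ids

.scale_curve <- function(curve, factor) {
  s <- curve$survival
  s[-1] <- s[-1] * factor
  s <- cummin(pmin(pmax(s, 0), 1))
  survival_curve(curve$time, s, name = curve$name)
}

#' Read or substitute a model parameter by id
#'
#' `get_model_param()` returns the current value of a scalar parameter;
#' `set_model_param()` returns a copy of the inputs with the parameter
#' substituted. Survival-curve ids (`os_intervention`, `pfs_comparator`, ...)
#' take a multiplicative factor applied to all anchors after time 0 (clipped
#' to `[0, 1]`, monotonicity re-enforced); their `get` value is always 1.
#'
#' @param inputs A [cea_inputs()] object.
#' @param id Parameter id (see Details).
#' @param value Replacement value (or curve factor).
#' @return `get_model_param()`: the scalar value; `set_model_param()`: a new
#'   [cea_inputs()] object.
#' @export
get_model_param <- function(inputs, id) {
  switch(id,
    annual_omd_cost = inputs$costs$annual_omd_cost,
    annual_pmd_cost = inputs$costs$annual_pmd_cost,
    end_of_life_cost = inputs$costs$end_of_life_cost,
    palliative_rt_unit_cost = inputs$costs$palliative_rt_unit_cost,
    sabr_unit_cost = inputs$costs$sabr_unit_cost,
    utility_omd = inputs$utilities$u_omd,
    utility_pmd = inputs$utilities$u_pmd,
    ae_cost_intervention = inputs$intervention$ae_onetime_cost,
    ae_cost_comparator = inputs$comparator$ae_onetime_cost,
    ae_disutility_intervention = inputs$intervention$ae_onetime_disutility,
    ae_disutility_comparator = inputs$comparator$ae_onetime_disutility,
    os_intervention = 1, os_comparator = 1, pfs_intervention = 1, pfs_comparator = 1,
    stop("unknown parameter id: ", id)
  )
}

#' @rdname get_model_param
#' @export
set_model_param <- function(inputs, id, value) {
  if (is_curve_param(id)) {
    role <- if (endsWith(id, "intervention")) "intervention" else "comparator"
    field <- if (startsWith(id, "os")) "os" else "pfs"
    inputs[[role]][[field]] <- .scale_curve(inputs[[role]][[field]], value)
    return(inputs)
  }
  switch(id,
    annual_omd_cost = { inputs$costs$annual_omd_cost <- value },
    annual_pmd_cost = { inputs$costs$annual_pmd_cost <- value },
    end_of_life_cost = { inputs$costs$end_of_life_cost <- value },
    palliative_rt_unit_cost = { inputs$costs$palliative_rt_unit_cost <- value },
    sabr_unit_cost = { inputs$costs$sabr_unit_cost <- value },
    utility_omd = { inputs$utilities$u_omd <- value },
    utility_pmd = { inputs$utilities$u_pmd <- value },
    ae_cost_intervention = { inputs$intervention$ae_onetime_cost <- value },
    ae_cost_comparator = { inputs$comparator$ae_onetime_cost <- value },
    ae_disutility_intervention = { inputs$intervention$ae_onetime_disutility <- value },
    ae_disutility_comparator = { inputs$comparator$ae_onetime_disutility <- value },
    stop("unknown parameter id: ", id)
  )
  inputs
}

#' One-way sensitivity range for a parameter
#'
#' @param id Parameter id (see [get_model_param()]).
#' @param base,low,high Base value and range endpoints, `low <= base <= high`.
#' @return A one-row data frame of class `param_range`.
#' @export
param_range <- function(id, base, low, high) {
  if (!(low <= base && base <= high)) {
    stop(sprintf("param_range '%s': need low <= base <= high", id))
  }
  structure(data.frame(id = id, base = base, low = low, high = high),
            class = c("param_range", "data.frame"))
}

#' Published one-way sensitivity ranges
#'
#' The deterministic sensitivity ranges of the SABR-COMET model: costs varied
#' over their published 95% ranges (plus/minus 20%, except the SABR unit cost
#' whose published range is 8,190-14,040), utilities over their published
#' ranges, adverse-event disutilities plus/minus 10%, and each survival curve
#' by a multiplicative plus/minus 15% factor on its anchors.
#'
#' @param inputs A [cea_inputs()] object; ranges for costs/disutilities are
#'   derived from its current base values, so the published table results when
#'   called on [sabr_comet_inputs()].
#' @return A data frame of ranges (one [param_range()] row per parameter).
#' @export
sabr_comet_dsa_ranges <- function(inputs = sabr_comet_inputs()) {
  g <- function(id) get_model_param(inputs, id)
  rows <- list(
    param_range("annual_omd_cost", g("annual_omd_cost"),
                0.8 * g("annual_omd_cost"), 1.2 * g("annual_omd_cost")),
    param_range("annual_pmd_cost", g("annual_pmd_cost"),
                0.8 * g("annual_pmd_cost"), 1.2 * g("annual_pmd_cost")),
    param_range("end_of_life_cost", g("end_of_life_cost"),
                0.8 * g("end_of_life_cost"), 1.2 * g("end_of_life_cost")),
    param_range("palliative_rt_unit_cost", g("palliative_rt_unit_cost"),
                0.8 * g("palliative_rt_unit_cost"), 1.2 * g("palliative_rt_unit_cost")),
    param_range("sabr_unit_cost", g("sabr_unit_cost"),
                0.7 * g("sabr_unit_cost"), 1.2 * g("sabr_unit_cost")),
    param_range("utility_omd", g("utility_omd"), 0.70, 0.90),
    param_range("utility_pmd", g("utility_pmd"), 0.50, 0.70),
    param_range("ae_cost_intervention", g("ae_cost_intervention"),
                0.8 * g("ae_cost_intervention"), 1.2 * g("ae_cost_intervention")),
    param_range("ae_cost_comparator", g("ae_cost_comparator"),
                0.8 * g("ae_cost_comparator"), 1.2 * g("ae_cost_comparator")),
    param_range("ae_disutility_intervention", g("ae_disutility_intervention"),
                0.9 * g("ae_disutility_intervention"), 1.1 * g("ae_disutility_intervention")),
    param_range("ae_disutility_comparator", g("ae_disutility_comparator"),
                0.9 * g("ae_disutility_comparator"), 1.1 * g("ae_disutility_comparator")),
    param_range("os_intervention", 1, 0.85, 1.15),
    param_range("os_comparator", 1, 0.85, 1.15),
    param_range("pfs_intervention", 1, 0.85, 1.15),
    param_range("pfs_comparator", 1, 0.85, 1.15))
  do.call(rbind, rows)
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-evaluates the full base case twice per parameter — once at each range
#' endpoint, all other parameters at base — and reports the chosen metric at
#' both endpoints with the resulting spread, sorted by spread (descending).
#'
#' With `metric = "icer"` an endpoint whose comparison leaves the ICER
#' undefined (dominant, dominated or equivalent) is reported as `NA` with its
#' status; rows with any undefined endpoint have `NA` spread and sort last.
#' `metric = "inmb"` (incremental net monetary benefit at the configured
#' willingness-to-pay) is always defined and is the stabler tornado metric
#' when incremental effects may change sign.
#'
#' @param inputs A [cea_inputs()] object.
#' @param ranges Data frame of [param_range()] rows.
#' @param metric `"icer"` (default) or `"inmb"`.
#' @return A data frame of class `tornado` with columns `id`, `base`, `low`,
#'   `high`, `value_at_low`, `value_at_high`, `status_at_low`,
#'   `status_at_high`, `spread`.
#' @export
one_way_dsa <- function(inputs, ranges, metric = c("icer", "inmb")) {
  metric <- match.arg(metric)
  stopifnot(inherits(inputs, "cea_inputs"),
            all(c("id", "base", "low", "high") %in% names(ranges)))
  eval_at <- function(id, value) {
    cmp <- run_base_case(set_model_param(inputs, id, value))$comparison
    val <- if (metric == "icer") cmp$icer else cmp$inmb
    list(value = val, status = cmp$status)
  }
  out <- lapply(seq_len(nrow(ranges)), function(i) {
    r <- ranges[i, ]
    lo <- eval_at(r$id, r$low)
    hi <- eval_at(r$id, r$high)
    data.frame(id = r$id, base = r$base, low = r$low, high = r$high,
               value_at_low = lo$value, value_at_high = hi$value,
               status_at_low = lo$status, status_at_high = hi$status,
               spread = abs(hi$value - lo$value))
  })
  out <- do.call(rbind, out)
  out <- out[order(-out$spread, na.last = TRUE), ]
  rownames(out) <- NULL
  structure(out, class = c("tornado", "data.frame"), metric = metric)
}

#' Willingness-to-pay threshold for the SABR unit cost
#'
#' Finds the SABR unit cost at which the incremental net monetary benefit of
#' the intervention reaches zero at the given willingness-to-pay, by bisection
#' to an absolute tolerance of $1. The substituted cost applies everywhere the
#' unit cost enters the model: the primary SABR course and salvage SABR
#' courses of both arms. Because the unit cost enters total cost linearly,
#' incremental NMB is monotone in it and the bisection result agrees with the
#' closed form
#' `c* = c_base + iNMB_base / (n_sabr_courses_intervention - n_sabr_courses_comparator)`
#' where `n_sabr_courses` counts expected courses per patient.
#'
#' @param inputs A [cea_inputs()] object.
#' @param wtp Willingness-to-pay (defaults to the configured setting).
#' @param bracket Search bracket for the unit cost; default `c(0, 1e6)`.
#' @param tol Absolute tolerance in USD (default 1).
#' @return A list of class `threshold_result`: `parameter`, `base`,
#'   `threshold`, `multiple_of_base`, `wtp`.
#' @export
#' @examples
#' threshold_search(sabr_comet_inputs())$threshold
threshold_search <- function(inputs, wtp = inputs$settings$wtp,
                             bracket = c(0, 1e6), tol = 1) {
  stopifnot(inherits(inputs, "cea_inputs"))
  base <- inputs$costs$sabr_unit_cost
  f <- function(cs) {
    run_base_case(set_model_param(inputs, "sabr_unit_cost", cs))$comparison$inmb
  }
  f_base <- f(base)
  if (f_base == 0) {
    return(structure(list(parameter = "sabr_unit_cost", base = base, threshold = base,
                          multiple_of_base = 1, wtp = wtp),
                     class = "threshold_result"))
  }
  lo <- bracket[1]; hi <- bracket[2]
  flo <- f(lo); fhi <- f(hi)
  if (sign(flo) == sign(fhi)) {
    stop(sprintf(paste0("threshold_search: incremental NMB has the same sign at both ",
                        "bracket endpoints (%.4g at $%.6g, %.4g at $%.6g); widen the bracket"),
                 flo, lo, fhi, hi))
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (sign(f(mid)) == sign(flo)) lo <- mid else hi <- mid
  }
  thr <- (lo + hi) / 2
  structure(list(parameter = "sabr_unit_cost", base = base, threshold = thr,
                 multiple_of_base = thr / base, wtp = wtp),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result: %s cost-neutral at $%s (%.3g x base $%s) at WTP $%s/QALY>\n",
              x$parameter, format(round(x$threshold), big.mark = ","),
              x$multiple_of_base, format(round(x$base), big.mark = ","),
              format(x$wtp, big.mark = ",", scientific = FALSE)))
  invisible(x)
}
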