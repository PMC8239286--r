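#' Net monetary benefit
#'
#' `effect * wtp - cost`: positive incremental NMB at a willingness-to-pay
#' threshold means the intervention is cost-effective at that threshold.
#'
#' @param cost Cost in USD.
#' @param effect Effectiveness in QALYs.
#' @param wtp Willingness-to-pay in USD per QALY (>= 0).
#' @return NMB in USD.
#' @export
nmb <- function(cost, effect, wtp) {
  if (any(wtp < 0)) stop("nmb: wtp must be non-negative")
  effect * wtp - cost
}

#' Pairwise incremental cost-effectiveness comparison
#'
#' Computes incremental cost and effect of the intervention over the
#' comparator, the ICER where it is interpretable, per-arm net monetary
#' benefit, and a dominance status. The ICER is reported only in the standard
#' quadrants (both deltas positive, or both negative); when the intervention
#' is cheaper and more effective it is *dominant*, in the reverse case
#' *dominated*, and when the effect difference is below 1e-12 QALY the arms
#' are *equivalent* — in all three cases `icer` is `NA` (negative cost/effect
#' ratios are uninterpretable).
#'
#' @param intervention,comparator `arm_result` objects from [run_arm()].
#' @param wtp Willingness-to-pay, USD/QALY.
#' @return An object of class `cea_result`: list with `delta_cost`,
#'   `delta_effect`, `icer`, `status` (one of `"icer_defined"`,
#'   `"intervention_dominant"`, `"intervention_dominated"`, `"equivalent"`),
#'   `nmb_intervention`, `nmb_comparator`, `inmb` and `wtp`.
#' @export
#' @examples
#' bc <- run_base_case(sabr_comet_inputs())
#' bc$comparison$icer
compare_arms <- function(intervention, comparator, wtp) {
  dc <- intervention$total_cost - comparator$total_cost
  de <- intervention$total_qaly - comparator$total_qaly
  status <- if (abs(de) < 1e-12) {
    "equivalent"
  } else if (de > 0 && dc < 0) {
    "intervention_dominant"
  } else if (de < 0 && dc > 0) {
    "intervention_dominated"
  } else {
    "icer_defined"
  }
  icer <- if (status == "icer_defined") dc / de else NA_real_
  structure(list(
    intervention = intervention$name, comparator = comparator$name,
    delta_cost = dc, delta_effect = de, icer = icer, status = status,
    nmb_intervention = nmb(intervention$total_cost, intervention$total_qaly, wtp),
    nmb_comparator = nmb(comparator$total_cost, comparator$total_qaly, wtp),
    inmb = nmb(dc, de, wtp), wtp = wtp),
    class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  lab <- switch(x$status,
                icer_defined = sprintf("$%s/QALY", format(round(x$icer, 1), big.mark = ",")),
                intervention_dominant = "dominant (cheaper, more effective)",
                intervention_dominated = "dominated (costlier, less effective)",
                equivalent = "equivalent effectiveness")
  cat(sprintf("<cea_result %s vs %s: dCost $%s, dEffect %.4g QALY, ICER %s, iNMB $%s at WTP $%s>\n",
              x$intervention, x$comparator,
              format(round(x$delta_cost), big.mark = ","), x$delta_effect, lab,
              format(round(x$inmb), big.mark = ","),
              format(x$wtp, big.mark = ",", scientific = FALSE)))
  invisible(x)
}

#' Write a two-arm comparison table as CSV
#'
#' One row per arm with columns `arm`, `cost`, `incremental_cost`, `effect`,
#' `incremental_effect`, `nmb`, `icer`, `status` (incremental columns filled
#' on the intervention row only).
#'
#' @param base_case A `base_case_result` from [run_base_case()].
#' @param path Output CSV path.
#' @return The table, invisibly (also written to `path` if not `NULL`).
#' @export
cea_table <- function(base_case, path = NULL) {
  cmp <- base_case$comparison
  tab <- data.frame(
    arm = c(base_case$intervention$name, base_case$comparator$name),
    cost = c(base_case$intervention$total_cost, base_case$comparator$total_cost),
    incremental_cost = c(cmp$delta_cost, NA),
    effect = c(base_case$intervention$total_qaly, base_case$comparator$total_qaly),
    incremental_effect = c(cmp$delta_effect, NA),
    nmb = c(cmp$nmb_intervention, cmp$nmb_comparator),
    icer = c(cmp$icer, NA),
    status = c(cmp$status, NA))
  if (!is.null(path)) utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
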