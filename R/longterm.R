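#' Extend a model input set to a long-term horizon via a reference curve
#'
#' For each arm, overall survival is extended beyond the trial follow-up by
#' [splice_extrapolate()] along the supplied long-term reference curve, and
#' progression-free survival by [extrapolate_pfs_proportional()] (the trial's
#' end-of-follow-up PFS/OS ratio applied to the extended OS). The horizon in
#' the settings is raised to `horizon_months`.
#'
#' @param inputs A [cea_inputs()] object with trial-period curves.
#' @param reference A long-term reference [survival_curve()] (e.g. a pooled
#'   registry curve, or the synthetic stand-in from
#'   [generate_reference_survival()]).
#' @param horizon_months Long-term horizon (default 192 months = 16 years).
#' @return A [cea_inputs()] object with extended curves and horizon.
#' @export
#' @examples
#' ref <- generate_reference_survival(synthetic_reference_specs(), horizon_years = 20)
#' lt <- extend_inputs_longterm(sabr_comet_inputs(), ref)
#' lt$settings$horizon_months
extend_inputs_longterm <- function(inputs, reference, horizon_months = 192) {
  stopifnot(inherits(inputs, "cea_inputs"), inherits(reference, "survival_curve"))
  horizon_years <- horizon_months / 12
  out <- inputs
  for (role in c("intervention", "comparator")) {
    arm <- out[[role]]
    os_ext <- splice_extrapolate(arm$os, reference, horizon_years)
    pfs_ext <- extrapolate_pfs_proportional(os_ext, arm$pfs, arm$os)
    out[[role]]$os <- os_ext
    out[[role]]$pfs <- pfs_ext
  }
  out$settings <- econ_settings(
    annual_discount_rate = inputs$settings$annual_discount_rate,
    horizon_months = horizon_months,
    wtp = inputs$settings$wtp,
    cost_scaling_mode = inputs$settings$cost_scaling_mode)
  out
}
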