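# Independent fine-step integration oracle for one arm: discretizes the same
# continuous-time accrual at `steps_per_month` sub-steps per month, evaluating
# occupancy and discounting at each sub-step midpoint. Written directly from
# the model definition, independent of the engine's cycle bookkeeping.
fine_step_arm_totals <- function(arm, costs, utilities, settings,
                                 steps_per_month = 30) {
  h <- settings$horizon_months
  k <- steps_per_month
  tb <- seq(0, h, by = 1 / k)                    # step boundaries, months
  os <- curve_value(arm$os, tb / 12)
  pfs <- pmin(curve_value(arm$pfs, tb / 12), os)
  n <- length(tb) - 1
  mid <- (tb[-1] + tb[-(n + 1)]) / 2
  disc <- (1 + settings$annual_discount_rate)^(-mid / 12)
  omd <- (pfs[-1] + pfs[-(n + 1)]) / 2
  pmd <- (os[-1] - pfs[-1] + os[-(n + 1)] - pfs[-(n + 1)]) / 2
  ddead <- os[-(n + 1)] - os[-1]
  s <- if (settings$cost_scaling_mode == "systemic_fraction") {
    arm$systemic_therapy_fraction
  } else 1
  state <- sum((omd * costs$annual_omd_cost + pmd * costs$annual_pmd_cost) *
                 s / 12 / k * disc)
  eol <- sum(ddead * costs$end_of_life_cost * disc)
  onetime <- (if (arm$receives_primary_sabr) costs$sabr_unit_cost else 0) +
    arm$salvage_rt_count / arm$arm_size * costs$palliative_rt_unit_cost +
    arm$salvage_sabr_count / arm$arm_size * costs$sabr_unit_cost +
    arm$ae_onetime_cost
  qaly <- sum((omd * utilities$u_omd + pmd * utilities$u_pmd) / 12 / k * disc) -
    arm$ae_onetime_disutility
  c(cost = state + eol + onetime, qaly = qaly)
}

# minimal stand-in arm result for testing comparison metrics in isolation
fake_arm_result <- function(name, cost, qaly) {
  structure(list(name = name, total_cost = cost, total_qaly = qaly),
            class = "arm_result")
}
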