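test_that("occupancy is read directly off the survival curves", {
  tr <- compute_trace(c(1, 0.88, 0), c(1, 0.19, 0))
  expect_equal(tr$omd, c(1, 0.19, 0))
  expect_equal(tr$pmd, c(0, 0.69, 0))
  expect_equal(tr$dead, c(0, 0.12, 1))
  expect_equal(tr$omd + tr$pmd + tr$dead, rep(1, 3), tolerance = 1e-12)
  expect_error(compute_trace(c(1, 0.5), c(1, 0.6)), "enforce_dominance")
  expect_error(compute_trace(c(1, 0.5), c(1)), "equal length")
})

test_that("discounting follows (1 + r)^(-t/12)", {
  expect_equal(discount_factor(0, 0.03), 1)
  expect_equal(discount_factor(12, 0.03), 1 / 1.03, tolerance = 1e-9)
  expect_equal(discount_factor(24, 0.03), 1.03^-2, tolerance = 1e-9)
  expect_equal(discount_factor(0:36, 0), rep(1, 37))
  expect_error(discount_factor(-1, 0.03), "non-negative")
  expect_error(discount_factor(12, -0.01), "non-negative")
})

test_that("QALY accrual uses mid-cycle occupancy", {
  # an immortal cohort in full health accrues exactly 1 QALY per year
  settings <- econ_settings(annual_discount_rate = 0, horizon_months = 12)
  tr <- compute_trace(rep(1, 13), rep(1, 13))
  u <- health_utilities(1, 1)
  expect_equal(accrue_qalys(tr, u, 0, settings), 1, tolerance = 1e-12)
  # two-cycle toy, hand-computed under the mid-cycle rule:
  # cycle 1 omd = 1; cycle 2 omd = 0.75, pmd = 0.25
  settings2 <- econ_settings(annual_discount_rate = 0, horizon_months = 2)
  tr2 <- compute_trace(c(1, 1, 1), c(1, 1, 0.5))
  u2 <- health_utilities(0.8, 0.6)
  expect_equal(accrue_qalys(tr2, u2, 0, settings2),
               (1 * 0.8 + (0.75 * 0.8 + 0.25 * 0.6)) / 12, tolerance = 1e-12)
  # one-time disutility subtracts once
  expect_equal(accrue_qalys(tr2, u2, 0.002, settings2),
               (0.8 + 0.75) / 12 - 0.002, tolerance = 1e-12)
})

test_that("cost accrual components behave and sum to the total", {
  inputs <- sabr_comet_inputs()
  res <- run_arm(inputs$comparator, inputs$costs, inputs$utilities, inputs$settings)
  expect_equal(res$total_cost, sum(res$cost_breakdown), tolerance = 1e-6)
  # expected salvage + adverse-event one-time cost for the comparator arm
  expect_equal(res$cost_breakdown[["onetime"]], (23 / 33) * 11070 + 997,
               tolerance = 1e-9)
  # end-of-life component bounded by the unit cost
  expect_lt(res$cost_breakdown[["end_of_life"]], inputs$costs$end_of_life_cost)
  # all-zero cost inputs give zero
  zero <- state_costs(0, 0, 0, 0, 0)
  tr <- res$trace
  arm0 <- inputs$comparator
  arm0$ae_onetime_cost <- 0
  expect_equal(accrue_costs(tr, zero, arm0, inputs$settings)$total, 0)
})

test_that("cost scaling mode controls the systemic-therapy fraction", {
  inputs <- sabr_comet_inputs()
  s1 <- inputs$settings
  s2 <- econ_settings(annual_discount_rate = 0.03, horizon_months = 72,
                      cost_scaling_mode = "none")
  r1 <- run_arm(inputs$comparator, inputs$costs, inputs$utilities, s1)
  r2 <- run_arm(inputs$comparator, inputs$costs, inputs$utilities, s2)
  expect_equal(r1$cost_breakdown[["state"]],
               0.636 * r2$cost_breakdown[["state"]], tolerance = 1e-9)
  expect_equal(r1$cost_breakdown[["end_of_life"]], r2$cost_breakdown[["end_of_life"]])
})

test_that("a zero-cost immortal cohort at unit utility yields cost 0, QALY 1", {
  cv <- survival_curve(c(0, 1), c(1, 1))
  arm <- arm_spec("ideal", cv, cv, arm_size = 10, systemic_therapy_fraction = 1,
                  ae_onetime_cost = 0, ae_onetime_disutility = 0,
                  salvage_rt_count = 0, salvage_sabr_count = 0,
                  receives_primary_sabr = FALSE)
  res <- run_arm(arm, state_costs(0, 0, 0, 0, 0), health_utilities(1, 1),
                 econ_settings(annual_discount_rate = 0, horizon_months = 12))
  expect_equal(res$total_cost, 0)
  expect_equal(res$total_qaly, 1, tolerance = 1e-12)
})

test_that("zero discount makes totals equal plain undiscounted sums", {
  inputs <- sabr_comet_inputs()
  s0 <- econ_settings(annual_discount_rate = 0, horizon_months = 72)
  for (arm in list(inputs$intervention, inputs$comparator)) {
    res <- run_arm(arm, inputs$costs, inputs$utilities, s0)
    # plain-sum oracle straight from the trace
    tr <- res$trace
    m <- 1:72
    omd <- (tr$omd[m] + tr$omd[m + 1]) / 2
    pmd <- (tr$pmd[m] + tr$pmd[m + 1]) / 2
    qaly_plain <- sum(omd * 0.82 + pmd * 0.59) / 12 - arm$ae_onetime_disutility
    state_plain <- sum(omd * 97440 + pmd * 189840) * arm$systemic_therapy_fraction / 12
    eol_plain <- 19174 * (tr$dead[73] - tr$dead[1])
    expect_equal(res$total_qaly, qaly_plain, tolerance = 1e-9)
    expect_equal(res$cost_breakdown[["state"]], state_plain, tolerance = 1e-9)
    expect_equal(res$cost_breakdown[["end_of_life"]], eol_plain, tolerance = 1e-9)
  }
})

test_that("the monthly engine agrees with a fine-step integration oracle within 1%", {
  inputs <- sabr_comet_inputs()
  for (arm in list(inputs$intervention, inputs$comparator)) {
    res <- run_arm(arm, inputs$costs, inputs$utilities, inputs$settings)
    oracle <- fine_step_arm_totals(arm, inputs$costs, inputs$utilities,
                                   inputs$settings, steps_per_month = 30)
    expect_equal(res$total_cost, oracle[["cost"]], tolerance = 0.01)
    expect_equal(res$total_qaly, oracle[["qaly"]], tolerance = 0.01)
  }
})

test_that("refining the oracle step hardly moves the totals (discretization converged)", {
  inputs <- sabr_comet_inputs()
  arm <- inputs$intervention
  c15 <- fine_step_arm_totals(arm, inputs$costs, inputs$utilities, inputs$settings, 15)
  c30 <- fine_step_arm_totals(arm, inputs$costs, inputs$utilities, inputs$settings, 30)
  expect_equal(c15[["cost"]], c30[["cost"]], tolerance = 0.005)
  expect_equal(c15[["qaly"]], c30[["qaly"]], tolerance = 0.005)
})

test_that("occupancy conservation and dead-state monotonicity hold on random inputs", {
  for (seed in 1:200) {
    inputs <- generate_random_model_inputs(seed)
    for (arm in list(inputs$intervention, inputs$comparator)) {
      res <- run_arm(arm, inputs$costs, inputs$utilities, inputs$settings)
      tr <- res$trace
      expect_true(max(abs(tr$omd + tr$pmd + tr$dead - 1)) <= 1e-9)
      expect_true(all(diff(tr$dead) >= -1e-12))
      expect_true(all(tr$omd >= -1e-12 & tr$pmd >= -1e-12 & tr$dead >= -1e-12))
      expect_true(is.finite(res$total_cost) && res$total_cost >= 0)
      expect_true(is.finite(res$total_qaly) && res$total_qaly >= 0)
    }
  }
})

test_that("identical inputs give identical arm results", {
  inputs <- sabr_comet_inputs()
  r1 <- run_arm(inputs$intervention, inputs$costs, inputs$utilities, inputs$settings)
  r2 <- run_arm(inputs$intervention, inputs$costs, inputs$utilities, inputs$settings)
  expect_identical(r1$total_cost, r2$total_cost)
  expect_identical(r1$total_qaly, r2$total_qaly)
})
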