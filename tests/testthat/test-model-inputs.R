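test_that("the bundled input set carries the published values", {
  inputs <- sabr_comet_inputs()
  expect_equal(inputs$comparator$os$survival, c(1, 0.88, 0.58, 0.38, 0.18, 0.18, 0.18))
  expect_equal(inputs$comparator$pfs$survival, c(1, 0.19, 0.13, 0.07, 0.04, 0, 0))
  expect_equal(inputs$intervention$os$survival, c(1, 0.88, 0.69, 0.62, 0.52, 0.42, 0.42))
  expect_equal(inputs$intervention$pfs$survival, c(1, 0.50, 0.38, 0.30, 0.21, 0.18, 0.18))
  expect_equal(inputs$utilities$u_omd, 0.82)
  expect_equal(inputs$utilities$u_pmd, 0.59)
  expect_equal(inputs$costs$annual_omd_cost, 97440)
  expect_equal(inputs$costs$annual_pmd_cost, 189840)
  expect_equal(inputs$costs$end_of_life_cost, 19174)
  expect_equal(inputs$costs$palliative_rt_unit_cost, 11070)
  expect_equal(inputs$costs$sabr_unit_cost, 11700)
  expect_equal(inputs$intervention$salvage_rt_count, 16)
  expect_equal(inputs$intervention$salvage_sabr_count, 9)
  expect_equal(inputs$comparator$salvage_rt_count, 23)
  expect_equal(inputs$intervention$systemic_therapy_fraction, 0.55)
  expect_equal(inputs$comparator$systemic_therapy_fraction, 0.636)
  expect_equal(inputs$intervention$ae_onetime_cost, 1443)
  expect_equal(inputs$comparator$ae_onetime_cost, 997)
  expect_equal(inputs$intervention$ae_onetime_disutility, 0.002)
  expect_equal(inputs$comparator$ae_onetime_disutility, 0.0008)
  expect_equal(inputs$settings$annual_discount_rate, 0.03)
  expect_equal(inputs$settings$wtp, 1e5)
  expect_equal(inputs$settings$horizon_months, 72L)
  expect_true(inputs$intervention$receives_primary_sabr)
  expect_false(inputs$comparator$receives_primary_sabr)
})

test_that("domain type constructors validate their fields", {
  expect_error(state_costs(-1, 2, 3, 4, 5), "negative")
  expect_error(health_utilities(1.2, 0.5), "\\[0, 1\\]")
  expect_warning(health_utilities(0.5, 0.8), "u_pmd > u_omd")
  expect_error(econ_settings(annual_discount_rate = -0.01), "discount")
  expect_error(econ_settings(horizon_months = 0), "positive multiple")
  expect_error(econ_settings(cycle_length_months = 3), "fixed at 1 month")
  cv <- survival_curve(0:1, c(1, 0.5))
  expect_error(
    arm_spec("x", cv, cv, arm_size = 10, systemic_therapy_fraction = 0.5,
             ae_onetime_cost = 0, ae_onetime_disutility = 0,
             salvage_rt_count = 11, salvage_sabr_count = 0,
             receives_primary_sabr = FALSE),
    "salvage")
  expect_error(
    arm_spec("x", cv, cv, arm_size = 10, systemic_therapy_fraction = 1.5,
             ae_onetime_cost = 0, ae_onetime_disutility = 0,
             salvage_rt_count = 0, salvage_sabr_count = 0,
             receives_primary_sabr = FALSE),
    "systemic_therapy_fraction")
  expect_error(
    arm_spec("x", cv, cv, arm_size = 10, systemic_therapy_fraction = 0.5,
             ae_onetime_cost = 0, ae_onetime_disutility = -0.01,
             salvage_rt_count = 0, salvage_sabr_count = 0,
             receives_primary_sabr = FALSE),
    "positive magnitude")
})

test_that("configuration files round-trip field-for-field", {
  inputs <- sabr_comet_inputs()
  p1 <- withr::local_tempfile(fileext = ".yaml")
  p2 <- withr::local_tempfile(fileext = ".yaml")
  write_cea_config(inputs, p1)
  back <- read_cea_config(p1)
  # numeric content identical
  for (f in names(inputs$costs)) expect_equal(back$costs[[f]], inputs$costs[[f]])
  expect_equal(back$utilities$u_omd, inputs$utilities$u_omd)
  expect_equal(back$utilities$u_pmd, inputs$utilities$u_pmd)
  expect_equal(unclass(back$settings), unclass(inputs$settings))
  for (role in c("intervention", "comparator")) {
    for (f in setdiff(names(inputs[[role]]), c("os", "pfs"))) {
      expect_equal(back[[role]][[f]], inputs[[role]][[f]])
    }
    for (cv in c("os", "pfs")) {
      expect_equal(back[[role]][[cv]]$time, inputs[[role]][[cv]]$time)
      expect_equal(back[[role]][[cv]]$survival, inputs[[role]][[cv]]$survival)
    }
  }
  # serialized form is a fixed point of read/write
  write_cea_config(back, p2)
  expect_identical(yaml::read_yaml(p2), yaml::read_yaml(p1))
})

test_that("config validation names offending keys, fields and anchors", {
  inputs <- sabr_comet_inputs()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_cea_config(inputs, path)
  cfg <- yaml::read_yaml(path)

  bad <- cfg
  bad$state_costs$typo_key <- 1
  yaml::write_yaml(bad, path)
  expect_error(read_cea_config(path), "typo_key")

  bad <- cfg
  bad$state_costs$annual_omd_cost <- NULL
  yaml::write_yaml(bad, path)
  expect_error(read_cea_config(path), "missing field.*annual_omd_cost")

  bad <- cfg
  bad$comparator$os$survival <- c(1, 0.88, 0.90, 0.38, 0.18, 0.18, 0.18)
  yaml::write_yaml(bad, path)
  expect_error(read_cea_config(path), "comparator\\$os.*increases at anchor index 3")
})

test_that("omitted settings fall back to their defaults", {
  inputs <- sabr_comet_inputs()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_cea_config(inputs, path)
  cfg <- yaml::read_yaml(path)
  cfg$settings$wtp <- NULL
  cfg$settings$annual_discount_rate <- NULL
  yaml::write_yaml(cfg, path)
  back <- read_cea_config(path)
  expect_equal(back$settings$wtp, 1e5)
  expect_equal(back$settings$annual_discount_rate, 0.03)
})

test_that("the flat CSV export lists every scalar input", {
  inputs <- sabr_comet_inputs()
  path <- withr::local_tempfile(fileext = ".csv")
  write_inputs_csv(inputs, path)
  tab <- utils::read.csv(path)
  expect_true(all(c("section", "parameter", "value") %in% names(tab)))
  expect_equal(tab$value[tab$parameter == "u_omd"], 0.82)
  expect_equal(tab$value[tab$parameter == "os_year_1" &
                           tab$section == "comparator:SC"], 0.88)
})
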