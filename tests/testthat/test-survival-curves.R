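test_that("survival_curve enforces its invariants", {
  expect_s3_class(survival_curve(0:2, c(1, 0.5, 0.25)), "survival_curve")
  expect_error(survival_curve(c(0, 1), c(0.9, 0.5)), "first anchor")
  expect_error(survival_curve(c(0.5, 1), c(1, 0.5)), "first anchor")
  expect_error(survival_curve(c(0, 1, 1), c(1, 0.5, 0.4)), "strictly increasing")
  expect_error(survival_curve(c(0, 1, 2), c(1, 0.5, 0.6)), "increases at anchor index 3")
  expect_error(survival_curve(c(0, 1), c(1, -0.1)), "outside")
})

test_that("monthly interpolation reproduces anchors exactly and is constant-hazard between them", {
  os_sc <- survival_curve(0:6, c(1, 0.88, 0.58, 0.38, 0.18, 0.18, 0.18))
  m <- interpolate_monthly(os_sc, 72)
  # anchors at whole years are hit exactly
  expect_equal(m[12 * (0:6) + 1], c(1, 0.88, 0.58, 0.38, 0.18, 0.18, 0.18),
               tolerance = 1e-12)
  expect_identical(m[1], 1)
  # constant-hazard midpoint: S(6 months) = 0.88^(1/2)
  expect_equal(m[7], sqrt(0.88), tolerance = 1e-12)
  # general interior point, closed form
  expect_equal(m[19], 0.88 * (0.58 / 0.88)^(6 / 12), tolerance = 1e-12)
  expect_error(interpolate_monthly(os_sc, 0), "positive integer")
})

test_that("interpolation carries the last anchor flat and collapses at zero anchors", {
  cv <- survival_curve(c(0, 1), c(1, 0.6))
  expect_equal(as.numeric(interpolate_monthly(cv, 36)[13:37]), rep(0.6, 25))
  # a zero anchor has infinite hazard on its interval: values drop to 0
  # immediately after the previous anchor and stay there
  z <- survival_curve(c(0, 1, 2), c(1, 0.4, 0))
  m <- interpolate_monthly(z, 36)
  expect_equal(m[13], 0.4)
  expect_equal(as.numeric(m[14:37]), rep(0, 24))
})

test_that("dominance enforcement clips PFS to OS and warns with the first violating month", {
  os <- interpolate_monthly(survival_curve(0:2, c(1, 0.5, 0.25)), 24)
  ok <- interpolate_monthly(survival_curve(0:2, c(1, 0.4, 0.2)), 24)
  expect_identical(as.numeric(enforce_dominance(os, ok)), as.numeric(ok))
  bad <- structure(rep(0.6, 25), class = "monthly_survival")
  # os falls below 0.6 first at month 9 (0.5^(9/12) = 0.5946)
  expect_warning(clipped <- enforce_dominance(os, bad), "month 9")
  expect_true(all(clipped <= os))
  expect_error(enforce_dominance(os, bad[-1]), "equal length")
})

test_that("fixture curves need no clipping after monthly expansion", {
  inputs <- sabr_comet_inputs()
  for (arm in list(inputs$intervention, inputs$comparator)) {
    os <- interpolate_monthly(arm$os, 72)
    pfs <- interpolate_monthly(arm$pfs, 72)
    expect_true(all(pfs <= os + 1e-15), label = paste(arm$name, "PFS <= OS monthly"))
    expect_no_warning(enforce_dominance(os, pfs))
  }
})

test_that("splicing continues the trial curve along an exponential reference exactly", {
  trial <- survival_curve(0:6, c(1, 0.88, 0.69, 0.62, 0.52, 0.42, 0.42))
  lam <- 0.15
  ref <- survival_curve(seq(0, 30, by = 1 / 12),
                        exp(-lam * seq(0, 30, by = 1 / 12)))
  ext <- splice_extrapolate(trial, ref, horizon_years = 16)
  # junction continuity and pre-junction identity
  expect_equal(curve_value(ext, 6), 0.42, tolerance = 1e-12)
  expect_equal(curve_value(ext, c(1, 3, 5.5)), curve_value(trial, c(1, 3, 5.5)),
               tolerance = 1e-12)
  # closed form: t* = -ln(0.42)/lam, S(t > 6) = exp(-lam * (t* + t - 6))
  t_star <- -log(0.42) / lam
  for (t in c(7, 10, 16)) {
    expect_equal(curve_value(ext, t), exp(-lam * (t_star + t - 6)), tolerance = 1e-9)
  }
  # global monotonicity on a fine grid
  fine <- curve_value(ext, seq(0, 16, by = 1 / 24))
  expect_true(all(diff(fine) <= 1e-12))
})

test_that("splicing degenerate cases: no extension, self-splice, unreachable level", {
  trial <- survival_curve(0:6, c(1, 0.88, 0.69, 0.62, 0.52, 0.42, 0.42))
  expect_identical(splice_extrapolate(trial, trial, 6), trial)
  # self-splice: the flat tail continues flat
  self6 <- splice_extrapolate(trial, trial, 16)
  expect_equal(curve_value(self6, c(7, 12, 16)), rep(0.42, 3), tolerance = 1e-12)
  # reference that never falls to the trial-end level
  high <- survival_curve(c(0, 20), c(1, 0.9))
  expect_error(splice_extrapolate(trial, high, 16), "never reaches")
})

test_that("proportional PFS extension uses the trial-end PFS/OS ratio", {
  os <- survival_curve(0:6, c(1, 0.88, 0.69, 0.62, 0.52, 0.42, 0.42))
  pfs <- survival_curve(0:6, c(1, 0.50, 0.38, 0.30, 0.21, 0.18, 0.18))
  ref <- survival_curve(seq(0, 30, 0.25), exp(-0.2 * seq(0, 30, 0.25)))
  os_ext <- splice_extrapolate(os, ref, 16)
  pfs_ext <- extrapolate_pfs_proportional(os_ext, pfs, os)
  r <- 0.18 / 0.42
  for (t in c(8, 12, 16)) {
    expect_equal(curve_value(pfs_ext, t), r * curve_value(os_ext, t), tolerance = 1e-9)
  }
  # trial period untouched; extension never exceeds extended OS
  expect_equal(curve_value(pfs_ext, c(1, 4, 6)), c(0.50, 0.21, 0.18), tolerance = 1e-12)
  grid <- seq(0, 16, by = 1 / 12)
  expect_true(all(curve_value(pfs_ext, grid) <= curve_value(os_ext, grid) + 1e-12))
})

test_that("proportional extension handles zero and ill-defined ratios", {
  os <- survival_curve(0:2, c(1, 0.6, 0.4))
  pfs0 <- survival_curve(0:2, c(1, 0.2, 0))
  ref <- survival_curve(seq(0, 30, 0.5), exp(-0.3 * seq(0, 30, 0.5)))
  os_ext <- splice_extrapolate(os, ref, 10)
  ext <- extrapolate_pfs_proportional(os_ext, pfs0, os)
  expect_equal(curve_value(ext, c(3, 5, 10)), rep(0, 3))
  os_dead <- survival_curve(0:2, c(1, 0.5, 0))
  pfs_alive <- survival_curve(0:2, c(1, 0.4, 0.1))
  expect_error(extrapolate_pfs_proportional(os_ext, pfs_alive, os_dead), "ratio undefined")
})

test_that("pooling takes the weighted pointwise mean and preserves monotonicity", {
  t <- seq(0, 10, by = 0.5)
  a <- survival_curve(t, exp(-0.1 * t))
  b <- survival_curve(t, exp(-0.3 * t))
  expect_equal(pool_reference_curves(list(a, b), c(1, 0))$survival, a$survival,
               tolerance = 1e-12)
  pooled <- pool_reference_curves(list(a, b), c(0.5, 0.5))
  expect_equal(curve_value(pooled, 1), 0.5 * (exp(-0.1) + exp(-0.3)), tolerance = 1e-12)
  expect_true(all(diff(pooled$survival) <= 0))
  expect_error(pool_reference_curves(list(a, b), c(0.6, 0.5)), "sum to")
  # mismatched grids are resampled onto the union grid
  c2 <- survival_curve(c(0, 4, 10), exp(-0.2 * c(0, 4, 10)))
  mixed <- pool_reference_curves(list(a, c2), c(0.5, 0.5))
  expect_equal(curve_value(mixed, 4), 0.5 * (exp(-0.4) + exp(-0.8)), tolerance = 1e-12)
})

test_that("curve CSV round-trips", {
  cv <- survival_curve(0:3, c(1, 0.7, 0.5, 0.41), name = "roundtrip")
  path <- withr::local_tempfile(fileext = ".csv")
  write_survival_curve_csv(cv, path)
  back <- read_survival_curve_csv(path, name = "roundtrip")
  expect_equal(back$time, cv$time)
  expect_equal(back$survival, cv$survival)
})
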