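ba_mono <- emax_model(0.34, 44.0, 1)

test_that("single-drug Emax effect reproduces the anchor predictions", {
  # 180 mg monotherapy: about 27% lowering
  expect_equal(fractional_effect(180, ba_mono), 0.34 * 180 / 224,
               tolerance = 1e-12)
  expect_equal(round(percent_change(fractional_effect(180, ba_mono))), -27)
  # no dose, no effect; half-maximal at ED50 by construction
  expect_identical(fractional_effect(0, ba_mono), 0)
  expect_equal(fractional_effect(44, ba_mono), 0.34 / 2, tolerance = 1e-12)
  # atorvastatin 80 mg from the fixed statin parameters, frozen closed-form
  ator <- statin_profiles()$atorvastatin
  expect_equal(fractional_effect(80, ator$model), 0.5457, tolerance = 1e-3)
  expect_error(fractional_effect(-1, ba_mono), "non-negative")
})

test_that("dose-response is monotone and bounded by emax", {
  set.seed(11)
  for (i in 1:20) {
    m <- emax_model(runif(1, 0.05, 0.95), runif(1, 1, 150), runif(1, 0.3, 3))
    d <- sort(runif(50, 0, 500))
    e <- fractional_effect(d, m)
    expect_true(all(diff(e) > 0))
    expect_true(all(e < m$emax))
    expect_true(all(e >= 0))
  }
})

test_that("combination algebra: limits, less-than-additive, dominance", {
  e_ba <- fractional_effect(180, ba_model(context = "combination"))
  # monotherapy limits
  expect_equal(combined_effect(e_ba, 0, -1.35), e_ba)
  expect_equal(combined_effect(0, 0.431, -1.35), 0.431)
  # frozen anchor cells
  expect_equal(combined_effect(0.273, 0.431, -1.35), 0.545, tolerance = 2e-3)
  expect_equal(round(-100 * combined_effect(0.273, 0.297, -1.35)), -46)
  # gamma 0 is additive on the fraction scale
  expect_equal(combined_effect(0.2, 0.3, 0), 0.5)
  profs <- statin_profiles()
  for (p in profs) {
    e_st <- fractional_effect(p$dose_grid, p$model)
    e_tot <- combined_effect(rep(e_ba, length(e_st)), e_st, -1.35)
    # less than additive for negative gamma, but never below either drug
    expect_true(all(e_tot < e_ba + e_st))
    expect_true(all(e_tot >= pmax(e_ba, e_st)))
  }
  expect_warning(out <- combined_effect(0.6, 0.6, -10), "clamped")
  expect_identical(out, 0)
  expect_error(combined_effect(1.2, 0.3, -1.35), "\\[0, 1\\)")
})

test_that("reconstructed interaction reproduces every printed combination cell", {
  tab <- printed_table3()
  profs <- statin_profiles()
  e_ba <- fractional_effect(180, ba_model(context = "combination"))
  for (i in seq_len(nrow(tab))) {
    p <- profs[[tab$statin[i]]]
    e_st <- fractional_effect(tab$dose[i], p$model)
    expect_lt(abs(percent_change(e_st) - tab$alone[i]), 1)
    expect_lt(abs(percent_change(combined_effect(e_ba, e_st, -1.35)) -
                    tab$combo[i]), 1)
  }
})

test_that("turnover time course follows the first-order indirect model", {
  tv <- turnover_model(147.1, 0.01)
  expect_equal(tv$kin, 1.471)
  expect_identical(ldl_timecourse(tv, 0.4, 0), 147.1)
  # half-expression at t = ln(2)/kout (analytic solution of the linear ODE)
  t_half <- log(2) / 0.01
  expect_equal(ldl_timecourse(tv, 0.4, t_half),
               147.1 * (1 - 0.4 * 0.5), tolerance = 1e-12)
  # week 12 is steady state to < 1e-6 relative
  ss <- 147.1 * (1 - 0.4)
  expect_lt(abs(ldl_timecourse(tv, 0.4, 2016) - ss) / ss, 1e-6)
  # monotone approach to steady state
  path <- ldl_timecourse(tv, 0.4, seq(0, 2000, by = 50))
  expect_true(all(diff(path) < 0))
})

test_that("closed-form time course matches an independent ODE solution", {
  skip_if_not_installed("deSolve")
  tv <- turnover_model(160, 0.01)
  e <- 0.35
  times <- c(0, 24, 168, 504, 1008, 2016)
  ode <- deSolve::ode(y = c(L = 160), times = times,
                      func = function(t, y, parms)
                        list(tv$kin * (1 - e) - tv$kout * y[1]),
                      rtol = 1e-10, atol = 1e-10)
  expect_equal(unname(ode[, "L"]), ldl_timecourse(tv, e, times),
               tolerance = 1e-7)
})

test_that("added-effect formula matches the printed delta convention", {
  expect_equal(delta_added_effect(-51, -37), -14 / 0.63, tolerance = 1e-12)
  expect_equal(round(delta_added_effect(-51, -37)), -22)
  expect_equal(round(delta_added_effect(-62, -54)), -17)
  # no background statin: the combination percent passes through
  expect_identical(delta_added_effect(-27, 0), -27)
  expect_error(delta_added_effect(-50, -100), "-100")
})

test_that("percent and unit conversions follow the reporting conventions", {
  expect_identical(percent_change(0), 0)
  expect_identical(percent_change(0.5), -50)
  expect_error(percent_change(1.2), "\\[0, 1\\)")
  expect_identical(mgdl_to_mmoll(132.7), 3.4)
  expect_identical(mgdl_to_mmoll(183.1), 4.7)
  expect_identical(mgdl_to_mmoll(0), 0)
  expect_equal(mgdl_to_mmoll(100, digits = NULL), 100 / 38.67)
  expect_error(mgdl_to_mmoll(-5), "non-negative")
})

test_that("model constructors reject invalid parameters", {
  expect_error(emax_model(1.2, 44), "emax")
  expect_error(emax_model(0.3, -2), "ed50")
  expect_error(emax_model(0.3, 44, 0), "hill")
  expect_error(turnover_model(-10), "baseline")
  expect_error(statin_profile("lovastatin", ba_mono, 80, c(10, 20)))
})
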