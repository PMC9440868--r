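pop_ator <- function() {
  p <- study_population("atorvastatin")
  p$omega_emax <- 0
  p
}

test_that("baseline draws are log-normal with the documented moments", {
  pop <- pop_ator()
  s <- draw_subjects(1e5, pop, seed = 4)
  sdlog <- sqrt(log(1 + pop$omega_baseline^2))
  # mean of a log-normal with median m: m * exp(sdlog^2 / 2)
  expected <- pop$baseline_typical * exp(sdlog^2 / 2)
  mc_se <- expected * pop$omega_baseline / sqrt(1e5)
  expect_lt(abs(mean(s$baseline) - expected), 4 * mc_se)
  expect_equal(median(s$baseline), pop$baseline_typical,
               tolerance = 4 * pop$omega_baseline / sqrt(1e5) * 1.5)
})

test_that("draws are reproducible under seed and degenerate without variability", {
  pop <- study_population("ba_monotherapy")
  expect_identical(draw_subjects(5, pop, seed = 9),
                   draw_subjects(5, pop, seed = 9))
  one <- draw_subjects(1, pop, seed = 3)
  expect_identical(one, draw_subjects(1, pop, seed = 3))
  flat <- population_params(150, 0, 0)
  s <- draw_subjects(10, flat, seed = 1)
  expect_true(all(s$baseline == 150))
  expect_true(all(s$emax_mult == 1))
})

test_that("null condition returns the baseline; effects compose as modelled", {
  s <- draw_subjects(50, pop_ator(), seed = 2)
  null <- simulate_condition(s, statin_dose = 0, ba_dose = 0)
  expect_equal(null$ldl_week12, s$baseline)
  expect_true(all(null$pct_change == 0))
  ator <- statin_profiles()$atorvastatin
  sim <- simulate_condition(s, ator, 40, 180)
  e_exp <- combined_effect(fractional_effect(180, ba_model(context = "combination")),
                           fractional_effect(40, ator$model), -1.35)
  expect_equal(unique(round(sim$e_total, 12)), round(e_exp, 12))
  expect_equal(sim$ldl_week12, s$baseline * (1 - e_exp))
  expect_error(simulate_condition(s, statin = "atorvastatin", statin_dose = 40),
               "statin_profile")
  expect_error(simulate_condition(s, statin_dose = 40), "statin")
})

test_that("percent change is scale-free in baseline; absolute LDL-C scales", {
  p1 <- population_params(150, 0.25, 0.3)
  p2 <- population_params(300, 0.25, 0.3)
  s1 <- draw_subjects(200, p1, seed = 7)
  s2 <- draw_subjects(200, p2, seed = 7)
  a <- simulate_condition(s1, ba_dose = 180)
  b <- simulate_condition(s2, ba_dose = 180)
  expect_equal(a$pct_change, b$pct_change)
  expect_equal(b$ldl_week12, 2 * a$ldl_week12)
})

test_that("target attainment is monotone and dominated by adding bempedoic acid", {
  s <- draw_subjects(400, pop_ator(), seed = 5)
  all150 <- s; all150$ldl_week12 <- rep(150, 400)
  expect_equal(unname(target_attainment(all150)), c(0, 0))
  all50 <- s; all50$ldl_week12 <- rep(50, 400)
  expect_equal(unname(target_attainment(all50)), c(1, 1))
  ator <- statin_profiles()$atorvastatin
  for (d in ator$dose_grid) {
    att0 <- target_attainment(simulate_condition(s, ator, d, 0))
    att1 <- target_attainment(simulate_condition(s, ator, d, 180))
    expect_lte(att0[["lt70"]], att0[["lt100"]])
    expect_lte(att1[["lt70"]], att1[["lt100"]])
    expect_gte(att1[["lt100"]], att0[["lt100"]])
    expect_gte(att1[["lt70"]], att0[["lt70"]])
  }
  expect_error(target_attainment(s), "outcomes")
})

test_that("degenerate summaries collapse to the deterministic prediction", {
  flat <- population_params(177.9, 0, 0)
  s <- draw_subjects(10, flat, seed = 1)
  sim <- simulate_condition(s, ba_dose = 180)
  summ <- summarize_condition(sim, replicate_means = mean(sim$pct_change))
  point <- percent_change(fractional_effect(180, ba_model(context = "combination")))
  expect_equal(summ$pct_mean, point, tolerance = 1e-12)
  expect_equal(summ$pct_lo, summ$pct_hi)   # zero-width interval
  expect_equal(summ$ldl_mean, 177.9 * (1 + point / 100), tolerance = 1e-9)
})

test_that("residual layer adds observation noise reproducibly", {
  pop <- study_population("ba_monotherapy")
  s <- draw_subjects(500, pop, seed = 8)
  clean <- simulate_condition(s, ba_dose = 180)
  noisy1 <- simulate_condition(s, ba_dose = 180, residual = TRUE, seed = 21)
  noisy2 <- simulate_condition(s, ba_dose = 180, residual = TRUE, seed = 21)
  expect_identical(noisy1$ldl_week12, noisy2$ldl_week12)
  expect_gt(sd(noisy1$ldl_week12 - clean$ldl_week12), 0)
  # noise is centred: mean shift within Monte-Carlo error
  resid_sd <- sqrt((pop$residual_proportional * mean(clean$ldl_week12))^2 +
                     pop$residual_additive^2)
  expect_lt(abs(mean(noisy1$ldl_week12) - mean(clean$ldl_week12)),
            4 * resid_sd / sqrt(500))
})
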