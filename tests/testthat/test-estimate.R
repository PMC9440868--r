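theta_true <- function() {
  p <- model_parameters()$bempedoic_acid$monotherapy
  list(baseline = p$baseline, emax = p$emax, ed50 = p$ed50, hill = 1,
       omega_baseline = sqrt(log(1 + p$iiv_baseline^2)),
       omega_emax = sqrt(log(1 + p$iiv_emax^2)),
       prop = p$residual_proportional, add = p$residual_additive, gamma = 0)
}

test_that("likelihood matches the hand-computed residual density", {
  dat <- data.frame(subject_id = 1L, statin = "none", statin_dose = 0,
                    ba_dose = 180, week = 12, ldl = 110)
  th <- list(baseline = 147.1, emax = 0.34, ed50 = 44, hill = 1,
             prop = 0.084, add = 11.4, gamma = 0)
  f <- 147.1 * (1 - 0.34 * 180 / 224)
  v <- (0.084 * f)^2 + 11.4^2
  by_hand <- 0.5 * (log(2 * pi * v) + (110 - f)^2 / v)
  expect_equal(negloglik(dat, fit_spec(iiv = character()), th), by_hand,
               tolerance = 1e-10)
})

test_that("objective is invariant to subject relabelling and record order", {
  dat <- generate_trial(preset_designs()$monotherapy_dose_ranging,
                        seed = 31)
  dat <- dat[dat$subject_id %in% unique(dat$subject_id)[1:120], ]
  spec <- fit_spec()
  th <- theta_true()
  v0 <- negloglik(dat, spec, th)
  shuffled <- dat[sample(nrow(dat)), ]
  expect_equal(negloglik(shuffled, spec, th), v0, tolerance = 1e-8)
  relabelled <- dat
  ids <- unique(dat$subject_id)
  relabelled$subject_id <- match(dat$subject_id, rev(ids)) + 5000L
  expect_equal(negloglik(relabelled, spec, th), v0, tolerance = 1e-8)
})

test_that("Laplace marginal likelihood agrees with Gauss-Hermite quadrature", {
  dat <- generate_trial(preset_designs()$monotherapy_dose_ranging, seed = 33)
  dat <- dat[dat$subject_id %in% unique(dat$subject_id)[seq(1, 1000, by = 12)], ]
  th <- theta_true()
  lap <- negloglik(dat, fit_spec(), th)
  gh <- gh_marginal_nll(dat, th, n_nodes = 40)
  expect_equal(lap, gh, tolerance = 2e-3)
  # also under a perturbed parameter set (not at the generating values)
  th2 <- th; th2$emax <- 0.45; th2$ed50 <- 70; th2$omega_baseline <- 0.3
  expect_equal(negloglik(dat, fit_spec(), th2), gh_marginal_nll(dat, th2, 40),
               tolerance = 2e-3)
})

test_that("noiseless data is minimised at the generating parameters", {
  des <- trial_design(data.frame(statin = "none", statin_dose = 0,
                                 ba_dose = c(0, 20, 60, 120, 180, 240),
                                 n = 40), name = "exact")
  dat <- generate_trial(des, seed = 1, residual = 0, iiv = 0)
  spec0 <- fit_spec(iiv = character())
  th <- theta_true()
  th$prop <- 1e-3; th$add <- 1e-2    # residual-to-zero limit
  at_truth <- negloglik(dat, spec0, th)
  for (fac in c(0.9, 1.1)) {
    for (par in c("baseline", "emax", "ed50")) {
      th2 <- th; th2[[par]] <- th[[par]] * fac
      expect_gt(negloglik(dat, spec0, th2), at_truth)
    }
  }
})

test_that("non-finite parameter regions are penalised, not fatal", {
  dat <- data.frame(subject_id = 1:2, statin = "none", statin_dose = 0,
                    ba_dose = c(0, 180), week = 12, ldl = c(150, 110))
  spec <- fit_spec(iiv = character())
  th <- theta_true(); th$ed50 <- -1
  expect_identical(negloglik(dat, spec, th), 1e10)
  th <- theta_true(); th$emax <- 1.4
  expect_identical(negloglik(dat, spec, th), 1e10)
})

test_that("design degeneracy raises a structured identifiability error", {
  dat <- data.frame(subject_id = 1:10, statin = "none", statin_dose = 0,
                    ba_dose = 180, week = 12, ldl = rnorm(10, 110, 5))
  expect_error(fit_monotherapy(dat), class = "ldlemax_unidentifiable")
})

test_that("monotherapy fit recovers generating values with calibrated CIs", {
  dat <- generate_trial(preset_designs()$monotherapy_rich, seed = 42)
  fit <- fit_monotherapy(dat, fit_spec(n_starts = 1))
  expect_true(fit$convergence)
  th <- theta_true()
  # point estimates in the right neighbourhood
  expect_lt(abs(fit$estimates[["emax"]] - th$emax) / th$emax, 0.15)
  expect_lt(abs(fit$estimates[["ed50"]] - th$ed50) / th$ed50, 0.25)
  # 95% CIs bracket the estimates and cover the generating values
  expect_true(all(fit$ci[, "lower"] < fit$estimates &
                    fit$estimates < fit$ci[, "upper"]))
  expect_true(fit$ci["emax", "lower"] < th$emax &&
                th$emax < fit$ci["emax", "upper"])
  expect_true(fit$ci["ed50", "lower"] < th$ed50 &&
                th$ed50 < fit$ci["ed50", "upper"])
  expect_true(all(fit$se[!is.na(fit$se)] >= 0))
  # precision grows with n: CI width shrinks against a quarter-size fit
  small <- dat[dat$subject_id %in% unique(dat$subject_id)[seq(1, 1002, 4)], ]
  fit_small <- fit_monotherapy(small, fit_spec(n_starts = 1))
  expect_lt(diff(fit$ci["ed50", ]), diff(fit_small$ci["ed50", ]))
})

test_that("sigmoid variant on simple-Emax data keeps hill compatible with 1", {
  des <- preset_designs()$monotherapy_rich
  des$arms$n <- 80
  dat <- generate_trial(des, seed = 55)
  fit <- fit_monotherapy(dat, fit_spec(free_hill = TRUE, n_starts = 1))
  expect_true(fit$ci["hill", "lower"] < 1 && 1 < fit$ci["hill", "upper"])
})

test_that("gamma profiling recovers the null and degenerate grids", {
  des <- trial_design(data.frame(statin = "atorvastatin",
                                 statin_dose = c(10, 40), ba_dose = 180,
                                 n = 250), name = "null-gamma")
  p <- model_parameters()
  p$statin_shared$gamma <- 0            # generate additive data
  dat <- generate_trial(des, p, seed = 61)
  pr <- profile_gamma(dat, gamma_grid = seq(-1, 1, by = 0.1))
  expect_lt(abs(pr$gamma_hat), 0.25)
  one <- profile_gamma(dat, gamma_grid = -0.5)
  expect_identical(one$gamma_hat, -0.5)
  expect_error(profile_gamma(dat, gamma_grid = numeric()), "empty")
  mono <- generate_trial(preset_designs()$monotherapy_dose_ranging, seed = 1)
  expect_error(profile_gamma(mono), "combination")
})
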