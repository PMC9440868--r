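#' Draw a simulated patient population
#'
#' Draws individual baselines log-normally (median `baseline_typical`,
#' coefficient of variation `omega_baseline`, so `sdlog =
#' sqrt(log(1 + CV^2))`) and, when `omega_emax > 0`, an individual
#' multiplier `exp(eta)` on the bempedoic acid maximal effect with
#' `eta ~ N(0, log(1 + CV^2))`. Results are reproducible under a fixed
#' seed; the caller's RNG state is left untouched.
#'
#' @param n Number of subjects, >= 1.
#' @param pop A [population_params()] object.
#' @param seed Integer seed; `NULL` uses (and advances) the session RNG.
#' @return A data.frame of class `simulated_subjects` with columns
#'   `subject_id`, `baseline`, `emax_mult`.
#' @export
draw_subjects <- function(n, pop, seed = NULL) {
  stopifnot(inherits(pop, "population_params"))
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("`n` must be a positive count", call. = FALSE)
  n <- as.integer(n)
  draw <- function() {
    sd_b <- sqrt(log(1 + pop$omega_baseline^2))
    sd_e <- sqrt(log(1 + pop$omega_emax^2))
    data.frame(
      subject_id = seq_len(n),
      baseline = pop$baseline_typical * exp(stats::rnorm(n, 0, sd_b)),
      emax_mult = exp(stats::rnorm(n, 0, sd_e))
    )
  }
  out <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  class(out) <- c("simulated_subjects", "data.frame")
  attr(out, "pop") <- pop
  out
}

#' Apply a dosing condition to simulated subjects
#'
#' Computes each subject's total fractional effect and week-12 LDL-C under
#' a statin dose, a bempedoic acid dose, or both. Week 12 is evaluated with
#' the steady-state algebra (`baseline * (1 - e_total)`); with `kout =
#' 0.01/h` the transient term at 2016 h is below 1e-8 relative. The
#' individual bempedoic acid effect uses `emax * emax_mult`, clamped so the
#' total fraction stays below 1.
#'
#' @param subjects A [draw_subjects()] data.frame.
#' @param statin A [statin_profile()], or `NULL` for no statin.
#' @param statin_dose Statin dose (mg), 0 allowed.
#' @param ba_dose Bempedoic acid dose (mg), 0 allowed.
#' @param gamma Interaction coefficient used when both doses are positive.
#' @param ba [emax_model()] for bempedoic acid.
#' @param residual Add observation-level residual error (proportional +
#'   additive, magnitudes from the subjects' population)? Default `FALSE`:
#'   the prediction tables describe model-predicted LDL-C, not noisy
#'   observations.
#' @param seed Seed for the residual layer (ignored when `residual =
#'   FALSE`).
#' @return `subjects` with columns `e_total`, `ldl_week12`, `pct_change`
#'   added.
#' @export
simulate_condition <- function(subjects, statin = NULL, statin_dose = 0,
                               ba_dose = 0, gamma = -1.35,
                               ba = ba_model(context = "combination"),
                               residual = FALSE, seed = NULL) {
  stopifnot(inherits(subjects, "simulated_subjects"),
            statin_dose >= 0, ba_dose >= 0)
  if (statin_dose > 0 && is.null(statin))
    stop("`statin` must be supplied when `statin_dose` > 0", call. = FALSE)
  if (!is.null(statin) && !inherits(statin, "statin_profile"))
    stop("unknown statin: supply a statin_profile", call. = FALSE)

  e_st <- if (statin_dose > 0) fractional_effect(statin_dose, statin$model) else 0
  g_ba <- if (ba_dose > 0) fractional_effect(ba_dose, ba) / ba$emax else 0
  e_ba <- pmin(ba$emax * subjects$emax_mult * g_ba, 1 - 1e-9)
  e_tot <- combined_effect(e_ba, rep(e_st, nrow(subjects)), gamma)

  out <- subjects
  out$e_total <- e_tot
  out$ldl_week12 <- subjects$baseline * (1 - e_tot)
  if (residual) {
    pop <- attr(subjects, "pop")
    noise <- function() {
      f <- out$ldl_week12
      pmax(f * (1 + stats::rnorm(length(f), 0, pop$residual_proportional)) +
             stats::rnorm(length(f), 0, pop$residual_additive), 1e-6)
    }
    out$ldl_week12 <- if (is.null(seed)) noise() else withr::with_seed(seed, noise())
  }
  out$pct_change <- 100 * (out$ldl_week12 - subjects$baseline) / subjects$baseline
  attr(out, "condition") <- list(statin = if (is.null(statin)) "none" else statin$name,
                                 statin_dose = statin_dose, ba_dose = ba_dose,
                                 gamma = gamma, residual = residual)
  out
}

#' Proportion of subjects attaining LDL-C targets
#'
#' Strict-inequality attainment: the proportion of simulated week-12 LDL-C
#' values below each threshold. Defaults to the guideline targets of
#' 100 mg/dL (2.6 mmol/L) and 70 mg/dL (1.8 mmol/L).
#'
#' @param subjects Output of [simulate_condition()] (needs `ldl_week12`).
#' @param thresholds Positive thresholds (mg/dL).
#' @return Named numeric vector of proportions, one per threshold.
#' @export
target_attainment <- function(subjects, thresholds = c(100, 70)) {
  stopifnot(is.numeric(thresholds), all(thresholds > 0))
  if (is.null(subjects$ldl_week12))
    stop("`subjects` has no simulated outcomes; run simulate_condition()",
         call. = FALSE)
  out <- vapply(thresholds, function(th) mean(subjects$ldl_week12 < th),
                numeric(1))
  names(out) <- paste0("lt", thresholds)
  out
}

#' Summarise one simulated dosing condition
#'
#' Mean percent change, mean absolute week-12 LDL-C, target-attainment
#' proportions and a 90% interval. The interval is the empirical 5th-95th
#' percentile range of bootstrap replicate means when `replicate_means` is
#' supplied; with a single degenerate replicate the width is 0.
#'
#' @param subjects Output of [simulate_condition()].
#' @param replicate_means Optional vector of per-replicate mean percent
#'   changes from a bootstrap loop; `NULL` reports the point mean with an
#'   `NA` interval.
#' @param thresholds Attainment thresholds (mg/dL).
#' @return A one-row data.frame of class `condition_summary`.
#' @export
summarize_condition <- function(subjects, replicate_means = NULL,
                                thresholds = c(100, 70)) {
  if (is.null(subjects$pct_change))
    stop("`subjects` has no simulated outcomes; run simulate_condition()",
         call. = FALSE)
  cond <- attr(subjects, "condition")
  m <- mean(subjects$pct_change)
  if (is.null(replicate_means)) {
    lo <- hi <- NA_real_
  } else {
    stopifnot(length(replicate_means) >= 1)
    q <- stats::quantile(replicate_means, c(0.05, 0.95), names = FALSE, type = 7)
    lo <- q[1]; hi <- q[2]
  }
  att <- target_attainment(subjects, thresholds)
  out <- data.frame(statin = cond$statin, statin_dose = cond$statin_dose,
                    ba_dose = cond$ba_dose,
                    pct_mean = m, pct_lo = lo, pct_hi = hi,
                    ldl_mean = mean(subjects$ldl_week12))
  for (nm in names(att)) out[[nm]] <- att[[nm]]
  class(out) <- c("condition_summary", "data.frame")
  out
}
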