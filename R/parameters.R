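#' Load the shipped dose-response parameter fixtures
#'
#' Reads the packaged parameter file (typical values, fixed parameters,
#' standard errors, variability and residual-error magnitudes for bempedoic
#' acid monotherapy and the four statin combination models) and returns it
#' as a nested list. Effects in the file are stored as positive fractions
#' lowered; variability CVs as fractions.
#'
#' @param file Path to a YAML parameter file; defaults to the packaged
#'   fixture.
#' @return A list of class `ldl_params` with elements `bempedoic_acid`,
#'   `statin_shared` and `statins`, plus attributes `file` and `md5` used as
#'   provenance by the report writers.
#' @export
model_parameters <- function(file = system.file("extdata", "model_parameters.yaml",
                                                package = "ldlemax")) {
  if (!nzchar(file) || !file.exists(file))
    stop("parameter file not found: ", file, call. = FALSE)
  p <- yaml::read_yaml(file)
  needed <- c("bempedoic_acid", "statin_shared", "statins")
  if (!all(needed %in% names(p)))
    stop("parameter file is missing sections: ",
         paste(setdiff(needed, names(p)), collapse = ", "), call. = FALSE)
  structure(p, class = "ldl_params",
            file = file, md5 = unname(tools::md5sum(file)))
}

#' @export
print.ldl_params <- function(x, ...) {
  cat("LDL-C dose-response parameter set\n")
  m <- x$bempedoic_acid$monotherapy
  cat(sprintf("  bempedoic acid: emax %.2f, ED50 %.1f mg (monotherapy)\n",
              m$emax, m$ed50))
  cat(sprintf("  statins (%s): shared emax %.3f, hill %.3f, gamma %.2f\n",
              paste(names(x$statins), collapse = ", "),
              x$statin_shared$emax, x$statin_shared$hill, x$statin_shared$gamma))
  invisible(x)
}

#' Bempedoic acid Emax model from the fixtures
#'
#' @param params A [model_parameters()] list.
#' @param context `"monotherapy"` (ED50 44.0 mg) or `"combination"`
#'   (ED50 43.96 mg, as fixed in the combination models).
#' @return An [emax_model()].
#' @export
ba_model <- function(params = model_parameters(),
                     context = c("monotherapy", "combination")) {
  context <- match.arg(context)
  q <- params$bempedoic_acid[[context]]
  emax_model(emax = q$emax, ed50 = q$ed50, hill = q$hill)
}

#' Statin dose-response profiles from the fixtures
#'
#' @param params A [model_parameters()] list.
#' @return Named list of [statin_profile()] objects sharing emax and hill,
#'   each with its own ED50 and report dose grid.
#' @export
statin_profiles <- function(params = model_parameters()) {
  sh <- params$statin_shared
  out <- lapply(names(params$statins), function(nm) {
    s <- params$statins[[nm]]
    statin_profile(nm,
                   emax_model(emax = sh$emax, ed50 = s$ed50, hill = sh$hill),
                   max_label_dose = s$max_label_dose,
                   dose_grid = unlist(s$dose_grid))
  })
  names(out) <- names(params$statins)
  out
}

#' Combination interaction model for one statin
#'
#' @param statin Statin name or a [statin_profile()].
#' @param params A [model_parameters()] list.
#' @return An [interaction_model()] with drug A = bempedoic acid
#'   (combination-model parameters) and drug B = the statin, using the
#'   common fixed interaction coefficient.
#' @export
combination_model <- function(statin, params = model_parameters()) {
  if (is.character(statin)) statin <- statin_profiles(params)[[statin]]
  stopifnot(inherits(statin, "statin_profile"))
  interaction_model(ba_model(params, "combination"), statin$model,
                    gamma = params$statin_shared$gamma)
}

#' Population parameters for simulation
#'
#' Typical baseline plus the random-effect and residual magnitudes needed
#' to simulate individual patients. Variability is log-normal: baselines
#' have median `baseline_typical` and coefficient of variation
#' `omega_baseline`; the individual bempedoic acid emax is multiplied by
#' `exp(eta)` with CV `omega_emax` (0 disables it, as in the combination
#' models, which report baseline variability only).
#'
#' @param baseline_typical Median baseline LDL-C (mg/dL).
#' @param omega_baseline CV fraction of the baseline distribution.
#' @param omega_emax CV fraction on the bempedoic acid maximal effect.
#' @param residual_proportional,residual_additive Residual-error magnitudes
#'   (fraction and mg/dL) used when observation noise is requested.
#' @return An object of class `population_params`.
#' @export
population_params <- function(baseline_typical, omega_baseline,
                              omega_emax = 0,
                              residual_proportional = 0,
                              residual_additive = 0) {
  stopifnot(baseline_typical > 0, omega_baseline >= 0, omega_emax >= 0,
            residual_proportional >= 0, residual_additive >= 0)
  structure(list(baseline_typical = baseline_typical,
                 omega_baseline = omega_baseline,
                 omega_emax = omega_emax,
                 residual_proportional = residual_proportional,
                 residual_additive = residual_additive),
            class = "population_params")
}

#' @export
print.population_params <- function(x, ...) {
  cat(sprintf(paste0("Population: baseline median %.1f mg/dL (CV %.1f%%), ",
                     "emax CV %.1f%%, residual %.1f%% + %.1f mg/dL\n"),
              x$baseline_typical, 100 * x$omega_baseline, 100 * x$omega_emax,
              100 * x$residual_proportional, x$residual_additive))
  invisible(x)
}

#' Population parameters for a named study population
#'
#' `"ba_monotherapy"` gives the monotherapy population (baseline 147.1
#' mg/dL, baseline and emax variability, monotherapy residual error); a
#' statin name gives that combination-study population (statin-specific
#' baseline and variability, no emax variability). The atorvastatin
#' population is the common baseline used for the cross-statin prediction
#' tables.
#'
#' @param which `"ba_monotherapy"` or a statin name.
#' @param params A [model_parameters()] list.
#' @return A [population_params()] object.
#' @export
study_population <- function(which = c("ba_monotherapy", "atorvastatin",
                                       "simvastatin", "rosuvastatin",
                                       "pravastatin"),
                             params = model_parameters()) {
  which <- match.arg(which)
  if (which == "ba_monotherapy") {
    m <- params$bempedoic_acid$monotherapy
    population_params(m$baseline, m$iiv_baseline, m$iiv_emax,
                      m$residual_proportional, m$residual_additive)
  } else {
    s <- params$statins[[which]]
    population_params(s$baseline, s$iiv_baseline, 0,
                      s$residual_proportional, s$residual_additive)
  }
}
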