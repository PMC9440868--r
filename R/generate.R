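#' Define a synthetic trial design
#'
#' A design is a set of arms (statin, statin dose, bempedoic acid dose,
#' subjects per arm, study label) plus a visit schedule. Visit weeks must
#' include the entry visit (0) and the primary endpoint week (12).
#'
#' @param arms data.frame with columns `statin` (name or `"none"`),
#'   `statin_dose`, `ba_dose`, `n`, and optionally `study` (label only; no
#'   study-level random effect is simulated, matching the fitted model).
#' @param weeks Visit weeks; must contain 0 and 12.
#' @param name Design label.
#' @return An object of class `trial_design`.
#' @export
trial_design <- function(arms, weeks = c(0, 12), name = "custom") {
  needed <- c("statin", "statin_dose", "ba_dose", "n")
  if (!is.data.frame(arms) || !all(needed %in% names(arms)))
    stop("`arms` needs columns: ", paste(needed, collapse = ", "), call. = FALSE)
  if (any(arms$n < 1)) stop("every arm needs n >= 1", call. = FALSE)
  if (!all(c(0, 12) %in% weeks))
    stop("`weeks` must include baseline (0) and week 12", call. = FALSE)
  if (is.null(arms$study)) arms$study <- "SYN-1"
  structure(list(arms = arms, weeks = sort(unique(weeks)), name = name),
            class = "trial_design")
}

#' @export
print.trial_design <- function(x, ...) {
  cat(sprintf("Trial design '%s': %d arms, %d subjects, weeks %s\n",
              x$name, nrow(x$arms), sum(x$arms$n),
              paste(x$weeks, collapse = "/")))
  invisible(x)
}

#' Generate a synthetic subject-level trial dataset
#'
#' Emulates the statistical structure the dose-response analysis assumes:
#' log-normal individual baselines, log-normal variability on the
#' bempedoic acid maximal effect (monotherapy population), and combined
#' proportional + additive residual error on every observation,
#' `y = f * (1 + eps_prop) + eps_add`. Subjects in combination arms are
#' "on statin at entry": their week-0 record is the on-statin baseline
#' (statin effect already expressed, bempedoic acid dose 0), so the
#' imputation stage receives realistic input. Record-level `statin_dose`
#' and `ba_dose` columns give the doses governing each observation.
#'
#' @param design A [trial_design()].
#' @param params A [model_parameters()] list.
#' @param seed Integer seed (the generator is fully reproducible under it).
#' @param residual Scale factor on both residual-error magnitudes (1 =
#'   population values, 0 = noiseless observations).
#' @param iiv Scale factor on both variability CVs (0 disables
#'   inter-individual variability).
#' @return Long-format data.frame with columns `subject_id`, `study`,
#'   `statin`, `statin_dose`, `ba_dose`, `week`, `ldl`, `on_statin_entry`.
#' @export
generate_trial <- function(design, params = model_parameters(), seed = NULL,
                           residual = 1, iiv = 1) {
  stopifnot(inherits(design, "trial_design"), residual >= 0, iiv >= 0)
  if (!is.null(seed))
    return(withr::with_seed(seed, generate_trial(design, params, seed = NULL,
                                                 residual = residual, iiv = iiv)))
  profiles <- statin_profiles(params)
  gamma <- params$statin_shared$gamma
  ba_mono <- ba_model(params, "monotherapy")
  ba_comb <- ba_model(params, "combination")
  arms <- design$arms
  out <- vector("list", nrow(arms))
  next_id <- 0L
  for (a in seq_len(nrow(arms))) {
    st_name <- arms$statin[a]
    on_statin <- !identical(st_name, "none") && arms$statin_dose[a] > 0
    pop <- if (on_statin) study_population(st_name, params)
           else study_population("ba_monotherapy", params)
    pop$omega_baseline <- pop$omega_baseline * iiv
    pop$omega_emax <- pop$omega_emax * iiv
    n <- arms$n[a]
    subj <- draw_subjects(n, pop)
    ba <- if (on_statin) ba_comb else ba_mono
    e_st <- if (on_statin)
      fractional_effect(arms$statin_dose[a], profiles[[st_name]]$model) else 0
    rows <- vector("list", length(design$weeks))
    for (w in seq_along(design$weeks)) {
      week <- design$weeks[w]
      # at entry only the stable statin is on board; on-treatment visits are
      # taken at steady state of the assigned condition
      ba_dose_w <- if (week == 0) 0 else arms$ba_dose[a]
      e_ba <- if (ba_dose_w > 0)
        pmin(ba$emax * subj$emax_mult * ba_dose_w / (ba$ed50 + ba_dose_w),
             1 - 1e-9) else rep(0, n)
      e_tot <- combined_effect(e_ba, rep(e_st, n), gamma)
      f <- subj$baseline * (1 - e_tot)
      y <- f * (1 + stats::rnorm(n, 0, residual * pop$residual_proportional)) +
        stats::rnorm(n, 0, residual * pop$residual_additive)
      rows[[w]] <- data.frame(
        subject_id = next_id + subj$subject_id,
        study = arms$study[a],
        statin = st_name,
        statin_dose = if (on_statin) arms$statin_dose[a] else 0,
        ba_dose = ba_dose_w,
        week = week,
        ldl = pmax(y, 1),
        on_statin_entry = on_statin
      )
    }
    out[[a]] <- do.call(rbind, rows)
    next_id <- next_id + as.integer(n)
  }
  out <- do.call(rbind, out)
  out <- out[order(out$subject_id, out$week), ]
  rownames(out) <- NULL
  out
}

#' Shipped synthetic trial designs
#'
#' Named presets emulating the pooled development program:
#' \describe{
#'   \item{monotherapy_dose_ranging}{bempedoic acid 0/60/120/180/240 mg,
#'     200 subjects per arm.}
#'   \item{monotherapy_rich}{adds a 20 mg arm below the half-maximal dose
#'     so that ED50 is well identified in recovery studies (the plain
#'     dose-ranging grid starts above ED50).}
#'   \item{combination_per_statin}{each statin's labelled dose grid with
#'     bempedoic acid 180 mg on top, 100 subjects per arm; no simvastatin
#'     or rosuvastatin 80 mg arm (outside their supported grids).}
#'   \item{pooled_phase3_like}{placebo and bempedoic acid 180 mg on
#'     background atorvastatin 20/40 mg, 250 subjects per arm.}
#' }
#' The function is pure: repeated calls return identical structures.
#'
#' @param params A [model_parameters()] list (supplies the dose grids).
#' @return Named list of [trial_design()] objects.
#' @export
preset_designs <- function(params = model_parameters()) {
  mono <- function(doses, n, nm) trial_design(
    data.frame(statin = "none", statin_dose = 0, ba_dose = doses, n = n,
               study = sprintf("PH2-%02d", seq_along(doses))),
    name = nm)
  profs <- statin_profiles(params)
  comb_arms <- do.call(rbind, lapply(profs, function(p) {
    do.call(rbind, lapply(p$dose_grid, function(d)
      data.frame(statin = p$name, statin_dose = d, ba_dose = c(0, 180),
                 n = 100, study = paste0("CMB-", toupper(substr(p$name, 1, 4))))))
  }))
  rownames(comb_arms) <- NULL
  list(
    monotherapy_dose_ranging = mono(c(0, 60, 120, 180, 240), 200,
                                    "monotherapy_dose_ranging"),
    monotherapy_rich = mono(c(0, 20, 60, 120, 180, 240), 167,
                            "monotherapy_rich"),
    combination_per_statin = trial_design(comb_arms,
                                          name = "combination_per_statin"),
    pooled_phase3_like = trial_design(
      data.frame(statin = "atorvastatin", statin_dose = c(20, 20, 40, 40),
                 ba_dose = c(0, 180, 0, 180), n = 250, study = "PH3-1"),
      name = "pooled_phase3_like")
  )
}

#' Read and write trial datasets
#'
#' Long-format comma-separated text with a header row; missing values are
#' empty fields. The round trip is lossless to full double precision
#' (values are written with 17 significant digits).
#'
#' @param dataset A trial data.frame as produced by [generate_trial()].
#' @param path File path.
#' @return `write_trial_data()` returns `path` invisibly;
#'   `read_trial_data()` the data.frame.
#' @export
write_trial_data <- function(dataset, path) {
  df <- dataset
  df$ldl <- sprintf("%.17g", df$ldl)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trial_data
#' @export
read_trial_data <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(subject_id = "integer",
                                        statin = "character"))
  out$on_statin_entry <- as.logical(out$on_statin_entry)
  out
}
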