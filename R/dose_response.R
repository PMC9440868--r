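#' Emax dose-response model for a single drug
#'
#' Constructs the saturating dose-response model
#' \deqn{E(D) = E_{max} \frac{D^h}{ED_{50}^h + D^h}}
#' where the effect is stored as a positive fraction of baseline LDL-C
#' lowered. The published estimates report effects as negative proportional
#' changes; this container keeps the magnitude so that the combination
#' algebra stays free of double negatives.
#'
#' @param emax Maximal fraction of baseline lowered, in (0, 1).
#' @param ed50 Dose achieving half-maximal effect (mg), > 0.
#' @param hill Hill coefficient (dimensionless), > 0. `hill = 1` gives the
#'   simple Emax model; other values the sigmoid variant.
#' @return An object of class `emax_model`.
#' @examples
#' ba <- emax_model(emax = 0.34, ed50 = 44, hill = 1)
#' fractional_effect(180, ba)
#' @export
emax_model <- function(emax, ed50, hill = 1) {
  stopifnot(is.numeric(emax), length(emax) == 1L,
            is.numeric(ed50), length(ed50) == 1L,
            is.numeric(hill), length(hill) == 1L)
  if (!(emax > 0 && emax < 1)) stop("`emax` must lie in (0, 1)", call. = FALSE)
  if (ed50 <= 0) stop("`ed50` must be positive", call. = FALSE)
  if (hill <= 0) stop("`hill` must be positive", call. = FALSE)
  structure(list(emax = emax, ed50 = ed50, hill = hill),
            class = "emax_model")
}

#' @export
print.emax_model <- function(x, ...) {
  cat(sprintf("Emax dose-response model: emax = %.3f, ED50 = %.4g mg, hill = %.3g\n",
              x$emax, x$ed50, x$hill))
  invisible(x)
}

#' Dose-response profile for one statin
#'
#' Bundles a statin's Emax model with its labelled dose grid. All four
#' supported statins share the maximal effect (0.787) and Hill coefficient
#' (0.451); only the half-maximal dose differs.
#'
#' @param name One of `"atorvastatin"`, `"simvastatin"`, `"rosuvastatin"`,
#'   `"pravastatin"`.
#' @param model An [emax_model()] for this statin.
#' @param max_label_dose Maximum labelled daily dose (mg).
#' @param dose_grid Ordered doses (mg) used in the report tables.
#' @return An object of class `statin_profile`.
#' @export
statin_profile <- function(name, model, max_label_dose, dose_grid) {
  name <- match.arg(name, c("atorvastatin", "simvastatin",
                            "rosuvastatin", "pravastatin"))
  stopifnot(inherits(model, "emax_model"),
            is.numeric(dose_grid), all(dose_grid > 0),
            !is.unsorted(dose_grid))
  structure(list(name = name, model = model,
                 max_label_dose = max_label_dose,
                 dose_grid = as.numeric(dose_grid)),
            class = "statin_profile")
}

#' @export
print.statin_profile <- function(x, ...) {
  cat(sprintf("Statin profile: %s (ED50 = %.4g mg; doses %s mg)\n",
              x$name, x$model$ed50, paste(x$dose_grid, collapse = "/")))
  invisible(x)
}

#' Two-drug interaction model
#'
#' Combines two single-drug Emax models through the bilinear interaction
#' \deqn{E_{total} = E_a + E_b + \gamma E_a E_b}
#' on the positive-fraction scale. A negative interaction coefficient
#' \eqn{\gamma} makes the combination less than additive whenever both
#' effects are positive.
#'
#' @param drug_a,drug_b [emax_model()] objects (bempedoic acid and a statin,
#'   conventionally in that order).
#' @param gamma Interaction coefficient (dimensionless, finite).
#' @return An object of class `interaction_model`.
#' @export
interaction_model <- function(drug_a, drug_b, gamma) {
  stopifnot(inherits(drug_a, "emax_model"), inherits(drug_b, "emax_model"),
            is.numeric(gamma), length(gamma) == 1L, is.finite(gamma))
  structure(list(drug_a = drug_a, drug_b = drug_b, gamma = gamma),
            class = "interaction_model")
}

#' @export
print.interaction_model <- function(x, ...) {
  cat(sprintf("Interaction model (gamma = %.3g)\n", x$gamma))
  cat("  drug A: "); print(x$drug_a)
  cat("  drug B: "); print(x$drug_b)
  invisible(x)
}

#' Indirect-effect turnover model for LDL-C
#'
#' LDL-C is produced at a zero-order rate `kin` and eliminated with
#' first-order rate `kout`; drug effect inhibits production. At steady state
#' with no drug the level equals `baseline`, so `kin = baseline * kout` is
#' derived, not supplied.
#'
#' @param baseline LDL-C at dose 0 (mg/dL), > 0.
#' @param kout First-order loss rate (1/h), > 0. Fixed at 0.01/h in all
#'   shipped parameter sets.
#' @return An object of class `turnover_model` with derived `kin`.
#' @export
turnover_model <- function(baseline, kout = 0.01) {
  stopifnot(is.numeric(baseline), length(baseline) == 1L,
            is.numeric(kout), length(kout) == 1L)
  if (baseline <= 0) stop("`baseline` must be positive", call. = FALSE)
  if (kout <= 0) stop("`kout` must be positive", call. = FALSE)
  structure(list(baseline = baseline, kout = kout, kin = baseline * kout),
            class = "turnover_model")
}

#' @export
print.turnover_model <- function(x, ...) {
  cat(sprintf("Turnover model: baseline = %.1f mg/dL, kout = %.3g /h (kin = %.3g mg/dL/h)\n",
              x$baseline, x$kout, x$kin))
  invisible(x)
}

#' Fractional LDL-C lowering at a dose
#'
#' Evaluates the Emax model at one or more doses. The value is the fraction
#' of baseline lowered: 0 at dose 0, strictly increasing, bounded above by
#' `model$emax`.
#'
#' @param dose Dose(s) in mg, >= 0. Vectorised.
#' @param model An [emax_model()].
#' @return Fraction(s) of baseline lowered, in `[0, emax)`.
#' @examples
#' ba <- emax_model(0.34, 44, 1)
#' percent_change(fractional_effect(180, ba))  # about -27
#' @export
fractional_effect <- function(dose, model) {
  stopifnot(inherits(model, "emax_model"), is.numeric(dose))
  if (any(dose < 0)) stop("`dose` must be non-negative", call. = FALSE)
  dh <- dose^model$hill
  out <- model$emax * dh / (model$ed50^model$hill + dh)
  out[dose == 0] <- 0  # guards 0^0 under hill exactly 0-adjacent values
  out
}

#' Total fractional effect of a two-drug combination
#'
#' Combines two single-drug fractional effects through
#' `e_a + e_b + gamma * e_a * e_b`. With `gamma = 0` the combination is
#' additive on the fraction scale; `gamma = -1` recovers multiplicative
#' independence `1 - (1 - e_a)(1 - e_b)`; the fitted value -1.35 is slightly
#' less than multiplicative. The result is clamped to `[0, 1)` so downstream
#' LDL-C predictions remain positive; a clamp at the lower end warns, since
#' it only occurs for pathological `gamma`.
#'
#' @param e_a,e_b Single-drug fractional effects in `[0, 1)`. Vectorised.
#' @param gamma Interaction coefficient.
#' @return Total fraction lowered, clamped to `[0, 1)`.
#' @export
combined_effect <- function(e_a, e_b, gamma) {
  stopifnot(is.numeric(e_a), is.numeric(e_b),
            is.numeric(gamma), all(is.finite(gamma)))
  if (any(e_a < 0 | e_a >= 1) || any(e_b < 0 | e_b >= 1))
    stop("single-drug effects must lie in [0, 1)", call. = FALSE)
  out <- e_a + e_b + gamma * e_a * e_b
  if (any(out < 0)) {
    warning("combined effect below 0 clamped to 0 (pathological gamma)")
    out <- pmax(out, 0)
  }
  pmin(out, 1 - 1e-12)
}

#' @rdname combined_effect
#' @param statin_dose,ba_dose Doses (mg) handed to the two component models
#'   of an [interaction_model()] (drug A = bempedoic acid, drug B = statin).
#' @param model An [interaction_model()].
#' @export
combined_effect_at_dose <- function(statin_dose, ba_dose, model) {
  stopifnot(inherits(model, "interaction_model"))
  combined_effect(fractional_effect(ba_dose, model$drug_a),
                  fractional_effect(statin_dose, model$drug_b),
                  model$gamma)
}

#' LDL-C concentration over time under constant drug effect
#'
#' Closed-form solution of the indirect-effect model
#' `dL/dt = kin * (1 - e_total) - kout * L`, `L(0) = baseline`:
#' \deqn{L(t) = B (1 - e_{total} (1 - e^{-k_{out} t}))}
#' The level declines monotonically from `baseline` toward the steady state
#' `baseline * (1 - e_total)`. With `kout = 0.01/h` the week-12 value
#' (2016 h) is within 1e-8 relative of steady state, which is why week-12
#' predictions elsewhere in the package use the steady-state algebra.
#'
#' @param turnover A [turnover_model()].
#' @param e_total Total fractional effect in `[0, 1)`.
#' @param t Time(s) since treatment start (hours), >= 0. Vectorised.
#' @return LDL-C (mg/dL) at each time.
#' @export
ldl_timecourse <- function(turnover, e_total, t) {
  stopifnot(inherits(turnover, "turnover_model"),
            is.numeric(e_total), e_total >= 0, e_total < 1,
            is.numeric(t))
  if (any(t < 0)) stop("`t` must be non-negative", call. = FALSE)
  turnover$baseline * (1 - e_total * (1 - exp(-turnover$kout * t)))
}

#' Fraction lowered expressed as signed percent change
#'
#' @param e_total Fraction(s) of baseline lowered, in `[0, 1)`.
#' @return `-100 * e_total`, the percent change from baseline (negative for
#'   lowering), matching the reporting convention of the clinical tables.
#' @export
percent_change <- function(e_total) {
  stopifnot(is.numeric(e_total))
  if (any(e_total < 0 | e_total >= 1))
    stop("`e_total` must lie in [0, 1)", call. = FALSE)
  -100 * e_total
}

#' Additional lowering attributable to bempedoic acid on a statin background
#'
#' The add-on effect is expressed on the on-statin baseline scale:
#' \deqn{\Delta = \frac{pct_{combo} - pct_{mono}}{1 + pct_{mono}/100}}
#' with both inputs as signed percent changes. With no background statin
#' (`mono_pct = 0`) the combination percent is returned unchanged.
#'
#' @param combo_pct Signed percent change on statin + bempedoic acid.
#' @param mono_pct Signed percent change on statin monotherapy; must be
#'   > -100 (a statin cannot abolish LDL-C entirely).
#' @return Signed percent: the added lowering from bempedoic acid.
#' @export
delta_added_effect <- function(combo_pct, mono_pct) {
  stopifnot(is.numeric(combo_pct), is.numeric(mono_pct))
  if (any(mono_pct <= -100))
    stop("`mono_pct` must be greater than -100", call. = FALSE)
  (combo_pct - mono_pct) / (1 + mono_pct / 100)
}

#' Convert LDL-C from mg/dL to mmol/L
#'
#' @param value LDL-C in mg/dL, >= 0.
#' @param digits Decimal places for the reported value (default 1, the
#'   display precision of the clinical tables). Use `NULL` for full
#'   precision.
#' @return LDL-C in mmol/L (`value / 38.67`).
#' @export
mgdl_to_mmoll <- function(value, digits = 1) {
  stopifnot(is.numeric(value))
  if (any(value < 0)) stop("`value` must be non-negative", call. = FALSE)
  out <- value / 38.67
  if (is.null(digits)) out else round(out, digits)
}
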