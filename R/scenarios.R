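## One-command runners for the published analyses: base case, trial-specific
## effect estimates, observational baseline rates, bleeding-weight sweep,
## risk-score strata (caller-parameterized), and the dynamic
## treatment-switching model.

TRIAL_EFFECTS <- list(
  noah = list(rr_ischemic_stroke = 0.79, rr_major_bleeding = 2.10),
  artesia = list(rr_ischemic_stroke = 0.62, rr_major_bleeding = 1.36)
)

## Deep-merge overrides into a config; every override key must already
## exist in the config (scenario specs are pure data over the schema).
merge_overrides <- function(config, overrides, path = "") {
  for (nm in names(overrides)) {
    here <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(config)) {
      abort(sprintf("Scenario override '%s' does not match any config field.", here))
    }
    if (is.list(overrides[[nm]]) && is.list(config[[nm]])) {
      config[[nm]] <- merge_overrides(config[[nm]], overrides[[nm]], here)
    } else {
      if (is.null(overrides[[nm]])) {
        abort(sprintf("Scenario override '%s' is null; supply a value.", here))
      }
      config[[nm]] <- overrides[[nm]]
    }
  }
  config
}

#' Load a scenario specification
#'
#' A scenario spec is pure data: a name plus overrides to existing config
#' fields. `apply_scenario()` merges it into a base config and revalidates.
#'
#' @param path Path to a scenario YAML file (`name` + `overrides`).
#' @return A `scenario_spec` list.
#' @export
load_scenario_spec <- function(path) {
  x <- yaml::read_yaml(path)
  if (is.null(x$name)) abort("Scenario spec must have a 'name'.")
  structure(list(name = x$name, overrides = x$overrides %||% list()),
            class = "scenario_spec")
}

#' Apply a scenario specification to a configuration
#'
#' @param config A `model_config`.
#' @param spec A `scenario_spec` (or list with `name` and `overrides`).
#' @return The merged, revalidated `model_config`.
#' @export
apply_scenario <- function(config, spec) {
  config <- as_model_config(config)
  merged <- merge_overrides(unclass(config), spec$overrides %||% list())
  merged$name <- spec$name %||% merged$name
  as_model_config(merged)
}

#' Run the base-case two-arm comparison
#'
#' @param config A `model_config`; defaults to the shipped base case.
#' @param mode `"cohort"` or `"microsim"`.
#' @param seed Seed for microsimulation mode.
#' @inheritParams run_decision_model
#' @return A `decision_summary`.
#' @examples
#' run_base_case(mode = "cohort")
#' @export
run_base_case <- function(config = base_case_config(),
                          mode = c("cohort", "microsim"), seed = NULL,
                          use_crn = NULL) {
  run_decision_model(config, mode = match.arg(mode), seed = seed,
                     use_crn = use_crn)
}

#' Run the model with a trial's effect estimates
#'
#' Substitutes the named trial's point estimates for both treatment effects
#' (stroke RR 0.79 and bleeding RR 2.10 for NOAH-AFNET 6; 0.62 and 1.36 for
#' ARTESiA); everything else stays at base case.
#'
#' @param config A `model_config`.
#' @param trial `"noah"` or `"artesia"`.
#' @inheritParams run_decision_model
#' @return A `decision_summary`.
#' @export
run_trial_estimates <- function(config = base_case_config(),
                                trial = c("noah", "artesia"),
                                mode = c("cohort", "microsim"), seed = NULL,
                                use_crn = NULL) {
  trial <- match.arg(trial)
  eff <- TRIAL_EFFECTS[[trial]]
  cfg <- as_model_config(config)
  cfg$treatment_effect$rr_ischemic_stroke[c("point", "ci_low", "ci_high")] <-
    eff$rr_ischemic_stroke
  cfg$treatment_effect$rr_major_bleeding[c("point", "ci_low", "ci_high")] <-
    eff$rr_major_bleeding
  cfg$name <- trial
  run_decision_model(cfg, mode = match.arg(mode), seed = seed, use_crn = use_crn)
}

#' Run the model with observational-study baseline rates
#'
#' Raises the untreated ischemic-stroke, total major-bleeding and mortality
#' rates to observational levels (1.9, 1.7 and 8.5 per 100 patient-years by
#' default). Bleeding subtypes are rescaled proportionally so their shares
#' of the total are preserved. Treatment effects stay at base case.
#'
#' @param config A `model_config`.
#' @param stroke_rate,bleeding_rate,death_rate Replacement untreated annual
#'   rates per 100 patient-years.
#' @inheritParams run_decision_model
#' @return A `decision_summary`.
#' @export
run_observational_rates <- function(config = base_case_config(),
                                    stroke_rate = 1.9, bleeding_rate = 1.7,
                                    death_rate = 8.5,
                                    mode = c("cohort", "microsim"),
                                    seed = NULL, use_crn = NULL) {
  cfg <- as_model_config(config)
  er <- cfg$event_rates
  scale <- bleeding_rate / er$major_bleeding_total
  er$ischemic_stroke <- stroke_rate
  er$hemorrhagic_stroke <- er$hemorrhagic_stroke * scale
  er$other_intracranial_bleeding <- er$other_intracranial_bleeding * scale
  er$extracranial_major_bleeding <- er$extracranial_major_bleeding * scale
  er$major_bleeding_total <- er$hemorrhagic_stroke +
    er$other_intracranial_bleeding + er$extracranial_major_bleeding
  er$death <- death_rate
  cfg$event_rates <- er
  cfg$name <- "observational"
  run_decision_model(cfg, mode = match.arg(mode), seed = seed, use_crn = use_crn)
}

#' Sweep the extracranial share of the bleeding increase
#'
#' Runs the two-arm comparison for each weight in `weights` (the fraction of
#' the NOAC-induced bleeding increase assigned to extracranial bleeds) and
#' tabulates the per-patient QALY difference. With more of the harm shifted
#' to the less severe extracranial bleeds the QALY difference increases
#' monotonically in the weight.
#'
#' @param config A `model_config`.
#' @param weights Numeric vector of weights in `[0, 1]`.
#' @inheritParams run_decision_model
#' @return A tibble with columns `weight`, `qaly_diff_per_patient`, and a
#'   list-column `summary` of `decision_summary` objects.
#' @export
run_bleeding_weight_sweep <- function(config = base_case_config(),
                                      weights = seq(0.70, 0.90, by = 0.05),
                                      mode = c("cohort", "microsim"),
                                      seed = NULL, use_crn = NULL) {
  if (any(weights < 0 | weights > 1)) abort("`weights` must lie in [0, 1].")
  mode <- match.arg(mode)
  cfg <- as_model_config(config)
  res <- purrr::map(weights, function(w) {
    cw <- cfg
    cw$extracranial_bleed_weight <- w
    run_decision_model(cw, mode = mode, seed = seed, use_crn = use_crn)
  })
  tibble::tibble(
    weight = weights,
    qaly_diff_per_patient = vapply(res, qaly_diff_per_patient, numeric(1)),
    summary = res
  )
}

#' Run the dynamic treatment-switching model
#'
#' Both arms are simulated with treatment status responding to events: an
#' intracranial bleeding event on NOAC leads to permanent cessation, and an
#' ischemic stroke leads to (re)initiation of NOAC — also in the initially
#' untreated arm. Extracranial bleeds keep the ordinary 1-month pause. Arms
#' are compared by initial assignment (intention to treat).
#'
#' @param config A `model_config`.
#' @inheritParams run_decision_model
#' @return A `decision_summary`.
#' @export
run_dynamic_treatment <- function(config = base_case_config(),
                                  mode = c("cohort", "microsim"), seed = NULL,
                                  use_crn = NULL) {
  cfg <- as_model_config(config)
  cfg$dynamic_policy <- TRUE
  cfg$name <- paste0(cfg$name, "_dynamic")
  run_decision_model(cfg, mode = match.arg(mode), seed = seed, use_crn = use_crn)
}

#' Run a stroke-risk-score stratum analysis
#'
#' Applies the ARTESiA effect point estimates on top of caller-supplied
#' stratum event rates. The numeric per-stratum inputs are not shipped with
#' the package; supply them via `stratum_overrides` (see the
#' `stratum_template.yaml` shipped config for the required fields).
#'
#' @param config A `model_config`.
#' @param stratum_overrides A `scenario_spec` or list with `overrides`
#'   containing at least `event_rates` with stroke, bleeding-subtype and
#'   death rates for the stratum.
#' @inheritParams run_decision_model
#' @return A `decision_summary`.
#' @export
run_stratum <- function(config = base_case_config(), stratum_overrides,
                        mode = c("cohort", "microsim"), seed = NULL,
                        use_crn = NULL) {
  ov <- stratum_overrides$overrides %||% stratum_overrides
  er <- ov$event_rates
  needed <- c("ischemic_stroke", "major_bleeding_total", "hemorrhagic_stroke",
              "other_intracranial_bleeding", "extracranial_major_bleeding",
              "death")
  missing <- needed[vapply(needed, function(f) is.null(er[[f]]), logical(1))]
  if (length(missing)) {
    abort(sprintf(paste0("Stratum rates missing: %s. Per-stratum inputs are ",
                         "published in the source study's supplementary eTable ",
                         "and must be supplied by the caller."),
                  paste(missing, collapse = ", ")))
  }
  cfg <- apply_scenario(config, list(name = stratum_overrides$name %||% "stratum",
                                     overrides = ov))
  run_trial_estimates(cfg, trial = "artesia", mode = match.arg(mode),
                      seed = seed, use_crn = use_crn)
}
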