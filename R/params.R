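## Parameter schema, config IO and validation, and derivation of the
## NOAC-arm event rates from untreated rates + relative risks.

SEVERITY_CATEGORIES <- list(
  ischemic_stroke              = c("death", "severe", "moderate", "mild"),
  hemorrhagic_stroke           = c("death", "severe", "moderate", "mild"),
  other_intracranial_bleeding  = c("death", "severe", "mild", "none"),
  extracranial_major_bleeding  = c("death", "severe", "mild", "none")
)

config_defaults <- function() {
  list(
    name = "unnamed",
    start_age = 77,
    horizon = 120L,
    cycle_length = 1,
    n_patients = 10000L,
    extracranial_bleed_weight = 0.80,
    pause_cycles_after_bleed = 1L,
    rng_seed = 42L,
    use_common_random_numbers = FALSE,
    dynamic_policy = FALSE
  )
}

#' Locate a configuration file shipped with the package
#'
#' @param name File name under `extdata/configs`, e.g. `"base_case.yaml"`.
#'   With no argument, lists the available files.
#' @return A file path (or a character vector of file names).
#' @export
noacaf_config_path <- function(name = NULL) {
  dir <- system.file("extdata", "configs", package = "noacaf")
  if (is.null(name)) return(list.files(dir))
  path <- file.path(dir, name)
  if (!file.exists(path)) {
    abort(sprintf("No shipped config '%s'. Available: %s",
                  name, paste(list.files(dir), collapse = ", ")))
  }
  path
}

#' Load and validate a model configuration
#'
#' Reads a YAML model configuration, fills missing optional fields with
#' base-case defaults, and validates every schema invariant (rate
#' non-negativity, bleeding-subtype additivity, severity-column sums,
#' utility-weight ranges, confidence-interval ordering).
#'
#' @param path Path to a YAML configuration file.
#' @return A validated `model_config` object (a named list).
#' @examples
#' cfg <- load_model_config(noacaf_config_path("base_case.yaml"))
#' cfg$event_rates$ischemic_stroke
#' @export
load_model_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  as_model_config(raw)
}

#' Build a model_config from a nested list
#'
#' @param x Nested list following the configuration schema.
#' @return A validated `model_config`.
#' @export
as_model_config <- function(x) {
  stopifnot(is.list(x))
  defs <- config_defaults()
  for (f in names(defs)) x[[f]] <- x[[f]] %||% defs[[f]]
  x$horizon <- as.integer(x$horizon)
  x$n_patients <- as.integer(x$n_patients)
  x$pause_cycles_after_bleed <- as.integer(x$pause_cycles_after_bleed)
  x$rng_seed <- as.integer(x$rng_seed)
  structure(validate_model_config(x), class = "model_config")
}

#' The base-case configuration
#'
#' Loads the shipped base-case parameter set: a 77-year-old patient with
#' device-detected subclinical AF, averaged trial event rates, pooled
#' meta-analytic relative risks, 1-month cycles, 10-year horizon, and
#' 10 000 patients per arm.
#'
#' @return A `model_config`.
#' @export
base_case_config <- function() {
  load_model_config(noacaf_config_path("base_case.yaml"))
}

must_have <- function(x, fields, where) {
  miss <- setdiff(fields, names(x))
  if (length(miss)) {
    abort(sprintf("Config section '%s' is missing field(s): %s",
                  where, paste(miss, collapse = ", ")))
  }
}

check_prob <- function(v, field) {
  if (any(!is.finite(v)) || any(v < 0) || any(v > 1)) {
    abort(sprintf("Field '%s' must be a probability in [0, 1]; got %s",
                  field, paste(signif(v, 6), collapse = ", ")))
  }
}

#' Validate a model configuration
#'
#' Checks every schema invariant and returns the config invisibly unchanged.
#' Errors name the offending field.
#'
#' @param config A `model_config` or conforming list.
#' @return The config, invisibly validated.
#' @export
validate_model_config <- function(config) {
  must_have(config, c("event_rates", "treatment_effect", "severity",
                      "utility", "post_event_mortality", "clinical_af_risks"),
            "top level")

  if (config$extracranial_bleed_weight < 0 || config$extracranial_bleed_weight > 1) {
    abort(sprintf("Field 'extracranial_bleed_weight' must lie in [0, 1]; got %g",
                  config$extracranial_bleed_weight))
  }
  if (config$horizon < 0) abort("Field 'horizon' must be >= 0 cycles.")
  if (config$cycle_length <= 0) abort("Field 'cycle_length' must be positive months.")
  if (config$n_patients < 1) abort("Field 'n_patients' must be >= 1.")
  if (config$pause_cycles_after_bleed < 0) abort("Field 'pause_cycles_after_bleed' must be >= 0.")

  er <- config$event_rates
  must_have(er, c("ischemic_stroke", "major_bleeding_total", "hemorrhagic_stroke",
                  "other_intracranial_bleeding", "extracranial_major_bleeding",
                  "death", "clinical_af_progression"), "event_rates")
  for (f in names(er)) {
    if (!is.finite(er[[f]]) || er[[f]] < 0) {
      abort(sprintf("Field 'event_rates.%s' must be a non-negative rate per 100 patient-years.", f))
    }
  }
  subtype_sum <- er$hemorrhagic_stroke + er$other_intracranial_bleeding +
    er$extracranial_major_bleeding
  if (abs(subtype_sum - er$major_bleeding_total) > 1e-9) {
    abort(sprintf(paste0("Bleeding subtypes (%.6g) must sum to ",
                         "'event_rates.major_bleeding_total' (%.6g) within 1e-9."),
                  subtype_sum, er$major_bleeding_total))
  }

  te <- config$treatment_effect
  must_have(te, c("rr_ischemic_stroke", "rr_major_bleeding"), "treatment_effect")
  for (f in names(te)) {
    rr <- te[[f]]
    must_have(rr, c("point", "ci_low", "ci_high"), paste0("treatment_effect.", f))
    if (!(rr$ci_low > 0 && rr$ci_low <= rr$point && rr$point <= rr$ci_high)) {
      abort(sprintf("Field 'treatment_effect.%s' must satisfy 0 < ci_low <= point <= ci_high.", f))
    }
  }

  sev <- config$severity
  must_have(sev, EVENT_TYPES, "severity")
  for (ev in EVENT_TYPES) {
    s <- sev[[ev]]
    must_have(s, c("categories", "untreated", "treated"), paste0("severity.", ev))
    want <- SEVERITY_CATEGORIES[[ev]]
    if (!identical(as.character(s$categories), want)) {
      abort(sprintf("Field 'severity.%s.categories' must be exactly: %s",
                    ev, paste(want, collapse = ", ")))
    }
    for (col in c("untreated", "treated")) {
      p <- as.numeric(s[[col]])
      if (length(p) != length(want)) {
        abort(sprintf("Field 'severity.%s.%s' must have %d probabilities.",
                      ev, col, length(want)))
      }
      if (any(p < 0)) abort(sprintf("Field 'severity.%s.%s' has a negative probability.", ev, col))
      if (sum(p) < 0.97 || sum(p) > 1.03) {
        abort(sprintf(paste0("Field 'severity.%s.%s' sums to %.4f; columns must sum ",
                             "within [0.97, 1.03] before normalization (typo guard)."),
                      ev, col, sum(p)))
      }
    }
  }

  ut <- config$utility
  must_have(ut, c("base_weight_77_80", "base_weight_80_87", "qaly_ratio"), "utility")
  check_prob(ut$base_weight_77_80, "utility.base_weight_77_80")
  check_prob(ut$base_weight_80_87, "utility.base_weight_80_87")
  for (lev in c("mild", "moderate", "severe")) {
    r <- ut$qaly_ratio[[lev]]
    if (is.null(r)) abort(sprintf("Field 'utility.qaly_ratio.%s' is missing.", lev))
    must_have(r, c("first_6_months", "after_6_months"), paste0("utility.qaly_ratio.", lev))
    check_prob(r$first_6_months, sprintf("utility.qaly_ratio.%s.first_6_months", lev))
    check_prob(r$after_6_months, sprintf("utility.qaly_ratio.%s.after_6_months", lev))
    if (r$first_6_months > r$after_6_months) {
      abort(sprintf("Field 'utility.qaly_ratio.%s': first_6_months ratio must be <= after_6_months.", lev))
    }
  }
  if (!is.null(ut$bands)) {
    b <- ut$bands
    must_have(b, c("from", "to", "weight"), "utility.bands")
  }

  pm <- config$post_event_mortality
  must_have(pm, c("one_year_prob_after_ischemic_stroke",
                  "one_year_prob_after_intracranial_bleeding"), "post_event_mortality")
  check_prob(pm$one_year_prob_after_ischemic_stroke,
             "post_event_mortality.one_year_prob_after_ischemic_stroke")
  check_prob(pm$one_year_prob_after_intracranial_bleeding,
             "post_event_mortality.one_year_prob_after_intracranial_bleeding")

  cr <- config$clinical_af_risks
  must_have(cr, c(EVENT_TYPES, "death"), "clinical_af_risks")
  for (f in names(cr)) check_prob(cr[[f]], paste0("clinical_af_risks.", f))
  if (sum(unlist(cr[c(EVENT_TYPES, "death")])) >= 1) {
    abort("Field 'clinical_af_risks': 1-year probabilities must sum to < 1.")
  }

  invisible(config)
}

#' Serialize a model configuration to YAML
#'
#' Round-trips losslessly with [load_model_config()] (numeric precision 12
#' significant digits).
#'
#' @param config A `model_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(config, path) {
  x <- unclass(config)
  yaml::write_yaml(x, path, precision = 12L)
  invisible(path)
}

#' Normalize severity-distribution columns to sum exactly to 1
#'
#' The published severity probabilities carry rounding (e.g. the on-NOAC
#' hemorrhagic-stroke column sums to 0.994); categorical sampling requires
#' exact normalization. Each column is rescaled proportionally. Columns must
#' sum within `[0.97, 1.03]` beforehand, guarding against transcription
#' errors.
#'
#' @param severity A severity table: named list per event type with
#'   `categories`, `untreated` and `treated` probability vectors (the
#'   `severity` section of a `model_config`).
#' @return The severity table with each column summing to exactly 1.
#' @export
normalize_severity_table <- function(severity) {
  for (ev in names(severity)) {
    for (col in c("untreated", "treated")) {
      p <- as.numeric(severity[[ev]][[col]])
      if (any(p < 0)) abort(sprintf("severity.%s.%s has a negative entry.", ev, col))
      s <- sum(p)
      if (s < 0.97 || s > 1.03) {
        abort(sprintf("severity.%s.%s sums to %.4f, outside [0.97, 1.03].", ev, col, s))
      }
      severity[[ev]][[col]] <- p / s
    }
  }
  severity
}

#' Derive NOAC-arm event rates and the per-context transition table
#'
#' Applies the treatment effects to the untreated annual rates: the treated
#' ischemic-stroke rate is `untreated * RR_stroke`; the total major-bleeding
#' increase `delta = total * (RR_bleed - 1)` is allocated with fraction
#' `weight` to extracranial bleeding and the remainder to the two
#' intracranial subtypes in proportion to their untreated rates, so the
#' treated subtypes sum exactly to `total * RR_bleed`. Death and clinical-AF
#' progression rates are identical in both arms (no mortality effect of
#' NOAC). Annual rates are then converted to per-cycle probabilities (and
#' clinical-AF 1-year probabilities compounded) to give the per-context
#' transition table.
#'
#' @param rates Untreated annual event rates (the `event_rates` config
#'   section).
#' @param effect Treatment effects (the `treatment_effect` section).
#' @param weight Fraction of the bleeding increase assigned to extracranial
#'   bleeds, in `[0, 1]`. Default 0.80.
#' @param clinical_af_risks Optional 1-year probabilities for the clinical-AF
#'   state; when supplied a `clinical_af` context row is included.
#' @param cycle_months Cycle length in months. Default 1.
#' @return A tibble with one row per context (`untreated`, `treated`, and
#'   optionally `clinical_af`) and per-cycle probability columns for each
#'   event type, death and clinical-AF progression. The treated annual rates
#'   are attached as attribute `"treated_annual"`.
#' @examples
#' cfg <- base_case_config()
#' derive_arm_event_rates(cfg$event_rates, cfg$treatment_effect, 0.80)
#' @export
derive_arm_event_rates <- function(rates, effect, weight = 0.80,
                                   clinical_af_risks = NULL, cycle_months = 1) {
  if (weight < 0 || weight > 1) abort("`weight` must lie in [0, 1].")
  treated <- noac_treated_annual_rates(rates, effect, weight)

  row_probs <- function(r) {
    tibble::tibble(
      ischemic_stroke = annual_rate_to_cycle_prob(r$ischemic_stroke, cycle_months),
      hemorrhagic_stroke = annual_rate_to_cycle_prob(r$hemorrhagic_stroke, cycle_months),
      other_intracranial_bleeding = annual_rate_to_cycle_prob(r$other_intracranial_bleeding, cycle_months),
      extracranial_major_bleeding = annual_rate_to_cycle_prob(r$extracranial_major_bleeding, cycle_months),
      death = annual_rate_to_cycle_prob(r$death, cycle_months),
      clinical_af_progression = annual_rate_to_cycle_prob(r$clinical_af_progression, cycle_months)
    )
  }
  out <- dplyr::bind_rows(
    dplyr::mutate(row_probs(rates), context = "untreated", .before = 1),
    dplyr::mutate(row_probs(treated), context = "treated", .before = 1)
  )
  if (!is.null(clinical_af_risks)) {
    caf <- tibble::tibble(
      context = "clinical_af",
      ischemic_stroke = annual_prob_to_cycle_prob(clinical_af_risks$ischemic_stroke, cycle_months),
      hemorrhagic_stroke = annual_prob_to_cycle_prob(clinical_af_risks$hemorrhagic_stroke, cycle_months),
      other_intracranial_bleeding = annual_prob_to_cycle_prob(clinical_af_risks$other_intracranial_bleeding, cycle_months),
      extracranial_major_bleeding = annual_prob_to_cycle_prob(clinical_af_risks$extracranial_major_bleeding, cycle_months),
      death = annual_prob_to_cycle_prob(clinical_af_risks$death, cycle_months),
      clinical_af_progression = 0
    )
    out <- dplyr::bind_rows(out, caf)
  }
  exit <- rowSums(out[, setdiff(names(out), "context")])
  if (any(exit >= 1)) {
    abort("Total per-cycle exit probability >= 1 in some context; rates are implausibly large.")
  }
  attr(out, "treated_annual") <- treated
  out
}

#' Treated-arm annual event rates
#'
#' The annual-rate algebra underlying [derive_arm_event_rates()], exposed for
#' inspection: returns the NOAC-arm annual rates per 100 patient-years.
#'
#' @inheritParams derive_arm_event_rates
#' @return Named list of treated annual rates.
#' @export
noac_treated_annual_rates <- function(rates, effect, weight = 0.80) {
  rr_s <- effect$rr_ischemic_stroke$point
  rr_b <- effect$rr_major_bleeding$point
  delta <- rates$major_bleeding_total * (rr_b - 1)
  ic_total <- rates$hemorrhagic_stroke + rates$other_intracranial_bleeding
  ic_share <- if (ic_total > 0) {
    c(rates$hemorrhagic_stroke, rates$other_intracranial_bleeding) / ic_total
  } else {
    c(0.5, 0.5)
  }
  treated <- list(
    ischemic_stroke = rates$ischemic_stroke * rr_s,
    extracranial_major_bleeding = rates$extracranial_major_bleeding + weight * delta,
    hemorrhagic_stroke = rates$hemorrhagic_stroke + (1 - weight) * delta * ic_share[1],
    other_intracranial_bleeding = rates$other_intracranial_bleeding + (1 - weight) * delta * ic_share[2],
    death = rates$death,
    clinical_af_progression = rates$clinical_af_progression
  )
  treated$major_bleeding_total <- treated$hemorrhagic_stroke +
    treated$other_intracranial_bleeding + treated$extracranial_major_bleeding
  neg <- names(treated)[unlist(treated) < 0]
  if (length(neg)) {
    abort(sprintf("Derived treated rate(s) negative (%s); bleeding weight %.2f incompatible with RR %.3f.",
                  paste(neg, collapse = ", "), weight, rr_b))
  }
  treated
}
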