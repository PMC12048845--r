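## Shared engine machinery: compiled model inputs, utility lookup,
## per-cycle competing-risk probabilities, and arm comparison.

## Severity slot -> disability code per event type. Slots follow the
## configured category order; -1 marks the fatal category.
severity_dis_codes <- function() {
  rbind(
    ischemic_stroke             = c(-1L, 3L, 2L, 1L),
    hemorrhagic_stroke          = c(-1L, 3L, 2L, 1L),
    other_intracranial_bleeding = c(-1L, 3L, 1L, 0L),
    extracranial_major_bleeding = c(-1L, 3L, 1L, 0L)
  )
}

## Precompute every lookup the engines need from a validated config.
compile_model <- function(config) {
  config <- validate_model_config(config)
  cm <- config$cycle_length

  arm_tab <- derive_arm_event_rates(
    config$event_rates, config$treatment_effect,
    weight = config$extracranial_bleed_weight,
    clinical_af_risks = config$clinical_af_risks, cycle_months = cm
  )
  ## prob_mat rows: 1 untreated, 2 treated, 3 clinical AF
  pm <- as.matrix(arm_tab[, c("ischemic_stroke", "hemorrhagic_stroke",
                              "other_intracranial_bleeding",
                              "extracranial_major_bleeding",
                              "death", "clinical_af_progression")])
  rownames(pm) <- arm_tab$context

  sev <- normalize_severity_table(config$severity)
  sev_prob <- array(0, dim = c(4, 4, 2),
                    dimnames = list(EVENT_TYPES, NULL, c("untreated", "treated")))
  for (i in seq_along(EVENT_TYPES)) {
    sev_prob[i, , 1] <- sev[[EVENT_TYPES[i]]]$untreated
    sev_prob[i, , 2] <- sev[[EVENT_TYPES[i]]]$treated
  }
  sev_cum <- sev_prob
  for (i in 1:4) for (j in 1:2) sev_cum[i, , j] <- cumsum(sev_prob[i, , j])

  ut <- config$utility
  if (!is.null(ut$bands)) {
    bands <- tibble::tibble(from = as.numeric(ut$bands$from),
                            to = as.numeric(ut$bands$to),
                            weight = as.numeric(ut$bands$weight))
  } else {
    bands <- tibble::tibble(from = c(77, 80), to = c(80, 87),
                            weight = c(ut$base_weight_77_80, ut$base_weight_80_87))
  }
  horizon <- config$horizon
  ## Base weight for the age at the start of each cycle t = 0..horizon-1.
  age_at <- config$start_age + (seq_len(max(horizon, 1)) - 1) * cm / 12
  bw <- base_weight_for_age(age_at, bands)

  ratio <- rbind(
    none     = c(1, 1),
    mild     = c(ut$qaly_ratio$mild$first_6_months, ut$qaly_ratio$mild$after_6_months),
    moderate = c(ut$qaly_ratio$moderate$first_6_months, ut$qaly_ratio$moderate$after_6_months),
    severe   = c(ut$qaly_ratio$severe$first_6_months, ut$qaly_ratio$severe$after_6_months)
  )
  colnames(ratio) <- c("first_6_months", "after_6_months")

  pem <- config$post_event_mortality
  excess_monthly <- c(
    ischemic = annual_prob_to_cycle_prob(pem$one_year_prob_after_ischemic_stroke, cm),
    intracranial = annual_prob_to_cycle_prob(pem$one_year_prob_after_intracranial_bleeding, cm)
  )

  list(
    config = config,
    prob_mat = pm,
    sev_prob = sev_prob,
    sev_cum = sev_cum,
    sev_dis = severity_dis_codes(),
    base_weight = bw,
    ratio = ratio,
    excess_monthly = excess_monthly,
    horizon = horizon,
    n_patients = config$n_patients,
    pause_cycles = config$pause_cycles_after_bleed,
    dynamic_policy = isTRUE(config$dynamic_policy),
    cycle_months = cm
  )
}

base_weight_for_age <- function(age, bands) {
  w <- rep(NA_real_, length(age))
  for (i in seq_len(nrow(bands))) {
    inb <- age >= bands$from[i] & age < bands$to[i] + 1e-9
    w[inb] <- bands$weight[i]
  }
  if (anyNA(w)) {
    abort(sprintf("Age %.2f falls outside the configured utility age bands [%g, %g].",
                  age[which(is.na(w))[1]], min(bands$from), max(bands$to)))
  }
  w
}

#' Per-cycle utility weight of a patient state
#'
#' The utility weight is the age-band base weight (0.794 for ages 77 to <80,
#' 0.733 from 80 on in the base case) multiplied by the QALY ratio for the
#' patient's current worst disability, using the first-6-months ratio while
#' fewer than 6 months have passed since the last disabling event. Dead
#' patients have weight 0.
#'
#' @param state A data frame of patient states with columns `age` (years),
#'   `disability` (`"none"`, `"mild"`, `"moderate"`, `"severe"` or `"dead"`),
#'   and `months_since_event` (`Inf` or `NA` if no event yet).
#' @param utility_params The `utility` section of a `model_config` (or a full
#'   `model_config`).
#' @return Numeric vector of per-cycle utility weights in `[0, 1]`.
#' @examples
#' cfg <- base_case_config()
#' utility_weight(
#'   data.frame(age = 82, disability = "severe", months_since_event = 8),
#'   cfg
#' )
#' @export
utility_weight <- function(state, utility_params) {
  if (inherits(utility_params, "model_config")) {
    cfg <- utility_params
  } else {
    cfg <- base_case_config()
    cfg$utility <- utility_params
  }
  cmod <- compile_model_for_utility(cfg)
  dis <- as.character(state$disability)
  mse <- state$months_since_event
  mse[is.na(mse)] <- Inf
  dead <- dis == "dead"
  out <- numeric(nrow(state))
  if (any(!dead)) {
    bw <- base_weight_for_age(state$age[!dead], cmod$bands)
    code <- match(dis[!dead], DISABILITY_LEVELS)
    if (anyNA(code)) abort("`disability` must be one of none/mild/moderate/severe/dead.")
    phase <- ifelse(mse[!dead] < 6, 1L, 2L)
    out[!dead] <- bw * cmod$ratio[cbind(code, phase)]
  }
  out
}

compile_model_for_utility <- function(cfg) {
  ut <- cfg$utility
  bands <- if (!is.null(ut$bands)) {
    tibble::tibble(from = as.numeric(ut$bands$from), to = as.numeric(ut$bands$to),
                   weight = as.numeric(ut$bands$weight))
  } else {
    tibble::tibble(from = c(77, 80), to = c(80, 87),
                   weight = c(ut$base_weight_77_80, ut$base_weight_80_87))
  }
  ratio <- rbind(
    c(1, 1),
    c(ut$qaly_ratio$mild$first_6_months, ut$qaly_ratio$mild$after_6_months),
    c(ut$qaly_ratio$moderate$first_6_months, ut$qaly_ratio$moderate$after_6_months),
    c(ut$qaly_ratio$severe$first_6_months, ut$qaly_ratio$severe$after_6_months)
  )
  list(bands = bands, ratio = ratio)
}

new_arm_result <- function(arm, mode, n_patients, horizon, totals, severity_counts,
                           trajectories, final_disability, qaly_sd = NA_real_,
                           life_sd = NA_real_, subclin_sd = NA_real_) {
  structure(
    list(
      arm = arm, mode = mode, n_patients = n_patients, horizon = horizon,
      totals = totals, severity_counts = severity_counts,
      trajectories = trajectories, final_disability = final_disability,
      qaly_sd = qaly_sd, life_sd = life_sd, subclin_sd = subclin_sd
    ),
    class = "arm_result"
  )
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf("<arm_result: %s, %s, %d patients, %d cycles>\n",
              x$arm, x$mode, x$n_patients, x$horizon))
  t <- x$totals
  cat(sprintf("  events: IS %.1f, HS %.1f, OIB %.1f, ECB %.1f; deaths %.1f\n",
              t$ischemic_stroke, t$hemorrhagic_stroke,
              t$other_intracranial_bleeding, t$extracranial_major_bleeding,
              t$deaths))
  cat(sprintf("  life-years %.1f, QALYs %.1f, mean subclinical years %.3f\n",
              t$life_years, t$qalys, t$mean_subclinical_years))
  invisible(x)
}

#' Compare the two decision arms
#'
#' Builds the two-arm comparison: cumulative event counts, deaths,
#' life-years and QALYs per cohort, their differences (with NOAC minus
#' without NOAC, so a positive QALY difference favours anticoagulation), and
#' per-patient differences.
#'
#' @param without `arm_result` for the no-anticoagulation arm.
#' @param with_noac `arm_result` for the NOAC arm.
#' @return A `decision_summary` object.
#' @export
compare_arms <- function(without, with_noac) {
  if (without$n_patients != with_noac$n_patients ||
      without$horizon != with_noac$horizon) {
    abort("Arms were run with different n_patients or horizon; cannot compare.")
  }
  n <- without$n_patients
  metrics <- c("ischemic_stroke", "major_bleeding", "hemorrhagic_stroke",
               "other_intracranial_bleeding", "extracranial_major_bleeding",
               "deaths", "life_years", "qalys")
  get <- function(a) {
    t <- a$totals
    mb <- t$hemorrhagic_stroke + t$other_intracranial_bleeding +
      t$extracranial_major_bleeding
    c(t$ischemic_stroke, mb, t$hemorrhagic_stroke,
      t$other_intracranial_bleeding, t$extracranial_major_bleeding,
      t$deaths, t$life_years, t$qalys)
  }
  wo <- get(without); wi <- get(with_noac)
  tab <- tibble::tibble(
    outcome = metrics,
    without_noac = wo,
    with_noac = wi,
    difference = wi - wo,
    per_patient = (wi - wo) / n
  )
  structure(
    list(table = tab, without = without, with_noac = with_noac,
         n_patients = n, horizon = without$horizon, mode = without$mode),
    class = "decision_summary"
  )
}

#' @export
print.decision_summary <- function(x, ...) {
  cat(sprintf("<decision_summary: %d patients/arm, %d cycles, %s>\n",
              x$n_patients, x$horizon, x$mode))
  print(as.data.frame(x$table), digits = 5, row.names = FALSE)
  invisible(x)
}

## Per-patient QALY difference (NOAC minus no-NOAC), the headline metric.
qaly_diff_per_patient <- function(summary) {
  summary$table$per_patient[summary$table$outcome == "qalys"]
}
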