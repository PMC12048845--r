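## Shared fixtures: all built in code at test time.

base_cfg <- function() base_case_config()

## Base case with identity treatment effect and identical severity columns
## in both arms: the two decision arms must then coincide exactly.
identity_effect_cfg <- function() {
  cfg <- unclass(base_case_config())
  cfg$treatment_effect <- list(
    rr_ischemic_stroke = list(point = 1, ci_low = 1, ci_high = 1),
    rr_major_bleeding = list(point = 1, ci_low = 1, ci_high = 1)
  )
  for (ev in names(cfg$severity)) {
    cfg$severity[[ev]]$treated <- cfg$severity[[ev]]$untreated
  }
  as_model_config(cfg)
}

## Smaller cohort for fast microsimulation tests.
small_cfg <- function(n = 2000L, horizon = 120L) {
  cfg <- base_case_config()
  cfg$n_patients <- as.integer(n)
  cfg$horizon <- as.integer(horizon)
  cfg
}

totals_vec <- function(arm_result) unlist(arm_result$totals)

## z-score of a microsim total against the cohort-expectation value
count_z <- function(micro, cohort) (micro - cohort) / sqrt(pmax(cohort, 1))
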