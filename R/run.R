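## Two-arm model runner and tibble-level single-cycle / single-event
## operations.

#' Run the full two-arm decision model
#'
#' Runs both decision arms (withhold vs initiate NOAC) and returns the
#' comparison. `mode = "cohort"` uses the deterministic cohort-expectation
#' solver; `mode = "microsim"` runs the patient-level microsimulation,
#' optionally with common random numbers pairing the per-patient uniform
#' draws across arms to reduce the variance of arm differences.
#'
#' @param config A `model_config`.
#' @param mode `"cohort"` (deterministic) or `"microsim"`.
#' @param seed Integer seed for microsimulation mode; defaults to
#'   `config$rng_seed`.
#' @param use_crn Use common random numbers across arms (microsim mode);
#'   defaults to `config$use_common_random_numbers`.
#' @return A `decision_summary`.
#' @examples
#' run_decision_model(base_case_config(), mode = "cohort")
#' @export
run_decision_model <- function(config, mode = c("cohort", "microsim"),
                               seed = NULL, use_crn = NULL) {
  mode <- match.arg(mode)
  config <- as_model_config(config)
  if (mode == "cohort") {
    return(compare_arms(solve_cohort_expectation(config, "without_noac"),
                        solve_cohort_expectation(config, "with_noac")))
  }
  seed <- seed %||% config$rng_seed
  use_crn <- use_crn %||% isTRUE(config$use_common_random_numbers)
  n <- config$n_patients
  T <- config$horizon
  if (use_crn) {
    uni <- withr::with_seed(seed, list(
      u1 = matrix(runif(n * T), n, T),
      u2 = matrix(runif(n * T), n, T)
    ))
    wo <- simulate_microsim(config, "without_noac", uniforms = uni)
    wi <- simulate_microsim(config, "with_noac", uniforms = uni)
  } else {
    res <- withr::with_seed(seed, list(
      wo = simulate_microsim(config, "without_noac", seed = NA),
      wi = simulate_microsim(config, "with_noac", seed = NA)
    ))
    wo <- res$wo; wi <- res$wi
  }
  compare_arms(wo, wi)
}

states_tibble_to_internal <- function(states) {
  ctx_map <- c(subclinical_untreated = 1L, subclinical_treated = 2L,
               subclinical_paused = 2L, clinical_af = 3L, dead = NA_integer_)
  ctx <- ctx_map[as.character(states$context)]
  if (any(is.na(ctx) & states$context != "dead")) {
    abort("Unknown health context in `states$context`.")
  }
  n <- nrow(states)
  mse <- states$months_since_event %||% rep(Inf, n)
  mse[is.na(mse)] <- Inf
  list(
    alive = states$context != "dead",
    ctx = ifelse(is.na(ctx), 1L, ctx),
    dis = match(as.character(states$disability), DISABILITY_LEVELS) - 1L,
    mse = as.integer(pmin(mse, 6)),
    exct = as.integer(states$excess_type %||% rep(0L, n)),
    exck = as.integer(states$excess_clock %||% rep(0L, n)),
    pausek = as.integer(states$pause_clock %||% rep(0L, n)),
    acc_q = as.numeric(states$qalys %||% rep(0, n)),
    acc_life = as.numeric(states$life_years %||% rep(0, n)),
    acc_sub = as.numeric(states$subclinical_years %||% rep(0, n))
  )
}

internal_to_states_tibble <- function(st) {
  context <- dplyr::case_when(
    !st$alive ~ "dead",
    st$ctx == 3L ~ "clinical_af",
    st$ctx == 2L & st$pausek > 0L ~ "subclinical_paused",
    st$ctx == 2L ~ "subclinical_treated",
    TRUE ~ "subclinical_untreated"
  )
  tibble::tibble(
    context = context,
    disability = DISABILITY_LEVELS[st$dis + 1L],
    months_since_event = as.numeric(st$mse),
    excess_type = st$exct,
    excess_clock = st$exck,
    pause_clock = st$pausek,
    qalys = st$acc_q,
    life_years = st$acc_life,
    subclinical_years = st$acc_sub
  )
}

#' Advance a cohort of patient states by one model cycle
#'
#' Tibble-level interface to the engine's per-cycle transition: for each
#' alive patient one categorical draw over the competing outcomes
#' (four event types, death, clinical-AF conversion, remain), severity
#' resolution for events, clock updates, and cycle-start utility accrual.
#'
#' @param states A tibble of patient states with columns `context`
#'   (`"subclinical_untreated"`, `"subclinical_treated"`,
#'   `"subclinical_paused"`, `"clinical_af"`, `"dead"`), `disability`,
#'   `months_since_event`, `excess_type` (0 none / 1 ischemic /
#'   2 intracranial), `excess_clock`, `pause_clock`, and accumulators
#'   `qalys`, `life_years`, `subclinical_years` (missing columns default
#'   to event-free values).
#' @param config A `model_config`.
#' @param cycle 0-based cycle index (selects the age-band utility weight).
#' @param u_event,u_severity Optional per-patient uniforms in `[0,1]` for
#'   the outcome and severity draws (drawn from the session RNG if omitted).
#' @return The updated states tibble, with a one-row ledger tibble in
#'   attribute `"ledger"`.
#' @export
step_cycle <- function(states, config, cycle = 0L, u_event = NULL,
                       u_severity = NULL) {
  config <- as_model_config(config)
  cmod <- compile_model(config)
  st <- states_tibble_to_internal(states)
  n <- nrow(states)
  u1 <- u_event %||% runif(n)
  u2 <- u_severity %||% runif(n)
  res <- ms_step_internal(st, cmod, as.integer(cycle), u1, u2)
  out <- internal_to_states_tibble(res$st)
  s <- res$stats
  attr(out, "ledger") <- tibble::tibble(
    cycle = as.integer(cycle) + 1L, alive_start = s$alive_start,
    ischemic_stroke = s$events[1], hemorrhagic_stroke = s$events[2],
    other_intracranial_bleeding = s$events[3],
    extracranial_major_bleeding = s$events[4],
    deaths = s$deaths, caf_conversions = s$caf, qalys_accrued = s$qalys
  )
  out
}

#' Resolve the severity of an event for one patient
#'
#' Samples a severity from the supplied categorical distribution and applies
#' its consequences: a fatal draw kills the patient this cycle; otherwise
#' disability worsens to the sampled level if worse than current, the
#' 6-month utility phase restarts if the event is disabling, strokes and
#' intracranial bleeds start the 12-month excess-mortality clock, and a
#' major bleed on NOAC pauses anticoagulation for
#' `config$pause_cycles_after_bleed` cycles.
#'
#' @param state A one-row patient-state tibble (see [step_cycle()]).
#' @param event_type One of `"ischemic_stroke"`, `"hemorrhagic_stroke"`,
#'   `"other_intracranial_bleeding"`, `"extracranial_major_bleeding"`.
#' @param severity_distribution Named probability vector over severity
#'   categories (`death`, `severe`, `moderate`, `mild`, `none`); must sum
#'   to 1 within 1e-6.
#' @param config A `model_config`.
#' @param u Optional uniform in `[0,1]` for the severity draw.
#' @return The updated one-row state tibble.
#' @export
resolve_event <- function(state, event_type, severity_distribution, config,
                          u = NULL) {
  config <- as_model_config(config)
  cmod <- compile_model(config)
  k <- match(event_type, EVENT_TYPES)
  if (is.na(k)) abort(sprintf("Unknown event type '%s'.", event_type))
  p <- as.numeric(severity_distribution)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-6) {
    abort("`severity_distribution` must be non-negative and sum to 1.")
  }
  codes <- c(death = -1L, severe = 3L, moderate = 2L, mild = 1L, none = 0L)
  nm <- names(severity_distribution)
  if (is.null(nm) || !all(nm %in% names(codes))) {
    abort("`severity_distribution` must be named with severity categories.")
  }
  u <- u %||% runif(1)
  slot <- findInterval(u, cumsum(p), left.open = TRUE) + 1L
  slot <- min(slot, length(p))
  dcode <- codes[[nm[slot]]]
  st <- states_tibble_to_internal(state)
  st <- apply_event_consequences(st, 1L, k, dcode, cmod)
  internal_to_states_tibble(st)
}
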