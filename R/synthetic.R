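## Analytically solvable toy configurations and perturbed parameter tables.
## Toys reuse the full config schema (no special engine paths), so oracle
## tests exercise the production transition code.

toy_base_skeleton <- function(horizon, utility) {
  cfg <- unclass(base_case_config())
  cfg$horizon <- as.integer(horizon)
  cfg$event_rates <- list(
    ischemic_stroke = 0, major_bleeding_total = 0, hemorrhagic_stroke = 0,
    other_intracranial_bleeding = 0, extracranial_major_bleeding = 0,
    death = 0, clinical_af_progression = 0
  )
  cfg$clinical_af_risks <- list(
    ischemic_stroke = 0, hemorrhagic_stroke = 0,
    other_intracranial_bleeding = 0, extracranial_major_bleeding = 0,
    death = 0
  )
  ## identity treatment effect: both arms share the toy dynamics
  cfg$treatment_effect <- list(
    rr_ischemic_stroke = list(point = 1, ci_low = 1, ci_high = 1),
    rr_major_bleeding = list(point = 1, ci_low = 1, ci_high = 1)
  )
  ## flat utility age band wide enough for any horizon
  cfg$utility$bands <- list(from = 0, to = 200, weight = utility)
  cfg
}

#' Death-only toy model with closed-form life expectancy
#'
#' All event and progression rates are zero; patients face a constant
#' monthly death probability `q`. Expected life-months over `T` cycles have
#' the geometric-series closed form `(1 - (1-q)^T) / q` (or `T` when
#' `q = 0`), and expected QALYs are `utility` times that.
#'
#' @param monthly_death_prob Constant per-cycle death probability in
#'   `[0, 1)`.
#' @param horizon Number of cycles.
#' @param utility Flat utility weight in `[0, 1]`.
#' @return A `toy_model`: list with the `config`, the closed-form
#'   `expected` values, and the `formula` function that recomputes them.
#' @examples
#' toy <- make_death_only_toy(0.01, 12, 1.0)
#' toy$expected$life_years * 12  # expected life-months
#' @export
make_death_only_toy <- function(monthly_death_prob, horizon, utility = 1.0) {
  stopifnot(monthly_death_prob >= 0, monthly_death_prob < 1, horizon >= 0)
  cfg <- toy_base_skeleton(horizon, utility)
  cfg$name <- "toy_death_only"
  ## invert the exponential transform so the cycle probability is exactly q
  cfg$event_rates$death <- if (monthly_death_prob > 0) {
    cycle_prob_to_annual_rate(monthly_death_prob)
  } else 0
  formula <- function(q = monthly_death_prob, T = horizon, u = utility) {
    lm <- if (q > 0) (1 - (1 - q)^T) / q else T
    list(life_years = lm / 12, qalys = u * lm / 12)
  }
  structure(list(config = as_model_config(cfg), expected = formula(),
                 formula = formula),
            class = "toy_model")
}

#' Single-event toy model with closed-form ever-affected fraction
#'
#' One event type with constant monthly probability `p`, no mortality, and a
#' degenerate severity distribution placing all mass on one disability
#' level. Because disability is monotone, the expected fraction of patients
#' ever affected after `T` cycles is `1 - (1-p)^T`; expected QALYs decompose
#' over the time-to-most-recent-event distribution (both formulas are
#' stored and recomputable).
#'
#' @param monthly_event_prob Per-cycle event probability in `[0, 1]`.
#' @param severity `"mild"`, `"moderate"` or `"severe"`.
#' @param horizon Number of cycles.
#' @param utility Flat base utility weight.
#' @return A `toy_model` (see [make_death_only_toy()]); `expected` also
#'   contains `ever_affected_fraction`.
#' @export
make_single_event_toy <- function(monthly_event_prob, severity = "mild",
                                  horizon = 24, utility = 1.0) {
  stopifnot(monthly_event_prob >= 0, monthly_event_prob <= 1, horizon >= 0)
  severity <- match.arg(severity, c("mild", "moderate", "severe"))
  cfg <- toy_base_skeleton(horizon, utility)
  cfg$name <- "toy_single_event"
  ## use the extracranial type: no excess-mortality clock, so the only
  ## dynamics are the event counter, disability and the utility phase
  if (monthly_event_prob >= 1) {
    abort("`monthly_event_prob` must be < 1 for the rate parameterization; use 0.999999 for near-certain events.")
  }
  cfg$event_rates$extracranial_major_bleeding <-
    if (monthly_event_prob > 0) cycle_prob_to_annual_rate(monthly_event_prob) else 0
  cfg$event_rates$major_bleeding_total <- cfg$event_rates$extracranial_major_bleeding
  slot <- match(severity, c("severe", "mild"))  # extracranial categories: death, severe, mild, none
  if (severity == "moderate") {
    abort("The extracranial severity scale has no 'moderate'; use mild or severe.")
  }
  p <- c(0, 0, 0, 0)
  p[slot + 1L] <- 1  # slots: death, severe, mild, none
  cfg$severity$extracranial_major_bleeding$untreated <- p
  cfg$severity$extracranial_major_bleeding$treated <- p
  cfg$pause_cycles_after_bleed <- 0L

  ratio <- cfg$utility$qaly_ratio[[severity]]
  formula <- function(p = monthly_event_prob, T = horizon, u = utility,
                      r1 = ratio$first_6_months, r2 = ratio$after_6_months) {
    ever <- 1 - (1 - p)^T
    ## expected utility weight at cycle start t (0-based): no event yet
    ## (weight u), most recent disabling event within the past 6 cycles
    ## (u*r1), or earlier (u*r2)
    qalys <- 0
    for (t in seq_len(max(T, 0)) - 1L) {
      p_none <- (1 - p)^t                      # no event in cycles 0..t-1
      p_recent <- 1 - (1 - p)^min(6, t)        # >=1 event in cycles t-6..t-1
      p_old <- (1 - p)^min(6, t) - p_none      # had events, none in the last 6
      qalys <- qalys + u * (p_none + r1 * p_recent + r2 * p_old) / 12
    }
    list(ever_affected_fraction = ever, life_years = T / 12, qalys = qalys)
  }
  structure(list(config = as_model_config(cfg), expected = formula(),
                 formula = formula),
            class = "toy_model")
}

#' Randomly perturb a model configuration
#'
#' Multiplies each event rate and 1-year probability by an independent
#' log-normal factor (`sdlog = relative_scale`), perturbs severity columns
#' the same way and renormalizes them, and revalidates. Draws that violate
#' the schema (e.g. a clinical-AF probability sum reaching 1) are resampled.
#' Used for property tests: the solvers must return finite,
#' invariant-satisfying results on any schema-valid configuration.
#'
#' @param config A `model_config`.
#' @param seed Optional integer seed for reproducibility.
#' @param relative_scale Log-scale standard deviation of the perturbation
#'   factors (0 returns the config unchanged).
#' @return A perturbed, validated `model_config`.
#' @export
perturb_parameters <- function(config, seed = NULL, relative_scale = 0.1) {
  stopifnot(relative_scale >= 0)
  config <- as_model_config(config)
  if (relative_scale == 0) return(config)
  run <- function() perturb_impl(config, relative_scale)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

perturb_impl <- function(config, scale, max_tries = 100) {
  for (try in seq_len(max_tries)) {
    cfg <- unclass(config)
    f <- function(x) x * exp(rnorm(length(x), 0, scale))
    er <- cfg$event_rates
    er$ischemic_stroke <- f(er$ischemic_stroke)
    er$hemorrhagic_stroke <- f(er$hemorrhagic_stroke)
    er$other_intracranial_bleeding <- f(er$other_intracranial_bleeding)
    er$extracranial_major_bleeding <- f(er$extracranial_major_bleeding)
    er$major_bleeding_total <- er$hemorrhagic_stroke +
      er$other_intracranial_bleeding + er$extracranial_major_bleeding
    er$death <- f(er$death)
    er$clinical_af_progression <- f(er$clinical_af_progression)
    cfg$event_rates <- er
    cfg$clinical_af_risks <- lapply(cfg$clinical_af_risks,
                                    function(p) min(f(p), 0.99))
    for (ev in EVENT_TYPES) {
      for (colnm in c("untreated", "treated")) {
        p <- f(as.numeric(cfg$severity[[ev]][[colnm]]))
        cfg$severity[[ev]][[colnm]] <- p / sum(p)
      }
    }
    ok <- tryCatch({
      out <- as_model_config(cfg)
      compile_model(out)  # also guards total exit probability < 1
      TRUE
    }, error = function(e) FALSE)
    if (ok) return(out)
  }
  abort("Failed to draw a schema-valid perturbed configuration.")
}
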