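test_that("cohort solver reproduces geometric-series life expectancy exactly", {
  for (case in list(list(q = 0.01, T = 12L, u = 1.0),
                    list(q = 0.3, T = 40L, u = 0.6),
                    list(q = 0, T = 24L, u = 0.8))) {
    toy <- make_death_only_toy(case$q, case$T, case$u)
    res <- solve_cohort_expectation(toy$config, "without_noac")
    n <- toy$config$n_patients
    expect_equal(res$totals$life_years / n, toy$expected$life_years,
                 tolerance = 1e-10)
    expect_equal(res$totals$qalys / n, toy$expected$qalys, tolerance = 1e-10)
  }
  ## frozen spec value: q = 0.01, 12 cycles -> 11.3616 expected life-months
  toy <- make_death_only_toy(0.01, 12L, 1.0)
  expect_equal(toy$expected$life_years * 12, 11.36151, tolerance = 1e-5)
})

test_that("zero rates accrue the age-band utility schedule exactly", {
  cfg <- unclass(base_cfg())
  cfg$event_rates <- lapply(cfg$event_rates, function(x) 0)
  cfg$clinical_af_risks <- lapply(cfg$clinical_af_risks, function(x) 0)
  res <- solve_cohort_expectation(as_model_config(cfg), "without_noac")
  n <- cfg$n_patients
  ## 3 years at 0.794 + 7 years at 0.733 per patient
  expect_equal(res$totals$qalys / n, 3 * 0.794 + 7 * 0.733, tolerance = 1e-10)
  expect_equal(res$totals$life_years / n, 10, tolerance = 1e-10)
  expect_equal(res$totals$deaths, 0)
  ## microsim is exact here (no randomness in outcomes affects survival)
  ms <- simulate_microsim(as_model_config(cfg), "without_noac", seed = 1,
                          n_patients = 50)
  expect_equal(ms$totals$qalys / 50, 3 * 0.794 + 7 * 0.733, tolerance = 1e-10)
})

test_that("horizon zero gives empty results", {
  cfg <- base_cfg()
  cfg$horizon <- 0L
  co <- solve_cohort_expectation(cfg, "with_noac")
  expect_equal(co$totals$qalys, 0)
  expect_equal(co$totals$ischemic_stroke, 0)
  ms <- simulate_microsim(cfg, "with_noac", seed = 1, n_patients = 10)
  expect_equal(ms$totals$qalys, 0)
  expect_equal(ms$totals$deaths, 0)
})

test_that("identity treatment effect with shared severities makes arms identical", {
  cfg <- identity_effect_cfg()
  wo <- solve_cohort_expectation(cfg, "without_noac")
  wi <- solve_cohort_expectation(cfg, "with_noac")
  expect_equal(totals_vec(wo), totals_vec(wi), tolerance = 1e-10)
  summ <- compare_arms(wo, wi)
  expect_true(all(abs(summ$table$difference) < 1e-9 * summ$n_patients))
})

test_that("QALY advantage of NOAC is monotone in the stroke relative risk", {
  cfg <- base_cfg()
  cfg$horizon <- 60L
  diffs <- vapply(c(0.5, 0.68, 0.9, 1.1), function(rr) {
    cfg$treatment_effect$rr_ischemic_stroke <- list(point = rr, ci_low = rr, ci_high = rr)
    glance(run_decision_model(cfg, mode = "cohort"))$qaly_diff_per_patient
  }, numeric(1))
  expect_true(all(diff(diffs) < 0))
})

test_that("microsimulation is deterministic given the seed", {
  cfg <- small_cfg(n = 1500L, horizon = 60L)
  a <- simulate_microsim(cfg, "with_noac", seed = 11)
  b <- simulate_microsim(cfg, "with_noac", seed = 11)
  expect_identical(totals_vec(a), totals_vec(b))
  expect_identical(a$trajectories, b$trajectories)
  c2 <- simulate_microsim(cfg, "with_noac", seed = 12)
  expect_false(identical(totals_vec(a), totals_vec(c2)))
})

test_that("conservation: deaths plus survivors equal the cohort, QALYs <= life-years", {
  cfg <- small_cfg(n = 3000L)
  for (arm in c("without_noac", "with_noac")) {
    ms <- simulate_microsim(cfg, arm, seed = 5)
    fd <- ms$final_disability
    expect_equal(sum(fd$count), cfg$n_patients)
    expect_equal(ms$totals$deaths, fd$count[fd$disability == "dead"])
    expect_lte(ms$totals$qalys, ms$totals$life_years)
    expect_gte(ms$totals$qalys, 0)
    ## alive counts non-increasing over cycles
    expect_true(all(diff(ms$trajectories$alive_start) <= 0))
    co <- solve_cohort_expectation(cfg, arm)
    expect_equal(sum(co$final_disability$count), cfg$n_patients, tolerance = 1e-9)
    expect_lte(co$totals$qalys, co$totals$life_years)
  }
})

test_that("microsimulation agrees with the cohort expectation within 3 SE", {
  cfg <- base_cfg()
  n <- 30000L
  ms <- simulate_microsim(cfg, "with_noac", seed = 21, n_patients = n)
  co <- solve_cohort_expectation(cfg, "with_noac")
  scale <- n / cfg$n_patients
  expect_lt(abs(ms$totals$qalys / scale - co$totals$qalys) /
              (ms$qaly_sd / sqrt(n) * cfg$n_patients), 3)
  expect_lt(abs(ms$totals$life_years / scale - co$totals$life_years) /
              (ms$life_sd / sqrt(n) * cfg$n_patients), 3)
  for (m in c("ischemic_stroke", "extracranial_major_bleeding", "deaths")) {
    expect_lt(abs(count_z(ms$totals[[m]] / scale, co$totals[[m]])) * sqrt(scale), 3.5)
  }
})

test_that("common random numbers reduce the variance of arm differences", {
  cfg <- small_cfg(n = 4000L, horizon = 60L)
  d_crn <- vapply(1:4, function(s) {
    glance(run_decision_model(cfg, mode = "microsim", seed = s, use_crn = TRUE))$qaly_diff_per_patient
  }, numeric(1))
  d_ind <- vapply(1:4, function(s) {
    glance(run_decision_model(cfg, mode = "microsim", seed = s, use_crn = FALSE))$qaly_diff_per_patient
  }, numeric(1))
  expect_lt(sd(d_crn), sd(d_ind) + 0.05)  # CRN at least comparable; typically much smaller
  ## CRN runs are reproducible
  expect_identical(
    glance(run_decision_model(cfg, mode = "microsim", seed = 3, use_crn = TRUE)),
    glance(run_decision_model(cfg, mode = "microsim", seed = 3, use_crn = TRUE))
  )
})

test_that("step_cycle with zero rates accrues base utility and changes nothing", {
  cfg <- unclass(base_cfg())
  cfg$event_rates <- lapply(cfg$event_rates, function(x) 0)
  cfg$clinical_af_risks <- lapply(cfg$clinical_af_risks, function(x) 0)
  cfg <- as_model_config(cfg)
  states <- tibble::tibble(
    context = c("subclinical_untreated", "subclinical_treated", "clinical_af"),
    disability = "none", months_since_event = Inf,
    excess_type = 0L, excess_clock = 0L, pause_clock = 0L,
    qalys = 0, life_years = 0, subclinical_years = 0
  )
  out <- step_cycle(states, cfg, cycle = 0, u_event = rep(0.99, 3),
                    u_severity = rep(0.5, 3))
  expect_equal(out$context, states$context)
  expect_equal(out$qalys, rep(0.794 / 12, 3))
  led <- attr(out, "ledger")
  expect_equal(led$deaths, 0)
  expect_equal(led$alive_start, 3)
})

test_that("excess mortality combines with background as independent hazards", {
  cfg <- base_cfg()
  p_bg <- annual_rate_to_cycle_prob(cfg$event_rates$death)
  p_exc <- annual_prob_to_cycle_prob(0.14)
  p_comb <- 1 - (1 - p_bg) * (1 - p_exc)
  base <- tibble::tibble(
    context = "subclinical_untreated", disability = "mild",
    months_since_event = 2, excess_type = 1L, excess_clock = 6L,
    pause_clock = 0L, qalys = 0, life_years = 0, subclinical_years = 0
  )
  ## an outcome draw just below the combined death threshold kills;
  ## just above survives (event probabilities precede death in the draw)
  q_events <- sum(compile_for_test(cfg)[1, 1:4])
  dead <- step_cycle(base, cfg, cycle = 0, u_event = q_events + p_comb - 1e-9,
                     u_severity = 0.5)
  expect_equal(dead$context, "dead")
  alive <- step_cycle(base, cfg, cycle = 0, u_event = q_events + p_comb + 1e-9,
                      u_severity = 0.5)
  expect_false(alive$context == "dead")
})

test_that("clinical-AF mortality replaces the subclinical background rate", {
  cfg <- base_cfg()
  p_caf_death <- annual_prob_to_cycle_prob(cfg$clinical_af_risks$death)
  q_events <- sum(compile_for_test(cfg)[3, 1:4])
  st <- tibble::tibble(
    context = "clinical_af", disability = "none", months_since_event = Inf,
    excess_type = 0L, excess_clock = 0L, pause_clock = 0L,
    qalys = 0, life_years = 0, subclinical_years = 0
  )
  dead <- step_cycle(st, cfg, cycle = 0, u_event = q_events + p_caf_death - 1e-9,
                     u_severity = 0.5)
  expect_equal(dead$context, "dead")
  alive <- step_cycle(st, cfg, cycle = 0, u_event = q_events + p_caf_death + 1e-9,
                      u_severity = 0.5)
  expect_equal(alive$context, "clinical_af")
})

test_that("resolve_event applies severity consequences", {
  cfg <- base_cfg()
  st <- tibble::tibble(
    context = "subclinical_treated", disability = "none",
    months_since_event = Inf, excess_type = 0L, excess_clock = 0L,
    pause_clock = 0L, qalys = 0, life_years = 0, subclinical_years = 0
  )
  ## fatal draw: the untreated ischemic-stroke death probability is 0.187
  out <- resolve_event(st, "ischemic_stroke",
                       c(death = 0.187, severe = 0.156, moderate = 0.220, mild = 0.437),
                       cfg, u = 0.10)
  expect_equal(out$context, "dead")

  ## non-disabling extracranial bleed on NOAC: pause starts, disability kept
  out2 <- resolve_event(st, "extracranial_major_bleeding",
                        c(death = 0.035, severe = 0.007, mild = 0.056, none = 0.902),
                        cfg, u = 0.5)
  expect_equal(out2$disability, "none")
  expect_equal(out2$pause_clock, 1L)
  expect_equal(out2$context, "subclinical_paused")
  expect_equal(out2$excess_clock, 0L)  # extracranial bleeds carry no excess mortality

  ## degenerate distribution: always mild, never fatal; stroke starts the
  ## excess-mortality clock and the 6-month utility phase
  out3 <- resolve_event(st, "ischemic_stroke", c(mild = 1), cfg, u = 0.999)
  expect_equal(out3$disability, "mild")
  expect_equal(out3$months_since_event, 0)
  expect_equal(out3$excess_clock, 12L)

  ## disability never improves: a later mild event keeps severe level
  sev <- out3
  sev$disability <- "severe"
  out4 <- resolve_event(sev, "ischemic_stroke", c(mild = 1), cfg, u = 0.5)
  expect_equal(out4$disability, "severe")

  expect_error(resolve_event(st, "ischemic_stroke", c(mild = 0.5), cfg, u = 0.1),
               "sum to 1")
})
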