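test_that("rate and probability transforms match their closed forms", {
  ## constant-hazard transform, frozen values computed from the closed form
  expect_equal(annual_rate_to_cycle_prob(1.05, 1), 1 - exp(-0.0105 / 12))
  expect_equal(annual_rate_to_cycle_prob(1.05, 1), 8.746173e-4, tolerance = 1e-6)
  expect_equal(annual_rate_to_cycle_prob(4.26, 1), 3.543706e-3, tolerance = 1e-6)
  expect_identical(annual_rate_to_cycle_prob(0, 1), 0)
  expect_error(annual_rate_to_cycle_prob(-1), "non-negative")

  ## compounding transform for 1-year probabilities
  expect_equal(annual_prob_to_cycle_prob(0.110), 1 - 0.890^(1 / 12))
  expect_equal(annual_prob_to_cycle_prob(0.110), 9.664150e-3, tolerance = 1e-6)
  expect_equal(annual_prob_to_cycle_prob(0.14), 1.248992e-2, tolerance = 1e-6)
  expect_identical(annual_prob_to_cycle_prob(0), 0)
  expect_error(annual_prob_to_cycle_prob(1.2), "probability")
})

test_that("transform round trips are exact", {
  rates <- c(0.01, 0.73, 1.05, 4.26, 7.5, 50)
  expect_equal(cycle_prob_to_annual_rate(annual_rate_to_cycle_prob(rates)),
               rates, tolerance = 1e-12)
  ## monthly probability compounded over 12 cycles reproduces the 1-year
  ## probability
  p1y <- c(0.005, 0.025, 0.11, 0.5)
  pm <- annual_prob_to_cycle_prob(p1y)
  expect_equal(1 - (1 - pm)^12, p1y, tolerance = 1e-12)
  ## monotone in the rate
  expect_true(all(diff(annual_rate_to_cycle_prob(seq(0, 10, by = 0.5))) > 0))
})

test_that("NOAC-arm rates follow the bleeding-weight allocation algebra", {
  cfg <- base_cfg()
  tr <- noac_treated_annual_rates(cfg$event_rates, cfg$treatment_effect, 0.80)
  ## frozen values from the allocation algebra on the published inputs
  expect_equal(tr$ischemic_stroke, 0.7140, tolerance = 1e-9)
  expect_equal(tr$extracranial_major_bleeding, 1.25576, tolerance = 1e-9)
  expect_equal(tr$hemorrhagic_stroke, 0.2516945455, tolerance = 1e-6)
  expect_equal(tr$other_intracranial_bleeding, 0.2097454545, tolerance = 1e-6)
  ## conservation: treated subtypes sum to total x RR
  expect_equal(tr$major_bleeding_total, 1.06 * 1.62, tolerance = 1e-9)
  ## death and progression unchanged across arms
  expect_equal(tr$death, cfg$event_rates$death)
  expect_equal(tr$clinical_af_progression, cfg$event_rates$clinical_af_progression)

  ## weight 1: intracranial subtypes unchanged, all increase extracranial
  tr1 <- noac_treated_annual_rates(cfg$event_rates, cfg$treatment_effect, 1.0)
  expect_equal(tr1$hemorrhagic_stroke, 0.18)
  expect_equal(tr1$other_intracranial_bleeding, 0.15)
  expect_equal(tr1$extracranial_major_bleeding, 0.73 + 1.06 * 0.62, tolerance = 1e-9)

  ## identity effect: treated rates equal untreated rates
  eff1 <- list(rr_ischemic_stroke = list(point = 1, ci_low = 1, ci_high = 1),
               rr_major_bleeding = list(point = 1, ci_low = 1, ci_high = 1))
  tr_id <- noac_treated_annual_rates(cfg$event_rates, eff1, 0.80)
  expect_equal(tr_id$ischemic_stroke, cfg$event_rates$ischemic_stroke)
  expect_equal(tr_id$extracranial_major_bleeding, cfg$event_rates$extracranial_major_bleeding)

  ## a protective bleeding RR with full extracranial weight can push a
  ## subtype negative -> error
  eff_neg <- list(rr_ischemic_stroke = list(point = 1, ci_low = 1, ci_high = 1),
                  rr_major_bleeding = list(point = 0.05, ci_low = 0.05, ci_high = 0.05))
  expect_error(noac_treated_annual_rates(cfg$event_rates, eff_neg, 1.0), "negative")
})

test_that("conservation holds for any weight and RR > 1", {
  cfg <- base_cfg()
  for (w in c(0, 0.25, 0.5, 0.8, 1)) {
    for (rr in c(1.01, 1.62, 2.5)) {
      eff <- cfg$treatment_effect
      eff$rr_major_bleeding[c("point", "ci_low", "ci_high")] <- rr
      tr <- noac_treated_annual_rates(cfg$event_rates, eff, w)
      expect_gte(tr$hemorrhagic_stroke, cfg$event_rates$hemorrhagic_stroke)
      expect_gte(tr$other_intracranial_bleeding, cfg$event_rates$other_intracranial_bleeding)
      expect_gte(tr$extracranial_major_bleeding, cfg$event_rates$extracranial_major_bleeding)
      expect_equal(tr$major_bleeding_total, 1.06 * rr, tolerance = 1e-9)
    }
  }
})

test_that("severity columns renormalize proportionally", {
  cfg <- base_cfg()
  norm <- normalize_severity_table(cfg$severity)
  ## the on-NOAC hemorrhagic column sums to 0.994 before normalization
  expect_equal(norm$hemorrhagic_stroke$treated,
               c(0.305, 0.206, 0.190, 0.293) / 0.994, tolerance = 1e-12)
  ## already-normalized columns are unchanged
  expect_equal(norm$ischemic_stroke$untreated, c(0.187, 0.156, 0.220, 0.437))
  ## all columns sum to exactly 1
  for (ev in names(norm)) {
    expect_equal(sum(norm[[ev]]$untreated), 1, tolerance = 1e-12)
    expect_equal(sum(norm[[ev]]$treated), 1, tolerance = 1e-12)
  }
  bad <- cfg$severity
  bad$ischemic_stroke$untreated[1] <- -0.1
  expect_error(normalize_severity_table(bad), "negative")
  typo <- cfg$severity
  typo$ischemic_stroke$treated <- c(0.12, 0.12, 0.12, 0.12)
  expect_error(normalize_severity_table(typo), "0.97")
})

test_that("config loading validates, fills defaults, and round-trips", {
  cfg <- load_model_config(noacaf_config_path("base_case.yaml"))
  expect_s3_class(cfg, "model_config")
  expect_equal(cfg$event_rates$ischemic_stroke, 1.05)
  expect_equal(cfg$horizon, 120L)

  ## defaults fill for omitted optional fields
  raw <- yaml::read_yaml(noacaf_config_path("base_case.yaml"))
  raw$rng_seed <- NULL
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(raw, f)
  expect_equal(load_model_config(f)$rng_seed, 42L)

  ## schema violations name the offending field
  raw2 <- yaml::read_yaml(noacaf_config_path("base_case.yaml"))
  raw2$extracranial_bleed_weight <- 1.2
  yaml::write_yaml(raw2, f)
  expect_error(load_model_config(f), "extracranial_bleed_weight")
  raw3 <- yaml::read_yaml(noacaf_config_path("base_case.yaml"))
  raw3$event_rates$hemorrhagic_stroke <- 0.5
  yaml::write_yaml(raw3, f)
  expect_error(load_model_config(f), "major_bleeding_total")

  ## lossless re-serialization
  f2 <- withr::local_tempfile(fileext = ".yaml")
  write_model_config(cfg, f2)
  cfg2 <- load_model_config(f2)
  expect_equal(unclass(cfg2), unclass(cfg), tolerance = 1e-10)
})

test_that("utility weights multiply the age-band base by the disability ratio", {
  cfg <- base_cfg()
  expect_equal(utility_weight(
    data.frame(age = 78, disability = "none", months_since_event = NA), cfg), 0.794)
  expect_equal(utility_weight(
    data.frame(age = 82, disability = "severe", months_since_event = 8), cfg),
    0.733 * 0.45)
  expect_equal(utility_weight(
    data.frame(age = 79, disability = "moderate", months_since_event = 2), cfg),
    0.794 * 0.60)
  expect_equal(utility_weight(
    data.frame(age = 80, disability = "dead", months_since_event = 0), cfg), 0)
  expect_error(utility_weight(
    data.frame(age = 95, disability = "none", months_since_event = NA), cfg),
    "age bands")
})
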