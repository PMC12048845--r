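## Probabilistic sensitivity analysis: log-normal sampling of the two
## published relative risks, a two-arm model run per draw, and aggregation
## of the probability and magnitude of net benefit.

Z975 <- 1.959964  # 97.5% standard-normal quantile used for 95% CIs

#' Fit a log-normal distribution to a published relative risk and 95% CI
#'
#' Assumes the RR is log-normally distributed with the point estimate as
#' median: `mu = log(point)`, `sigma = (log(hi) - log(lo)) / (2 * 1.959964)`.
#'
#' @param point,lo,hi Point estimate and 95% confidence limits (all > 0,
#'   `lo <= point <= hi`).
#' @return A list with elements `mu` and `sigma`.
#' @examples
#' lognormal_params_from_ci(0.68, 0.50, 0.92)
#' @export
lognormal_params_from_ci <- function(point, lo, hi) {
  if (any(c(point, lo, hi) <= 0)) abort("Ratios must be positive.")
  if (!(lo <= point && point <= hi)) abort("Require lo <= point <= hi.")
  list(mu = log(point), sigma = (log(hi) - log(lo)) / (2 * Z975))
}

#' Sample treatment-effect pairs for the PSA
#'
#' Draws `n` independent (stroke RR, bleeding RR) pairs from the log-normal
#' distributions fitted to the published confidence intervals. The two
#' effects are sampled independently.
#'
#' @param effect The `treatment_effect` section of a `model_config`.
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @return A tibble with columns `rr_stroke` and `rr_bleed`.
#' @export
sample_treatment_effects <- function(effect, n, seed = NULL) {
  stopifnot(n >= 1)
  s <- effect$rr_ischemic_stroke
  b <- effect$rr_major_bleeding
  ls <- lognormal_params_from_ci(s$point, s$ci_low, s$ci_high)
  lb <- lognormal_params_from_ci(b$point, b$ci_low, b$ci_high)
  draw <- function() tibble::tibble(
    rr_stroke = exp(rnorm(n, ls$mu, ls$sigma)),
    rr_bleed = exp(rnorm(n, lb$mu, lb$sigma))
  )
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Run the probabilistic sensitivity analysis
#'
#' Per iteration: sample the two relative risks, re-derive the NOAC-arm
#' event rates with the configured bleeding weight, run both arms, and
#' record the per-patient QALY difference (NOAC minus no NOAC). In
#' `"microsim"` mode each iteration runs independent patient-level
#' simulations in both arms, so the favouring proportion reflects both
#' parameter uncertainty and Monte-Carlo noise — the published analysis did
#' the same. `"cohort"` mode removes the Monte-Carlo noise and therefore
#' yields a somewhat higher favouring proportion; this is expected
#' behaviour, not a defect.
#'
#' Draws for which the derived treated rates would go negative are
#' resampled; the resample count is recorded.
#'
#' @param config A `model_config`.
#' @param n_iterations Number of parameter draws.
#' @param n_patients_per_iter Patients per arm per iteration (microsim
#'   mode); defaults to `config$n_patients`.
#' @param mode `"microsim"` or `"cohort"`.
#' @param seed Integer seed; defaults to `config$rng_seed`.
#' @return A `psa_result` with per-iteration tibble and aggregates.
#' @export
run_psa <- function(config, n_iterations = 2000,
                    n_patients_per_iter = NULL,
                    mode = c("microsim", "cohort"), seed = NULL) {
  mode <- match.arg(mode)
  config <- as_model_config(config)
  seed <- seed %||% config$rng_seed
  if (!is.null(n_patients_per_iter)) {
    config$n_patients <- as.integer(n_patients_per_iter)
  }
  withr::with_seed(seed, run_psa_impl(config, n_iterations, mode))
}

run_psa_impl <- function(config, n_iterations, mode) {
  draws <- sample_treatment_effects(config$treatment_effect, n_iterations)
  n_resampled <- 0L
  qd <- numeric(n_iterations)
  for (i in seq_len(n_iterations)) {
    repeat {
      cfg_i <- config
      cfg_i$treatment_effect$rr_ischemic_stroke[c("point", "ci_low", "ci_high")] <-
        draws$rr_stroke[i]
      cfg_i$treatment_effect$rr_major_bleeding[c("point", "ci_low", "ci_high")] <-
        draws$rr_bleed[i]
      ok <- tryCatch({
        noac_treated_annual_rates(cfg_i$event_rates, cfg_i$treatment_effect,
                                  config$extracranial_bleed_weight)
        TRUE
      }, error = function(e) FALSE)
      if (ok) break
      n_resampled <- n_resampled + 1L
      rd <- sample_treatment_effects(config$treatment_effect, 1)
      draws$rr_stroke[i] <- rd$rr_stroke
      draws$rr_bleed[i] <- rd$rr_bleed
    }
    if (mode == "cohort") {
      summ <- run_decision_model(cfg_i, mode = "cohort")
    } else {
      wo <- simulate_microsim(cfg_i, "without_noac", seed = NA)
      wi <- simulate_microsim(cfg_i, "with_noac", seed = NA)
      summ <- compare_arms(wo, wi)
    }
    qd[i] <- qaly_diff_per_patient(summ)
  }
  iterations <- tibble::tibble(
    iteration = seq_len(n_iterations),
    rr_stroke = draws$rr_stroke,
    rr_bleed = draws$rr_bleed,
    qaly_diff = qd
  )
  structure(
    list(
      iterations = iterations,
      proportion_favoring_noac = mean(qd > 0),
      mean_qaly_diff = mean(qd),
      n_iterations = n_iterations,
      n_patients_per_iter = config$n_patients,
      mode = mode,
      n_resampled = n_resampled
    ),
    class = "psa_result"
  )
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result: %d iterations, %s mode, %d patients/arm/iteration>\n",
              x$n_iterations, x$mode, x$n_patients_per_iter))
  cat(sprintf("  P(NOAC gains QALYs) = %.1f%%; mean QALY difference = %.4f/patient\n",
              100 * x$proportion_favoring_noac, x$mean_qaly_diff))
  if (x$n_resampled > 0) cat(sprintf("  (%d draws resampled)\n", x$n_resampled))
  invisible(x)
}

#' Summarize a PSA run
#'
#' @param result A `psa_result`.
#' @return A one-row tibble: favouring proportion, mean/median QALY
#'   difference and 2.5/97.5 percentiles, iteration count, resample count.
#' @export
summarize_psa <- function(result) {
  stopifnot(inherits(result, "psa_result"))
  if (result$n_iterations < 1) abort("PSA result has no iterations.")
  qd <- result$iterations$qaly_diff
  tibble::tibble(
    n_iterations = result$n_iterations,
    mode = result$mode,
    proportion_favoring_noac = mean(qd > 0),
    mean_qaly_diff = mean(qd),
    median_qaly_diff = median(qd),
    q025_qaly_diff = unname(quantile(qd, 0.025)),
    q975_qaly_diff = unname(quantile(qd, 0.975)),
    n_resampled = result$n_resampled
  )
}
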