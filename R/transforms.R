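#' Convert an annual event rate to a per-cycle probability
#'
#' Uses the constant-hazard (exponential) transform, the standard conversion
#' in discrete-time decision models: a rate of `r` events per 100
#' patient-years over a cycle of `cycle_months` months gives probability
#' `1 - exp(-(r/100) * cycle_months/12)`.
#'
#' @param rate Annual event rate per 100 patient-years (non-negative).
#' @param cycle_months Cycle length in months. Default 1.
#' @return Per-cycle probability, same length as `rate`.
#' @examples
#' annual_rate_to_cycle_prob(1.05) # monthly ischemic stroke probability
#' @export
annual_rate_to_cycle_prob <- function(rate, cycle_months = 1) {
  if (any(!is.finite(rate)) || any(rate < 0)) {
    abort("`rate` must be finite and non-negative (per 100 patient-years).")
  }
  if (any(cycle_months <= 0)) abort("`cycle_months` must be positive.")
  1 - exp(-(rate / 100) * cycle_months / 12)
}

#' Recover an annual rate from a per-cycle probability
#'
#' Inverse of [annual_rate_to_cycle_prob()].
#'
#' @param p Per-cycle probability in `[0, 1)`.
#' @param cycle_months Cycle length in months. Default 1.
#' @return Annual rate per 100 patient-years.
#' @export
cycle_prob_to_annual_rate <- function(p, cycle_months = 1) {
  if (any(p < 0) || any(p >= 1)) abort("`p` must lie in [0, 1).")
  -log(1 - p) * 100 * 12 / cycle_months
}

#' Convert a 1-year probability to a per-cycle probability
#'
#' Uses the compounding transform `1 - (1 - p)^(cycle_months/12)`, so that
#' twelve monthly cycles reproduce the annual probability exactly.
#'
#' @param p One-year probability in `[0, 1)`.
#' @param cycle_months Cycle length in months. Default 1.
#' @return Per-cycle probability.
#' @examples
#' annual_prob_to_cycle_prob(0.110) # monthly death probability in clinical AF
#' @export
annual_prob_to_cycle_prob <- function(p, cycle_months = 1) {
  if (any(!is.finite(p)) || any(p < 0) || any(p >= 1)) {
    abort("`p` must be a probability in [0, 1).")
  }
  1 - (1 - p)^(cycle_months / 12)
}
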