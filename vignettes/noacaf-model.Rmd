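---
title: "The noacaf decision model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The noacaf decision model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The clinical question

Implanted cardiac devices detect short, asymptomatic atrial high-rate
episodes — *subclinical atrial fibrillation* (AF) — in patients who would
never have come to clinical attention. Two randomized trials showed that
non-vitamin K antagonist oral anticoagulants (NOACs) reduce ischemic stroke
in this population (pooled relative risk 0.68) at the cost of more major
bleeding (pooled RR 1.62), on top of an untreated stroke rate of only about
1 per 100 patient-years. Whether that trade is worth making cannot be read
off the event counts, because the events differ enormously in severity:
strokes disable and kill more than extracranial bleeds, anticoagulation
makes strokes milder but intracranial bleeds deadlier, and a high competing
mortality limits how much of any benefit patients live to collect.

`noacaf` quantifies the trade as quality-adjusted life-years (QALYs) with a
discrete-time Markov state-transition model: two identical cohorts of
77-year-old patients with subclinical AF are followed for 10 years in
monthly cycles, one cohort starting a NOAC and one withholding it, and
every event, death and quality-weighted month is accounted.

## Health states and transitions

Each patient occupies one context:

* **subclinical AF, untreated**
* **subclinical AF, on NOAC** (temporarily *paused* while the post-bleed
  pause clock runs)
* **clinical AF** — overt, diagnosed AF with guideline-directed management;
  both decision arms are treated identically here
* **dead** (absorbing)

crossed with a disability level (`none`, `mild`, `moderate`, `severe`), a
months-since-last-event counter (drives the 6-month utility phase), a
12-cycle post-event excess-mortality clock, and the pause clock.

Each cycle, one categorical draw per alive patient selects among seven
competing outcomes: ischemic stroke, hemorrhagic stroke, other intracranial
bleeding, extracranial major bleeding, death, conversion to clinical AF, or
no transition. Monthly probabilities are small (≤ 0.01), so the
"remain" probability `1 − Σp` is always comfortably positive; the engine
errors if any context's exit probabilities reach 1.

Event severities are drawn from the configured categorical distributions —
the *with-NOAC* columns while actively treated or in clinical AF, the
*without-NOAC* columns otherwise (including during a pause). A `death`
severity kills immediately (this carries the acute 30-day case fatality).
A disabling severity worsens the patient's disability if worse than the
current level — disability never improves — and restarts the 6-month
utility phase. Strokes and intracranial bleeds also start a 12-cycle
excess-mortality clock. Any major bleed on NOAC pauses treatment for one
cycle (untreated rates *and* untreated severities during the pause).

## Parameters

All inputs ship in `inst/extdata/configs/base_case.yaml` and are validated
on load:

* untreated annual event rates per 100 patient-years (ischemic stroke 1.05,
  major bleeding 1.06 split 0.18/0.15/0.73 across subtypes, death 4.26,
  progression to clinical AF 7.50), converted to monthly probabilities with
  the constant-hazard transform `1 − exp(−r/100 · 1/12)`;
* treatment effects as relative risks with 95% CIs (stroke 0.68, 0.50–0.92;
  major bleeding 1.62, 1.05–2.50);
* severity distributions per event type and treatment status (columns are
  renormalized to sum to exactly 1, since the published values carry
  rounding — e.g. the treated hemorrhagic-stroke column sums to 0.994);
* age-band utility weights (0.794 for ages 77–<80, 0.733 from 80) and
  disability QALY ratios with a first-6-months and an after-6-months value;
* first-year post-event mortality (1-year probabilities 0.14 after ischemic
  stroke, 0.16 after intracranial bleeding), converted by compounding
  `1 − (1−p)^{1/12}` and combined with background mortality as independent
  hazards, `p = 1 − (1−p_bg)(1−p_excess)`;
* clinical-AF 1-year event probabilities; the clinical-AF death probability
  (0.110) is all-cause for that population and therefore *replaces* the
  subclinical background mortality rather than adding to it.

The NOAC arm's rates are derived, not configured: the stroke rate is
multiplied by its RR, and the bleeding increase
`Δ = 1.06 × (RR_bleed − 1)` is allocated 80% (configurable 0–1) to
extracranial bleeding, the remaining 20% split between the two intracranial
subtypes in proportion to their untreated rates (0.18 : 0.15) — the source
specifies only the intracranial/extracranial split, and the proportional
rule keeps subtype shares stable. The treated subtypes then sum exactly to
`1.06 × RR_bleed`. Death and progression rates are identical in both arms.

## Utility accrual

A patient's per-cycle weight is the age-band base weight times the QALY
ratio for the current worst disability, using the first-6-months ratio
while fewer than six months have passed since the last disabling event.
The ratio always multiplies the age-band base — not the previous product —
so repeat events do not compound ratios toward zero; the worst disability
governs. Rewards follow the standard cycle-start convention with no
half-cycle correction and no discounting: everyone alive at the start of a
cycle accrues that cycle's `weight/12` QALYs and `1/12` life-years,
including patients who die during the cycle. On the death-only toy model
this makes expected life-months exactly `(1 − (1−q)^T)/q`, the geometric
series the test suite checks to 1e-10.

## Two engines, one model

`simulate_microsim()` draws individual patient trajectories (vectorized
over the cohort, two uniform draws per patient-cycle, bit-reproducible
given a seed, optional common random numbers pairing the draws across
arms). `solve_cohort_expectation()` propagates the exact expected occupancy
distribution over the expanded state space (context × disability ×
months-since-event bucket × excess clock × pause clock, ~4200 states in the
base case) and returns the expectation the microsimulation converges to.
The solvers share the transition rules; the test suite holds them to
agreement within 3 Monte-Carlo standard errors at 50 000 patients on every
shipped configuration, and to closed forms on analytically solvable toys.

## Monte-Carlo noise and reproducing the published differences

At 10 000 patients per arm with independently simulated arms, the standard
error of the per-patient QALY difference is ≈ 0.028 — larger than the
base-case difference itself. Single-run differences at this size are
therefore indicative, not precise. The exact cohort solver puts the
base-case NOAC advantage at **0.016 QALYs per patient** (and the
probabilistic sensitivity analysis mean — which averages 2000 single runs
and so suppresses that noise — sits at the same value). Published
single-run figures such as 0.024 scatter around the exact value within one
such standard error, as do single-run event-count and death differences.
The package's arm-difference outputs default to the cohort solver (or CRN
microsimulation) precisely to avoid this noise. For the same reason the
dynamic-treatment analysis, whose true effect is far below 0.028, is
meaningfully reported only as "within ±0.02 of zero".

## Sensitivity analyses

* **Probabilistic**: both RRs are sampled independently from log-normal
  distributions fitted to their CIs (`μ = ln point`,
  `σ = (ln hi − ln lo)/(2 × 1.959964)`); each draw re-derives the treated
  rates (same 80% bleeding weight) and runs both arms. In microsim mode the
  per-iteration difference carries Monte-Carlo noise on top of parameter
  uncertainty — deliberately, mirroring the source analysis; cohort mode
  isolates parameter uncertainty and yields a higher favouring proportion.
  Draws that would make a derived rate negative (possible only for extreme
  protective bleeding RRs) are resampled and counted.
* **Trial-specific effects**: stroke/bleeding RR 0.79/2.10 (NOAH-AFNET 6)
  or 0.62/1.36 (ARTESiA), all else base case.
* **Observational baseline rates**: stroke/bleeding/death raised to
  1.9/1.7/8.5 per 100 patient-years, bleeding subtypes rescaled
  proportionally.
* **Bleeding-weight sweep**: extracranial share varied 0.70–0.90; the QALY
  difference is monotone increasing in the weight, since more of the harm
  lands on the least severe bleed type.
* **Dynamic treatment**: intracranial bleeding on NOAC stops treatment
  permanently, ischemic stroke starts (or restarts) it in either arm —
  most recent event wins; extracranial bleeds keep the ordinary pause;
  arms are compared by initial assignment (intention to treat).
* **Risk-score strata**: the runner applies ARTESiA effects to
  caller-supplied stratum rates; the per-stratum numeric inputs live in the
  source study's supplement and are not shipped, so the runner errors
  helpfully until they are provided.

## The synthetic module

Toy models reuse the full configuration schema, so oracle tests exercise
the production engines rather than special-cased paths. The death-only toy
inverts the hazard transform so the monthly death probability is *exactly*
the requested `q`; the single-event toy uses the extracranial event type
(the only one without an excess-mortality clock) with a degenerate severity
and stores a closed form for the ever-affected fraction `1 − (1−p)^T` and
for expected QALYs via the time-to-most-recent-event decomposition.
`perturb_parameters()` jitters every rate and severity log-normally,
renormalizes and revalidates, for crash-and-invariant property tests. The
toys emulate the model's bookkeeping exactly, but not, of course, the
joint realism of the full parameter set — passing toy tests validates the
accounting, not the epidemiology.

## Numerical and design notes

* One transition per cycle (single categorical draw); monthly probabilities
  are far from saturating, so no renormalization is needed.
* The expanded-state solver guards against state-space explosion (bound
  200 000 states; reached only with implausible pause lengths).
* A pause cycle uses untreated rates *and* untreated severities; the
  no-NOAC arm has nothing to pause, and clinical-AF rates do not depend on
  treatment, so pauses are meaningful only in subclinical treated state.
* Clocks persist across conversion to clinical AF.
* With both RRs set to 1 the two arms still differ slightly under the base
  severity tables, because the NOAC arm keeps the with-NOAC severity
  columns (milder strokes, deadlier intracranial bleeds). The identity
  "equal arms" invariant holds — and is tested to 1e-10 — when the severity
  columns are also equalized.
* Problem sizes used by the test and reproduction scripts: 10 000 patients
  per arm for headline counts, 50 000 for solver-agreement checks, 500
  PSA iterations (the full 2000 is a one-line change).

## Limitations

The model inherits the source analysis's scope: ischemic stroke, major
bleeding, all-cause death and progression to clinical AF only — no
myocardial infarction, pulmonary embolism or non-major bleeding; perfect
NOAC adherence; no cost or treatment-burden disutility; utilities from
general-population and stroke-cohort studies rather than trial-measured
quality of life. The exact state diagram of the source implementation was
not available; the state granularity here reproduces every mechanism the
source describes, but equivalence is established against its published
outputs, not its code.
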