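# Base-case parameter set: 77-year-old patient with device-detected
# subclinical AF; untreated event rates averaged over the two randomized
# trials; pooled meta-analytic relative risks for NOAC therapy.
name: base_case
start_age: 77
horizon: 120          # cycles
cycle_length: 1       # months
n_patients: 10000     # per arm
extracranial_bleed_weight: 0.80
pause_cycles_after_bleed: 1
rng_seed: 42
use_common_random_numbers: false
dynamic_policy: false
event_rates:          # untreated, per 100 patient-years
  ischemic_stroke: 1.05
  major_bleeding_total: 1.06
  hemorrhagic_stroke: 0.18
  other_intracranial_bleeding: 0.15
  extracranial_major_bleeding: 0.73
  death: 4.26
  clinical_af_progression: 7.50
treatment_effect:     # relative risks with 95% CI
  rr_ischemic_stroke: {point: 0.68, ci_low: 0.50, ci_high: 0.92}
  rr_major_bleeding: {point: 1.62, ci_low: 1.05, ci_high: 2.50}
severity:             # probability of each outcome severity, by treatment
  ischemic_stroke:
    categories: [death, severe, moderate, mild]
    untreated: [0.187, 0.156, 0.220, 0.437]
    treated: [0.120, 0.124, 0.247, 0.509]
  hemorrhagic_stroke:
    categories: [death, severe, moderate, mild]
    untreated: [0.175, 0.172, 0.301, 0.352]
    treated: [0.305, 0.206, 0.190, 0.293]
  other_intracranial_bleeding:
    categories: [death, severe, mild, none]
    untreated: [0.157, 0.179, 0.332, 0.332]
    treated: [0.176, 0.237, 0.293, 0.293]
  extracranial_major_bleeding:
    categories: [death, severe, mild, none]
    untreated: [0.025, 0.008, 0.058, 0.909]
    treated: [0.035, 0.007, 0.056, 0.902]
utility:
  base_weight_77_80: 0.794   # well, ages [77, 80)
  base_weight_80_87: 0.733   # well, ages [80, 87]
  qaly_ratio:                # multiplies the age-band base weight
    mild: {first_6_months: 0.88, after_6_months: 0.89}
    moderate: {first_6_months: 0.60, after_6_months: 0.73}
    severe: {first_6_months: 0.16, after_6_months: 0.45}
  death_weight: 0
post_event_mortality:        # extra first-year mortality, 1-y probability
  one_year_prob_after_ischemic_stroke: 0.14
  one_year_prob_after_intracranial_bleeding: 0.16
clinical_af_risks:           # 1-year probabilities after clinical AF onset
  ischemic_stroke: 0.025
  hemorrhagic_stroke: 0.005
  other_intracranial_bleeding: 0.005
  extracranial_major_bleeding: 0.028
  death: 0.110
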