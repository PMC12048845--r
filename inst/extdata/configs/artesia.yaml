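# Scenario: effect estimates from the ARTESiA trial.
name: artesia
overrides:
  treatment_effect:
    rr_ischemic_stroke: {point: 0.62, ci_low: 0.62, ci_high: 0.62}
    rr_major_bleeding: {point: 1.36, ci_low: 1.36, ci_high: 1.36}
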