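# Scenario: effect estimates from the NOAH-AFNET 6 trial (point estimates
# substituted for both treatment effects; all other inputs base case).
name: noah
overrides:
  treatment_effect:
    rr_ischemic_stroke: {point: 0.79, ci_low: 0.79, ci_high: 0.79}
    rr_major_bleeding: {point: 2.10, ci_low: 2.10, ci_high: 2.10}
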