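# Scenario: untreated baseline stroke, bleeding and mortality rates raised
# to observational-study levels. Bleeding subtypes are rescaled
# proportionally (0.18 : 0.15 : 0.73) to the new total of 1.7.
name: observational
overrides:
  event_rates:
    ischemic_stroke: 1.9
    major_bleeding_total: 1.7
    hemorrhagic_stroke: 0.28867924528301887
    other_intracranial_bleeding: 0.24056603773584906
    extracranial_major_bleeding: 1.17075471698113207
    death: 8.5
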