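# Template for a stroke-risk-score stratum analysis. The numeric stratum
# inputs (untreated rates by CHA2DS2-VASc category) are not shipped; fill in
# every field below from the source supplement before use. The stratum
# runner applies the ARTESiA effect estimates on top of these rates.
name: stratum_template
overrides:
  event_rates:
    ischemic_stroke: null        # per 100 patient-years, stratum-specific
    major_bleeding_total: null
    hemorrhagic_stroke: null
    other_intracranial_bleeding: null
    extracranial_major_bleeding: null
    death: null
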