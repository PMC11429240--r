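study: higbee
regimen: {amount: 2000, kind: infusion, infusion_duration: 0.5}
proportion_female: 0
fe_cutoff: 12
arms:
  - {code: G, age_range: [69, 90], renal: {clcr_range: [24, 80], normalized: false}, horizon: 48}
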