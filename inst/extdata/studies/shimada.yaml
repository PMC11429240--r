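study: shimada
regimen: {amount: 1000, kind: bolus}
fe_cutoff: 12
arms:
  - {code: F, age_range: [68, 82], proportion_female: 0.333,
     renal: {clcr_range: [30, 70], normalized: false}, horizon: 48}
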